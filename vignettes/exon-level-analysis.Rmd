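---
title: "Methods: exon-level analysis of combinatorial-indexing snRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exon-level analysis of combinatorial-indexing snRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models and the choices behind
them: what each stage assumes, which parameters matter, what the synthetic
study does and does not emulate, and where the design was genuinely open.

## The data model

A combinatorial-indexing single-nucleus library encodes cell identity as the
pair (RT barcode, ligation barcode); the RT barcode also identifies the
sample (animal replicate). Each captured molecule carries a UMI, a primer
type (oligo-dT or random hexamer), and — after tagmentation — a genomic
fragmentation site. PCR copies of a molecule share the barcode combination,
the UMI, and the tagmentation site, which is therefore the duplicate
collapsing key. Because hexamer priming samples the whole gene body, reads
land in introns as well as exons, and the per-gene intronic read fraction
(gene-assigned molecules touching no exon, over all gene-assigned molecules)
is a usable proxy for the unspliced share of a gene's transcripts.

## Barcode correction and deduplication

Barcodes are corrected to the unique whitelist entry within edit distance 1;
ties and distance >= 2 exclude the read. "Edit distance" is implemented as
Hamming distance: for equal-length barcodes and a threshold below 2 the two
metrics coincide in practice, and the Hamming form admits an exact
precomputed-neighbour table (a Levenshtein mode is available behind
`demux_config(metric = "levenshtein")`). The packaged whitelists are
generated from a fixed internal seed with pairwise distance >= 3, so a
single substitution is always uniquely correctable.

The deduplication key includes the ligation barcode alongside the RT
barcode: cell identity in sci protocols is the barcode *combination*, so
collapsing across ligation barcodes would merge molecules of different
cells. `deduplicate(include_ligation = FALSE)` exposes the narrower key.
The representative read of each molecule is the first after a deterministic
position sort, and the operation is idempotent.

## Gene and exon assignment

Assignment applies four rules in order: (1) direct same-strand overlap;
(2) among multiple overlaps, an oligo-dT molecule is assigned to the gene
whose annotated 3' end is nearest the molecule's 3'-most aligned base
(strand-aware, in bp, ties broken lexicographically by gene id — a
deterministic stand-in for an unstated tie rule); ambiguous hexamer
molecules are discarded by default because the 3'-bias argument only
justifies the rule for dT priming (`assign_config(ambiguous_hexamer =
"closest3p")` extends it); (3) a molecule with no direct hit is rescued by
the unique gene starting within 1,000 bp downstream on the same strand,
else by the unique antisense-overlapping gene — upstream rescue is tried
first because it retains the sense-transcription interpretation; (4)
otherwise the molecule is dropped. The 1,000 bp window is inclusive: a
molecule exactly 1,000 bp upstream is rescued, 1,001 bp is not.

Exon features are the *merged union* of transcript exons per gene,
identified `gene:index` in transcription order. Whether exon counting
should merge overlapping isoform exons is a dialect choice (no transcript
resolution is implied by gene-level exon counts); merging makes exon counts
well-defined without an isoform model and is used consistently by the
quantifier, the DE stage and the domain mapper. Exon ambiguity for boundary
molecules is broken by the greatest overlap length, then 3'-proximity for dT
molecules, then exon id.

## Coordinates

Internally everything is 1-based inclusive — the GTF/GRanges convention —
so no conversion layer sits between the interval index and the Bioconductor
containers. Genomic-to-protein mapping intersects an interval with a
transcript's CDS segments, maps to CDS-relative nucleotide offsets
respecting strand, and returns the bounding amino-acid interval with
partial codons included (floor/ceil) — conservative for domain overlap,
since a boundary codon counts as touched. Transcripts whose CDS length is
not divisible by 3 are flagged out-of-frame and excluded from domain
mapping rather than silently truncated.

## Cell QC and doublet scoring

Cells are kept iff total UMIs >= `min_umis` (brain preset 500, cell-line
preset 1000) *and* detected genes >= 100: "discard below X and Y" is read as
standard QC semantics (discard if either fails). The doublet scorer follows
the simulated-doublet kNN design: `sim_doublet_ratio` (2) synthetic doublets
per observed cell are built by summing random observed pairs; genes are
filtered (count >= 3 in >= 3 cells); genes above the 85th variability
percentile are z-scaled; PCA (30 components) is fit on observed cells and
simulated cells are projected; a kNN graph (k = 30) spans the union. With
neighbour fraction `q`, ratio `r` and prior rate `rho` (0.06), the score is
the posterior

    f_d/f_s = q (1 - rho) / (r (1 - q) - q rho)
    score   = rho (f_d/f_s) / ((1 - rho) + rho (f_d/f_s))

clipped to [0, 1] and monotone in `q`; calls use score > 0.2. On the default
synthetic study this threshold is deliberately aggressive (it removes some
large homotypic singlets along with most true doublets); equivalence with
the reference scorer is asserted at the *ranking* level (AUROC vs ground
truth > 0.8), not score-for-score, because the original calibration is not
restated anywhere usable. Manual doublet-subcluster curation is out of
scope; scores are exported for review.

## Differential expression

Each feature (gene or exon) is tested by a negative-binomial
likelihood-ratio test: log link, `log(cell total)` offsets (size factors are
cell totals, consistent with the CPM framing — no median-of-ratios),
full model intercept + condition vs intercept-only, p from chi-squared with
1 df. Dispersion is per-feature by method of moments, shared across
conditions, floored at 1e-4; non-converging fits fall back to Poisson with
a flag. Fold changes are mean-based, not model-derived: the ratio of
per-condition mean CPM with a pseudocount of 1 CPM, thresholded
two-sidedly (> 1.5 or < 1/1.5). The reference condition is the first factor
level (or first appearance), so fold changes are reported aged-over-young
in the default design.

Genes and exons are tested as one concatenated feature list with a single
BH correction — the combined list gives exon tests the support of the
better-powered gene features in the FDR calculation. Calling uses
FDR < 0.05 and |FC| > 1.5 with max-condition CPM > 25 for genes and > 10
for exons. The classification re-filter is the subtle rule worth restating:
a DEE is *DEG-derived* iff its parent gene passes FDR and FC at the **exon**
CPM cutoff (> 10). A parent can therefore support its exon while failing
the stricter gene cutoff and not being a DEG itself; non-DEG-derived DEEs
are exactly those whose parent is undetectable even under the laxer
criterion.

## Neighborhood abundance

Neighborhoods are an index cell plus its k = 60 nearest neighbours
(Euclidean, exact) on a supplied embedding; index cells are a seeded sample
of all cells. Abundance is tested by the same NB-LRT applied to per-sample
cell counts with `log(sample total)` offsets. Plain BH across neighborhoods
replaces the graph-weighted spatial FDR of the established
neighborhood-testing framework — a documented deviation; the bespoke parts
(radius expansion and proportion labeling) are implemented exactly:
expanded membership is the union of the original members and all cells
within a fixed radius of the index cell's 2-D coordinates, proportions use
raw cell counts (no per-condition size normalisation, matching the
labeling description; a normalised mode is left to the caller via
pre-balanced inputs), and a label requires one condition to *strictly*
exceed 70.5% — 0.8 labels, 0.7 does not. The default radius is the median
index-to-k-th-neighbour distance, since no radius value is stated; it is a
config parameter.

## Probe candidates

Probe windows are 2 x 25 nt half-sites around a 2-nt gap — the split
initiator convention; the source tool does not print its geometry, so both
are configurable. Filters are independent and conjunctive: homopolymer runs
(A or T <= 5, C or G <= 4), per-half-site GC in [45, 60]%, and half-site GC
within 6 percentage points. Selection maximises the minimum inter-pair
spacing exactly (binary search on the spacing with a greedy feasibility
check — optimal for points on a line), after removing overlapping windows;
off-target screening is out of scope but candidates export to FASTA for an
external screen.

## The synthetic study

The generator emulates the study design the pipeline expects: two ages
(young, aged) x 3 replicate animals x 500 barcodes = 3,000 cells; four
oligodendrocyte-lineage-like subtypes (OPC, MFOL, MOL2, MOL56) whose
proportions shift with age (intermediate states depleted, the mature
subtype expanded); 6% doublet barcodes simulated as the sum of two
independently drawn cells; barcode errors as single substitutions at 2% of
reads; PCR duplication at 1.3 mean copies per molecule; a 50/50 dT/hexamer
primer mix. Counts are gamma-Poisson: per cell and gene,
`NB(mu = 900 x size_factor x p_gene, dispersion 0.3)` with lognormal size
factors (sd 0.3 on the log scale); each gene's molecules are then split
multinomially over its merged exons and intronic space. Gene effects are
drawn at |log2FC| in {0.5, 1, 1.5} for 15% of genes; 8% of exons get usage
shifts, a quarter of which (within DE genes) are forced to oppose the gene's
direction; four splicing-shift genes carry condition-dependent intron
fractions (0.961 young, 0.771 aged) together with a gene-level decline, so
their exonic signal rises against the gene trend — the decoupling the
combined test is built to detect. Two splicing-factor genes are injected
DE-up, and CLIP-target membership is drawn with 6x odds for genes carrying
a true differential exon. Where the emulated design states no value (gene
panel size, expression scale, dispersion, error and duplication rates)
the defaults are one-time choices at what a practitioner would call
realistic desk scale, documented here and never revisited per test outcome.

Because effects are drawn first and counts sampled after, estimates recover
the *recorded* truth only within sampling error; the truth table stores both
the drawn effect and the realized mean-model log2FC per subtype (which
absorbs the compositional shift of library-size normalisation), and
recovery tests compare against the realized value.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: ambient RNA, batch effects beyond
replicate labels, base-level sequencing error, positional (3' or 5') bias
within transcripts, isoform-level expression structure, or realistic
between-gene correlation. The simulated genes are also disjoint in the
genome, so the ambiguity and rescue branches of gene assignment are
exercised by constructed fixtures rather than by the simulation.

## Numerical choices and degenerate inputs

All-zero features return p = 1 and log2FC 0. Zero-total cells are excluded
from CPM with a warning. Replicates with zero molecules for a gene are
excluded from the intron-fraction t test; fewer than two remaining
replicates per group yields an undefined p, reported as NA, and identical
groups report p = 1. Empty molecule sets produce valid 0 x 0 matrices.
Fisher tables with empty margins return p = 1; infinite odds ratios are
representable. Assignment and selection ties break deterministically
(lexicographic ids, position sorts), and every stochastic step draws from a
seed derived from the single global seed via a documented stage-name hash,
so stages are individually reproducible and whole runs are bit-identical
per seed.

## Problem sizes used by the tests

The test suite and the acceptance script run the full default study
(3,000 cells, 150 genes, ~600 merged exons, ~3.5 million reads) once and
share it across checks; unit tests use a 40-gene, 360-cell study and
constructed fixtures. Calibration checks use 2,000 null NB features at 60
cells per condition and 800-cell null embeddings. These sizes are the
package's desk-scale choices: large enough for the statistical bands the
tests assert (binomial 99% intervals, AUROC > 0.8, recall >= 0.8), small
enough to run on a laptop in minutes.

## Known limitations

The NB-LRT uses a plug-in method-of-moments dispersion rather than a
shrunken estimate, which is slightly anticonservative for very low counts
(the floor and the combined-list BH temper this; the null-calibration test
bounds it). The doublet score calibration is a principled posterior, not a
replica of any particular tool's score scale, so the 0.2 threshold trades
recall for precision differently than elsewhere. Spatial FDR weighting for
neighborhoods is intentionally absent. The probe stage screens sequence
composition only — no thermodynamics, no off-target alignment.
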