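# exonsci

Exon-level downstream analysis for combinatorial-indexing single-nucleus
RNA-seq with full gene-body coverage.

Plate-based combinatorial indexing (sci) protocols encode cell identity as a
combination of barcodes added in successive rounds (an RT barcode that also
marks the sample, and a ligation barcode), use both oligo-dT and random
hexamer priming, and collapse PCR duplicates on the UMI + barcode +
tagmentation-site key. Because coverage spans the whole gene body, the same
libraries support **exon-level** differential expression — including exons
whose age-related dynamics run *against* their parent gene — and intronic
read fractions as a proxy for unspliced transcripts. `exonsci` implements
that downstream analysis as a tested R pipeline, together with a seeded
synthetic-data generator that emulates a two-age (young vs aged), three
replicate per age, oligodendrocyte-enrichment study so that every stage is
verifiable without any external download.

## What the pipeline computes

1. **Read processing** — barcode correction against whitelists (unique
   Hamming distance-1 correction, ties discarded), sample demultiplexing via
   the RT barcode, and PCR-duplicate collapsing on the
   (RT barcode, ligation barcode, UMI, tagmentation site) key.
2. **Quantification** — gene assignment with the field's ambiguity rules:
   direct same-strand overlap; ambiguous oligo-dT molecules go to the gene
   with the closest annotated 3' end; unassigned molecules are rescued from
   up to 1,000 bp upstream on the same strand, else from a unique antisense
   overlap. Exon counts use merged gene-level exon features; gene-assigned
   molecules touching no exon are intronic.
3. **Cell QC** — UMI/gene thresholds (brain preset: >= 500 UMIs and >= 100
   genes) and a simulated-doublet kNN classifier (sum random cell pairs,
   variable-gene PCA, kNN over observed + simulated, calibrated score with
   call threshold 0.2).
4. **Differential expression** — per-feature negative-binomial
   likelihood-ratio test (log link, library-size offsets, method-of-moments
   dispersion) applied to a *combined* gene+exon feature list with one BH
   correction. DEG: FDR < 0.05, |FC| > 1.5, max-condition CPM > 25. DEE:
   same, CPM > 10. A DEE is **DEG-derived** iff its parent gene passes when
   re-filtered at the exon CPM cutoff (> 10) — so a parent can support its
   exon without itself being a DEG.
5. **Exon-to-domain mapping** — each DEE's genomic interval is intersected
   with the CDS of its gene's transcripts, converted to amino-acid
   coordinates, and matched against annotated protein-domain intervals.
6. **Splicing-factor target enrichment** — one-sided Fisher exact test of
   CLIP-target membership among DEE parent genes vs non-DEE tested genes.
7. **Neighborhood differential abundance** — kNN neighborhoods (k = 60) on a
   2-D embedding, NB-LRT on per-sample cell counts with sample-total
   offsets, BH across neighborhoods, then radius expansion with
   *Young-/Aged-enriched* labeling when one age group strictly exceeds 70.5%
   of a neighborhood's cells.
8. **HCR split-probe candidates** — 25-nt half-site pairs with a 2-nt gap,
   skipping the first 100 bp, homopolymer limits (A/T <= 5, C/G <= 4), GC in
   [45, 60]% with half-sites within 6 points, spaced by exact max-min
   selection.

## Worked example

```r
library(exonsci)

res <- run_pipeline(pipeline_config(out_dir = "demo_run", seed = 1))

length(res$qc$kept_cells)
#> [1] 2261                         # of 3,000 simulated barcodes

tab <- res$de[["MOL2"]]            # young vs aged within the MOL2 subtype
sum(tab$is_deg); sum(tab$is_dee)
#> [1] 24
#> [1] 116
table(tab$dee_class)
#> DEG-derived  non-DEG-derived
#>          71               45

res$shared_deg$r                   # fold-change agreement across subtypes
#> [1] 0.9910218

res$intron_tests[[1]]$group_stats  # splicing-shift gene, intronic fraction
#>    condition   mean     sem  n
#>       aged   0.774   0.004   3
#>       young  0.966   0.001   3
```

The run directory contains per-stage outputs (MTX count matrices, DE tables,
domain hits, enrichment results, neighborhood labels, probe sheets) plus
`manifest.yaml` with parameters and md5 checksums; reruns with the same seed
are bit-identical. A thin CLI wrapping the same functions is installed at
`system.file("cli/exonsci.R", package = "exonsci")`.

Interpretation: 24 genes and 116 exons change between the simulated ages in
MOL2; 45 of those exons belong to genes that are *not* detectable as DEGs
even at the exon-level expression cutoff — the signal the combined gene+exon
test exists to expose. The intronic fraction of the splicing-shift genes
drops from ~97% to ~77% with age, the simulator's stand-in for an
age-dependent splicing change.

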