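#' Configuration for the synthetic study generator
#'
#' Defines the simulated study: a two-age (young, aged) design with three
#' replicate animals per age, several oligodendrocyte-lineage-like subtypes
#' whose mixing proportions shift with age, gene-level fold changes,
#' exon-level usage shifts decoupled from (and sometimes opposed to) their
#' parent genes, condition-dependent intronic read fractions for a small set
#' of splicing-shift genes, ~6% doublets, single-substitution barcode errors,
#' and PCR duplication of molecules.
#'
#' Counts are gamma-Poisson: per cell and gene, `count ~ NB(mu, 1/dispersion)`
#' with `mu = mean_umis * size_factor * p_gene(subtype, condition)`; each
#' gene's molecules are then split multinomially across its merged exons and
#' intronic space according to per-condition usage shares and intron
#' fractions.
#'
#' @param n_genes number of genes
#' @param exons_per_gene integer range (min, max) of exons per gene
#' @param exon_length,intron_length bp ranges
#' @param cds_fraction fraction of transcript length that is coding
#' @param n_cells_per_replicate cells (barcodes) per replicate animal
#' @param replicates_per_condition replicate animals per age group
#' @param conditions condition labels; first is the reference
#' @param subtypes subtype labels
#' @param subtype_props named list (per condition) of mixing proportions,
#'   each summing to 1
#' @param n_marker_genes,marker_boost subtype marker genes and their
#'   expression multiplier
#' @param mean_umis_per_cell,umi_sd_log lognormal cell size model
#' @param gene_de_fraction fraction of genes given a condition effect
#' @param gene_log2fc candidate |log2FC| magnitudes for gene effects
#' @param exon_de_fraction fraction of exons given a usage shift
#' @param exon_log2fc candidate |log2FC| magnitudes for exon usage shifts
#' @param opposed_exon_fraction fraction of usage-shifted exons in
#'   DE genes forced to the opposite sign of their parent gene
#' @param intron_fraction_range per-gene intronic read fraction range
#'   (stable genes; same in both conditions)
#' @param n_splice_shift_genes genes whose intron fraction is
#'   condition-dependent
#' @param splice_shift_fractions named intron fractions (young, aged) for
#'   splice-shift genes
#' @param n_splicing_factors number of splicing-factor genes (made DE-up)
#' @param clip_target_rate baseline probability a gene is a CLIP target
#' @param clip_target_odds odds multiplier for genes carrying a true DE exon
#' @param doublet_rate fraction of barcodes receiving two cells
#' @param barcode_error_rate per-read probability of one barcode substitution
#' @param umi_duplication_rate mean PCR copies per molecule (>= 1)
#' @param dt_primer_fraction fraction of molecules primed with oligo-dT
#' @param dispersion NB overdispersion (variance = mu + dispersion * mu^2)
#' @param read_length aligned read footprint in bp
#' @param umi_length,barcode_length UMI and barcode lengths in nt
#' @param seed integer seed; identical seeds give byte-identical outputs
#' @return validated list of class `sim_config`
#' @export
sim_config <- function(n_genes = 150L,
                       exons_per_gene = c(2L, 6L),
                       exon_length = c(150L, 400L),
                       intron_length = c(200L, 1500L),
                       cds_fraction = 0.6,
                       n_cells_per_replicate = 500L,
                       replicates_per_condition = 3L,
                       conditions = c("young", "aged"),
                       subtypes = c("OPC", "MFOL", "MOL2", "MOL56"),
                       subtype_props = list(
                         young = c(OPC = 0.15, MFOL = 0.25, MOL2 = 0.25, MOL56 = 0.35),
                         aged  = c(OPC = 0.15, MFOL = 0.10, MOL2 = 0.25, MOL56 = 0.50)),
                       n_marker_genes = 12L,
                       marker_boost = 8,
                       mean_umis_per_cell = 900,
                       umi_sd_log = 0.3,
                       gene_de_fraction = 0.15,
                       gene_log2fc = c(0.5, 1, 1.5),
                       exon_de_fraction = 0.08,
                       exon_log2fc = c(1, 1.5),
                       opposed_exon_fraction = 0.25,
                       intron_fraction_range = c(0.05, 0.4),
                       n_splice_shift_genes = 4L,
                       splice_shift_fractions = c(young = 0.961, aged = 0.771),
                       n_splicing_factors = 2L,
                       clip_target_rate = 0.15,
                       clip_target_odds = 6,
                       doublet_rate = 0.06,
                       barcode_error_rate = 0.02,
                       umi_duplication_rate = 1.3,
                       dt_primer_fraction = 0.5,
                       dispersion = 0.3,
                       read_length = 60L,
                       umi_length = 8L,
                       barcode_length = 10L,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#' @param cfg a [sim_config()]
#' @return `cfg` invisibly; errors on violation
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  frac <- c(cds = cfg$cds_fraction, gene_de = cfg$gene_de_fraction,
            exon_de = cfg$exon_de_fraction, opposed = cfg$opposed_exon_fraction,
            doublet = cfg$doublet_rate, bc_err = cfg$barcode_error_rate,
            dt = cfg$dt_primer_fraction, clip = cfg$clip_target_rate)
  if (any(frac < 0 | frac > 1)) stopf("fractions must lie in [0,1]")
  if (any(c(cfg$exon_length, cfg$intron_length, cfg$read_length,
            cfg$umi_length, cfg$barcode_length) <= 0))
    stopf("lengths must be positive")
  if (cfg$umi_duplication_rate < 1) stopf("umi_duplication_rate must be >= 1")
  if (length(cfg$conditions) != 2L) stopf("exactly two conditions are supported")
  for (cond in cfg$conditions) {
    p <- cfg$subtype_props[[cond]]
    if (is.null(p) || length(p) != length(cfg$subtypes) || abs(sum(p) - 1) > 1e-8)
      stopf("subtype proportions for '%s' must match subtypes and sum to 1", cond)
  }
  rng <- cfg$intron_fraction_range
  if (any(rng < 0 | rng > 1) || rng[1] > rng[2]) stopf("invalid intron_fraction_range")
  if (any(cfg$splice_shift_fractions < 0 | cfg$splice_shift_fractions > 1))
    stopf("splice_shift_fractions must lie in [0,1]")
  # minimum exon count must accommodate the CDS structure
  if (cfg$cds_fraction <= 0) stopf("cds_fraction must be > 0")
  if (3 * cfg$exon_length[1] * cfg$exons_per_gene[1] * cfg$cds_fraction < 3)
    stopf("CDS cannot fit the exon structure")
  invisible(cfg)
}
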