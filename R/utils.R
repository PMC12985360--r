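#' @importFrom data.table data.table as.data.table setDT setkey setkeyv
#'   setorder setorderv setcolorder setnames rbindlist fwrite fread CJ
#'   tstrsplit uniqueN copy := .N .SD .BY
#' @importFrom methods is
#' @importFrom stats rnbinom rpois rbinom rnorm runif rmultinom prcomp p.adjust
#'   pchisq glm anova t.test cor.test phyper quantile median var sd setNames
#'   rlnorm dhyper offset
#' @importFrom utils head tail
NULL

# data.table NSE columns
utils::globalVariables(c(
  ".", ".mol_row", "N", "aa_end", "aa_start", "assign_class", "cds_off",
  "cell_id", "cell_row", "chrom", "coding", "condition", "corrected", "d3",
  "dee_class", "delta_log2fc", "direction", "dist3p", "domain_name", "end",
  "end3", "ex_end", "ex_start", "exact", "exon_gene", "exon_id",
  "exon_log2fc", "exon_rank", "fdr", "feature_id", "gc1", "gc2", "gene_id",
  "gene_idx", "half1", "half2", "i_end", "i_start", "intron_fraction",
  "intron_fraction_aged", "intron_fraction_young", "is_dee", "is_dee_true",
  "is_deg", "is_deg_true", "is_doublet", "is_doublet_call",
  "is_splice_shift", "is_splicing_factor", "kind", "kept", "label", "len",
  "lig_bc", "log2fc", "max_cpm", "molecule_id", "mrow", "n_reads", "nhit",
  "obs", "opposed", "ov", "p3", "p_value", "parent_gene",
  "partner_size_factor", "partner_subtype", "pass", "primer", "prof_key",
  "read_id", "reason", "replicate", "rt_bc", "sample_id", "size_factor",
  "sj", "start", "strand", "subtype", "tag_chrom", "tag_pos", "tag_strand",
  "phase", "i.phase",
  "transcript_id", "true_log2fc", "type", "umi", "usage_aged",
  "usage_shift", "usage_young", "width", "window_start", "x", "y"
))

#' Hamming distance between equal-length strings
#'
#' Vectorised over `a`; `b` is a single string of the same length.
#'
#' @param a character vector of strings
#' @param b single string
#' @return integer vector of mismatch counts
#' @keywords internal
hamming_dist <- function(a, b) {
  bs <- strsplit(b, "", fixed = TRUE)[[1]]
  vapply(strsplit(a, "", fixed = TRUE), function(x) sum(x != bs), integer(1))
}

#' Derive a stage-specific seed from a global seed
#'
#' Each pipeline stage draws from its own RNG stream so that stages are
#' individually reproducible regardless of what ran before them.
#'
#' @param seed global integer seed
#' @param stage stage name
#' @return integer seed < 2^31
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483629L)
}

#' Random fixed-length DNA strings
#' @keywords internal
random_dna <- function(n, len) {
  cols <- replicate(len, sample(c("A", "C", "G", "T"), n, replace = TRUE),
                    simplify = FALSE)
  do.call(paste0, cols)
}

#' Barcode whitelists for the combinatorial indexing rounds
#'
#' Deterministic 10-nt whitelists for the RT (first-round) and ligation
#' (second-round) barcodes, generated from a fixed internal seed so the same
#' lists ship with every installation. Entries are mutually at Hamming
#' distance >= 3 so that single-substitution errors are always uniquely
#' correctable.
#'
#' @param n number of barcodes (default 96, one per well)
#' @param len barcode length in nt (default 10)
#' @param which `"rt"` or `"ligation"` (distinct lists)
#' @return character vector of barcodes
#' @export
barcode_whitelist <- function(n = 96L, len = 10L, which = c("rt", "ligation")) {
  which <- match.arg(which)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(if (which == "rt") 104729L else 224737L)
  out <- character(0)
  while (length(out) < n) {
    cand <- random_dna(4L * n, len)
    for (b in cand) {
      if (length(out) >= n) break
      if (length(out) == 0L || all(hamming_dist(out, b) >= 3L)) out <- c(out, b)
    }
  }
  out[seq_len(n)]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Substitute one barcode position with a different base
#' @keywords internal
mutate_barcode <- function(bc) {
  n <- length(bc)
  len <- nchar(bc[1])
  pos <- sample.int(len, n, replace = TRUE)
  cur <- substring(bc, pos, pos)
  sub <- vapply(cur, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1),
                character(1), USE.NAMES = FALSE)
  substring(bc, pos, pos) <- sub
  bc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
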