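#' Select differentially expressed splicing factors
#'
#' Intersects the DEG list with a known splicing-factor gene set, retaining
#' the direction of change.
#'
#' @param de_table a flagged `de_table` (after [call_and_classify()])
#' @param splicing_factors character vector of splicing-factor gene ids
#' @return data.table: gene_id, log2fc, direction
#' @export
select_de_splicing_factors <- function(de_table, splicing_factors) {
  if (!length(splicing_factors)) stopf("empty splicing-factor set")
  tab <- as.data.table(de_table)
  hits <- tab[is_deg == TRUE & feature_id %in% splicing_factors,
              .(gene_id = feature_id, log2fc)]
  hits[, direction := ifelse(log2fc > 0, "up", "down")]
  setorder(hits, gene_id)
  hits[]
}

#' Fisher enrichment of splicing-factor targets among DEE parent genes
#'
#' For each factor, builds the 2x2 table (DEE-parent vs non-DEE-parent within
#' the tested-gene universe, by target vs non-target) and computes the
#' one-sided (greater) exact p as the hypergeometric tail, plus the sample
#' odds ratio. Targets outside the universe are dropped.
#'
#' @param dee_parents gene ids that parent at least one DEE (subset of
#'   `universe`)
#' @param universe all genes entering the DE test after expression filtering
#' @param targets data.table (factor_id, gene_id) of per-factor target genes
#' @return data.table per factor: counts of the 2x2 table, `odds_ratio`
#'   (Inf representable), one-sided `p_value`, and `n_dee_in_targets`
#' @export
fisher_target_enrichment <- function(dee_parents, universe, targets) {
  if (!length(universe)) stopf("empty universe")
  universe <- unique(universe)
  dee_parents <- unique(dee_parents)
  if (!all(dee_parents %in% universe)) stopf("dee_parents must be within the universe")
  targets <- as.data.table(targets)
  dropped <- targets[!gene_id %in% universe]
  if (nrow(dropped))
    message(sprintf("%d target entries outside the universe dropped", nrow(dropped)))
  factors <- sort(unique(as.character(targets$factor_id)))
  targets <- targets[gene_id %in% universe]
  out <- lapply(setNames(factors, factors), function(f) {
    tg <- targets[factor_id == f, gene_id]
    a <- sum(dee_parents %in% tg)                         # DEE-parent & target
    b <- length(dee_parents) - a                          # DEE-parent & non-target
    cc <- length(setdiff(tg, dee_parents))                # non-DEE & target
    d <- length(universe) - a - b - cc                    # non-DEE & non-target
    # one-sided (greater) hypergeometric tail: P(X >= a)
    p <- phyper(a - 1L, a + cc, b + d, a + b, lower.tail = FALSE)
    or <- if (b * cc == 0) {
      if (a * d == 0) NaN else Inf
    } else (a * d) / (b * cc)
    data.table(n_dee_target = a, n_dee_nontarget = b,
               n_nondee_target = cc, n_nondee_nontarget = d,
               odds_ratio = or, p_value = p, n_dee_in_targets = a)
  })
  res <- rbindlist(out, idcol = "factor_id")
  setorder(res, factor_id)
  res[]
}
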