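#' Differential-expression configuration
#'
#' Calling thresholds: a gene is a DEG iff FDR < 0.05, |fold change| > 1.5 and
#' CPM in the maximum condition > 25; an exon is a DEE with the same FDR and
#' fold-change cutoffs but max-condition CPM > 10, reflecting the lower
#' expression of individual exons. A DEE is DEG-derived iff its parent gene
#' passes the same criteria re-filtered at the exon CPM cutoff (> 10) instead
#' of the gene cutoff (> 25); otherwise the parent is detectable only at the
#' exon level and the DEE is non-DEG-derived.
#'
#' @param fdr_threshold BH FDR cutoff (0.05)
#' @param fold_change_threshold linear fold change (1.5, two-sided)
#' @param gene_cpm_threshold max-condition CPM required for DEG calls (25)
#' @param exon_cpm_threshold max-condition CPM for DEE calls and for the
#'   DEG-derived re-filter (10)
#' @param pseudocount CPM pseudocount for fold changes (1)
#' @param dispersion_floor lower bound for the method-of-moments NB
#'   dispersion (1e-4)
#' @return object of class `de_config`
#' @export
de_config <- function(fdr_threshold = 0.05, fold_change_threshold = 1.5,
                      gene_cpm_threshold = 25, exon_cpm_threshold = 10,
                      pseudocount = 1, dispersion_floor = 1e-4) {
  stopifnot(fdr_threshold > 0, fold_change_threshold > 0,
            gene_cpm_threshold > 0, exon_cpm_threshold > 0, pseudocount > 0,
            dispersion_floor > 0)
  structure(as.list(environment()), class = "de_config")
}

#' Counts-per-million normalisation
#'
#' @param mat a [count_matrix()]
#' @return dense-free feature x cell CPM matrix (`dgCMatrix`); zero-total
#'   cells are dropped with a warning
#' @export
cpm <- function(mat) {
  stopifnot(inherits(mat, "count_matrix"))
  tot <- mat$cell_totals
  if (any(tot == 0)) {
    warnf("%d zero-total cells excluded from CPM", sum(tot == 0))
  }
  m <- mat$counts[, tot > 0, drop = FALSE]
  Matrix::t(Matrix::t(m) / tot[tot > 0]) * 1e6
}

#' Per-condition mean CPM
#'
#' @param mat a [count_matrix()]
#' @param labels named condition vector (names = cell ids) or unnamed vector
#'   aligned with columns
#' @return matrix features x conditions of mean per-cell CPM
#' @export
condition_mean_cpm <- function(mat, labels) {
  cp <- cpm(mat)
  lab <- align_labels(labels, colnames(cp))
  vapply(sort(unique(lab)), function(g)
    Matrix::rowMeans(cp[, lab == g, drop = FALSE]), numeric(nrow(cp)))
}

align_labels <- function(labels, cells) {
  if (!is.null(names(labels))) {
    lab <- labels[cells]
    if (anyNA(lab)) stopf("labels missing for some cells")
    unname(lab)
  } else {
    if (length(labels) != length(cells)) stopf("label length mismatch")
    labels
  }
}

# Method-of-moments NB dispersion shared across conditions, floored.
mom_dispersion <- function(y, sf, lab, floor = 1e-4) {
  z <- y / sf
  est <- vapply(split(seq_along(y), lab), function(i) {
    m <- mean(z[i]); v <- var(z[i])
    if (!is.finite(v) || m == 0) return(NA_real_)
    (v - m * mean(1 / sf[i])) / m^2
  }, numeric(1))
  est <- est[is.finite(est)]
  max(floor, if (length(est)) mean(est) else floor)
}

#' Negative-binomial likelihood-ratio test for one feature
#'
#' Fits an NB regression with log link and `log(size factor)` offsets: full
#' model intercept + condition versus intercept-only; p from the chi-squared
#' deviance difference with 1 df. The per-feature dispersion is estimated by
#' method of moments (shared across conditions, floored). The fold change is
#' the ratio of per-condition mean CPM with a pseudocount, so it is
#' mean-based, not model-derived.
#'
#' @param counts integer vector over cells
#' @param labels condition factor/vector (2 levels; first level = reference)
#' @param size_factors per-cell totals (CPM-consistent size factors)
#' @param config a [de_config()]
#' @return list: `p_value`, `log2fc`, `mean_cpm` (per condition),
#'   `dispersion`, `poisson_fallback`
#' @export
nb_lrt <- function(counts, labels, size_factors, config = de_config()) {
  lab <- factor(labels)
  if (nlevels(lab) != 2L) stopf("exactly two conditions required")
  if (min(table(lab)) < 2L) stopf("need >= 2 cells per condition")
  cpm_i <- counts / size_factors * 1e6
  mean_cpm <- tapply(cpm_i, lab, mean)
  pc <- config$pseudocount
  l2fc <- log2((mean_cpm[2] + pc) / (mean_cpm[1] + pc))
  if (all(counts == 0)) {
    return(list(p_value = 1, log2fc = 0,
                mean_cpm = setNames(as.numeric(mean_cpm), levels(lab)),
                dispersion = NA_real_, poisson_fallback = FALSE))
  }
  off <- log(size_factors)
  phi <- mom_dispersion(counts, size_factors, lab, config$dispersion_floor)
  fallback <- FALSE
  dev <- tryCatch({
    fam <- MASS::negative.binomial(theta = 1 / phi)
    f1 <- suppressWarnings(glm(counts ~ lab + offset(off), family = fam))
    f0 <- suppressWarnings(glm(counts ~ 1 + offset(off), family = fam))
    if (!f1$converged || !f0$converged) stop("non-convergence")
    c(f0$deviance, f1$deviance)
  }, error = function(e) {
    fallback <<- TRUE
    f1 <- suppressWarnings(glm(counts ~ lab + offset(off), family = stats::poisson()))
    f0 <- suppressWarnings(glm(counts ~ 1 + offset(off), family = stats::poisson()))
    c(f0$deviance, f1$deviance)
  })
  stat <- max(0, dev[1] - dev[2])
  list(p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       log2fc = unname(l2fc),
       mean_cpm = setNames(as.numeric(mean_cpm), levels(lab)),
       dispersion = phi, poisson_fallback = fallback)
}

#' Combined gene + exon differential expression
#'
#' Runs the NB likelihood-ratio test per feature on the concatenated gene and
#' exon feature list and applies one Benjamini-Hochberg correction across all
#' features, which is what gives the exon tests the gene-level features'
#' support in the FDR calculation. Size factors are the per-cell totals of
#' the gene matrix (library size).
#'
#' @param gene_mat gene-level [count_matrix()]
#' @param exon_mat exon-level [count_matrix()] over the same cells (or NULL
#'   for a gene-only or exon-only run pass the one matrix you have)
#' @param labels condition labels (named by cell or aligned with columns)
#' @param config a [de_config()]
#' @return `de_table` data.table: feature_id, kind, parent_gene, p_value,
#'   fdr, per-condition mean CPM, max_cpm, log2fc
#' @export
run_combined_de <- function(gene_mat, exon_mat, labels, config = de_config()) {
  mats <- Filter(Negate(is.null), list(gene_mat, exon_mat))
  cellsets <- lapply(mats, function(m) colnames(m$counts))
  if (length(mats) == 2L && !identical(cellsets[[1]], cellsets[[2]]))
    stopf("gene and exon matrices must share the same cells")
  cells <- cellsets[[1]]
  lab <- align_labels(labels, cells)
  # preserve supplied level order (reference first); characters are taken in
  # order of first appearance
  lab <- if (is.factor(lab)) droplevels(lab) else factor(lab, levels = unique(lab))
  sf <- if (!is.null(gene_mat)) gene_mat$cell_totals else mats[[1]]$cell_totals
  if (any(sf == 0)) {
    keep <- sf > 0
    warnf("%d zero-total cells excluded", sum(!keep))
    mats <- lapply(mats, function(m) count_matrix(m$counts[, keep, drop = FALSE], m$kind))
    lab <- lab[keep]; sf <- sf[keep]
  }
  rows <- list()
  for (m in mats) {
    cm <- as.matrix(m$counts)
    res <- lapply(seq_len(nrow(cm)), function(i)
      nb_lrt(cm[i, ], lab, sf, config))
    lev <- levels(lab)
    rows[[length(rows) + 1L]] <- data.table(
      feature_id = rownames(cm), kind = m$kind,
      parent_gene = if (m$kind == "exon") m$parent_gene else rownames(cm),
      p_value = vapply(res, `[[`, numeric(1), "p_value"),
      log2fc = vapply(res, `[[`, numeric(1), "log2fc"),
      mean_cpm_1 = vapply(res, function(r) r$mean_cpm[[lev[1]]], numeric(1)),
      mean_cpm_2 = vapply(res, function(r) r$mean_cpm[[lev[2]]], numeric(1)),
      poisson_fallback = vapply(res, `[[`, logical(1), "poisson_fallback"))
  }
  tab <- rbindlist(rows)
  setnames(tab, c("mean_cpm_1", "mean_cpm_2"),
           paste0("mean_cpm_", levels(lab)))
  tab[, max_cpm := pmax(tab[[paste0("mean_cpm_", levels(lab)[1])]],
                        tab[[paste0("mean_cpm_", levels(lab)[2])]])]
  tab[, fdr := p.adjust(p_value, method = "BH")]
  structure(tab, class = c("de_table", class(tab)),
            conditions = levels(lab))
}

#' Call DEGs/DEEs and classify DEEs as DEG-derived or not
#'
#' DEG: gene with FDR below threshold, |FC| beyond the two-sided fold-change
#' threshold, and max-condition CPM above the gene cutoff. DEE: exon with the
#' same FDR/FC rules at the exon CPM cutoff. A DEE is DEG-derived iff its
#' parent gene passes FDR and FC with max-condition CPM above the *exon*
#' cutoff; a parent can thus be DEG-derived support without itself being a
#' DEG (it fails the stricter gene CPM cutoff).
#'
#' @param table a `de_table` from [run_combined_de()]
#' @param config a [de_config()]
#' @return the table with `is_deg`, `is_dee`, `dee_class` columns
#' @export
call_and_classify <- function(table, config = de_config()) {
  tab <- copy(as.data.table(table))
  lfc <- log2(config$fold_change_threshold)
  pass_stat <- tab$fdr < config$fdr_threshold & abs(tab$log2fc) > lfc
  tab[, is_deg := kind == "gene" & pass_stat & max_cpm > config$gene_cpm_threshold]
  tab[, is_dee := kind == "exon" & pass_stat & max_cpm > config$exon_cpm_threshold]
  # parent genes re-filtered at the exon CPM cutoff
  g <- tab[kind == "gene"]
  if (anyNA(match(tab[kind == "exon", parent_gene], g$feature_id)))
    stopf("exon with no parent gene row in the table")
  parent_pass <- g$fdr < config$fdr_threshold &
    abs(g$log2fc) > lfc & g$max_cpm > config$exon_cpm_threshold
  names(parent_pass) <- g$feature_id
  tab[, dee_class := NA_character_]
  tab[is_dee == TRUE,
      dee_class := ifelse(parent_pass[parent_gene], "DEG-derived", "non-DEG-derived")]
  tab[]
}

#' Correlation of shared fold changes between two analyses
#'
#' Intersects the features flagged in both tables (e.g. DEGs of two subtypes)
#' and reports the Pearson correlation of their log2 fold changes with the
#' t-transform p value (n - 2 df).
#'
#' @param table_a,table_b flagged `de_table`s (after [call_and_classify()])
#' @param flag `"is_deg"` or `"is_dee"`
#' @return list: `r`, `p_value`, `n_shared`, `shared` (data.table of pairs)
#' @export
shared_logfc_correlation <- function(table_a, table_b, flag = c("is_deg", "is_dee")) {
  flag <- match.arg(flag)
  a <- as.data.table(table_a)[get(flag) == TRUE, .(feature_id, log2fc_a = log2fc)]
  b <- as.data.table(table_b)[get(flag) == TRUE, .(feature_id, log2fc_b = log2fc)]
  shared <- merge(a, b, by = "feature_id")
  if (nrow(shared) < 3L) {
    return(list(r = NA_real_, p_value = NA_real_, n_shared = nrow(shared),
                shared = shared))
  }
  ct <- cor.test(shared$log2fc_a, shared$log2fc_b, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n_shared = nrow(shared),
       shared = shared)
}
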