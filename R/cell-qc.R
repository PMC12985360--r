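#' Cell quality-control configuration
#'
#' Presets follow the two tissue settings: brain nuclei keep cells with at
#' least 500 UMIs, cell lines require 1000; both require at least 100 unique
#' detected genes. Doublet-scorer parameters mirror the standard
#' simulated-doublet kNN classifier defaults: min_count 3, min_cells 3,
#' vscore_percentile 85, n_pc 30, expected_doublet_rate 0.06,
#' sim_doublet_ratio 2, n_neighbors 30, call threshold 0.2.
#'
#' @param preset `"brain"` or `"cellline"` (sets `min_umis`)
#' @param min_umis,min_genes keep a cell iff total UMIs >= `min_umis` AND
#'   detected genes >= `min_genes`
#' @param min_count,min_cells gene filter for doublet scoring: keep genes with
#'   count >= min_count in >= min_cells cells
#' @param vscore_percentile variability percentile for gene selection
#' @param n_pc number of principal components
#' @param expected_doublet_rate prior doublet rate
#' @param sim_doublet_ratio simulated doublets per observed cell
#' @param n_neighbors kNN size
#' @param doublet_threshold score above which a cell is called a doublet
#' @param seed seed for doublet-pair sampling
#' @return object of class `qc_config`
#' @export
qc_config <- function(preset = c("brain", "cellline"),
                      min_umis = NULL, min_genes = 100L,
                      min_count = 3L, min_cells = 3L,
                      vscore_percentile = 85,
                      n_pc = 30L, expected_doublet_rate = 0.06,
                      sim_doublet_ratio = 2, n_neighbors = 30L,
                      doublet_threshold = 0.2, seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(min_umis)) min_umis <- if (preset == "brain") 500L else 1000L
  stopifnot(min_umis >= 0, min_genes >= 0, n_pc >= 1, n_neighbors >= 1,
            expected_doublet_rate > 0, expected_doublet_rate < 1)
  structure(list(preset = preset, min_umis = as.integer(min_umis),
                 min_genes = as.integer(min_genes),
                 min_count = as.integer(min_count),
                 min_cells = as.integer(min_cells),
                 vscore_percentile = vscore_percentile, n_pc = as.integer(n_pc),
                 expected_doublet_rate = expected_doublet_rate,
                 sim_doublet_ratio = sim_doublet_ratio,
                 n_neighbors = as.integer(n_neighbors),
                 doublet_threshold = doublet_threshold, seed = as.integer(seed)),
            class = "qc_config")
}

#' Filter low-quality cells by UMI and gene thresholds
#'
#' A cell is kept iff its total UMIs >= `min_umis` and its number of detected
#' genes >= `min_genes` (boundary inclusive). Idempotent.
#'
#' @param mat a gene-level [count_matrix()]
#' @param config a [qc_config()]
#' @return list with `matrix` (filtered [count_matrix()]) and `report`
#'   (data.table of all cells with totals, gene counts, kept flag and
#'   discard reason)
#' @export
filter_cells <- function(mat, config = qc_config()) {
  stopifnot(inherits(mat, "count_matrix"))
  totals <- mat$cell_totals
  ngenes <- Matrix::colSums(mat$counts > 0)
  keep <- totals >= config$min_umis & ngenes >= config$min_genes
  reason <- rep(NA_character_, length(keep))
  reason[ngenes < config$min_genes] <- sprintf("fewer than %d genes", config$min_genes)
  reason[totals < config$min_umis] <- sprintf("fewer than %d UMIs", config$min_umis)
  report <- data.table(cell_id = colnames(mat$counts), n_umis = totals,
                       n_genes_detected = ngenes, kept = keep, reason = reason)
  if (!any(keep)) warnf("no cells pass the QC thresholds")
  list(matrix = count_matrix(mat$counts[, keep, drop = FALSE], mat$kind),
       report = report)
}

#' Subset a count matrix to given cells
#' @param mat a [count_matrix()]
#' @param cells cell ids to keep
#' @return a [count_matrix()]
#' @export
subset_cells <- function(mat, cells) {
  count_matrix(mat$counts[, colnames(mat$counts) %in% cells, drop = FALSE],
               mat$kind)
}

#' Score cells for doublets with a simulated-doublet kNN classifier
#'
#' Simulates `sim_doublet_ratio * n` synthetic doublets by summing the counts
#' of random observed cell pairs, filters and selects variable genes, embeds
#' observed and simulated cells in `n_pc` principal components (PCA fit on
#' observed cells, simulated cells projected), builds a kNN graph over the
#' union, and converts each observed cell's simulated-neighbor fraction `q`
#' into a doublet score.
#'
#' Calibration: with simulated:observed ratio `r` and prior doublet rate
#' `rho`, the neighbour fraction estimates the local density ratio
#' `f_d/f_s = q (1 - rho) / (r (1 - q) - q rho)`; the score is the posterior
#' `rho (f_d/f_s) / ((1 - rho) + rho (f_d/f_s))`, clipped to [0, 1] and
#' monotone in `q`.
#'
#' @param mat a gene-level [count_matrix()] (post cell filtering)
#' @param config a [qc_config()]
#' @return data.table with `cell_id`, `doublet_score`, `is_doublet_call`
#' @export
doublet_scores <- function(mat, config = qc_config()) {
  stopifnot(inherits(mat, "count_matrix"))
  counts <- mat$counts
  n <- ncol(counts)
  if (n < 2L * config$n_neighbors) stopf("too few cells for doublet scoring")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  n_sim <- round(config$sim_doublet_ratio * n)
  pair1 <- sample.int(n, n_sim, replace = TRUE)
  pair2 <- sample.int(n, n_sim, replace = TRUE)
  sim <- counts[, pair1, drop = FALSE] + counts[, pair2, drop = FALSE]

  # gene filter on observed cells
  keep_g <- Matrix::rowSums(counts >= config$min_count) >= config$min_cells
  obs_f <- counts[keep_g, , drop = FALSE]
  sim_f <- sim[keep_g, , drop = FALSE]

  norm <- function(m) {
    tot <- pmax(1, Matrix::colSums(m))
    log1p(Matrix::t(Matrix::t(m) / tot) * 1e4)
  }
  obs_n <- norm(obs_f); sim_n <- norm(sim_f)

  # variable genes: dispersion (variance/mean of normalised counts) above the
  # configured percentile
  mu <- Matrix::rowMeans(obs_n)
  v <- Matrix::rowMeans(obs_n^2) - mu^2
  disp <- ifelse(mu > 0, v / mu, 0)
  thr <- quantile(disp, config$vscore_percentile / 100)
  vg <- which(disp >= thr)
  obs_v <- as.matrix(obs_n[vg, , drop = FALSE])
  sim_v <- as.matrix(sim_n[vg, , drop = FALSE])

  # z-scale by observed-cell statistics, PCA on observed, project simulated
  gm <- rowMeans(obs_v)
  gs <- apply(obs_v, 1, sd); gs[gs == 0] <- 1
  obs_z <- t((obs_v - gm) / gs)
  sim_z <- t((sim_v - gm) / gs)
  n_pc <- min(config$n_pc, ncol(obs_z) - 1L, nrow(obs_z) - 1L)
  pc <- prcomp(obs_z, center = FALSE, scale. = FALSE, rank. = n_pc)
  emb <- rbind(pc$x, sim_z %*% pc$rotation)

  k <- config$n_neighbors
  nn <- suppressWarnings(BiocNeighbors::findKNN(emb, k = k))$index
  is_sim <- c(rep(FALSE, n), rep(TRUE, n_sim))
  q <- rowMeans(matrix(is_sim[nn], nrow = nrow(nn)))[seq_len(n)]

  r <- n_sim / n
  rho <- config$expected_doublet_rate
  ratio <- q * (1 - rho) / pmax(r * (1 - q) - q * rho, 1e-8)
  score <- rho * ratio / ((1 - rho) + rho * ratio)
  score <- pmin(pmax(score, 0), 1)
  data.table(cell_id = colnames(counts), doublet_score = score,
             is_doublet_call = score > config$doublet_threshold)
}
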