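#' PCA embedding utility
#'
#' Log-CPM PCA for synthetic tests and demos, so no external embedding tool
#' is required; any 2-D embedding can be supplied to the neighborhood
#' functions instead.
#'
#' @param mat a gene-level [count_matrix()]
#' @param n_pc number of components (default 2)
#' @return matrix cells x n_pc with cell ids as rownames
#' @export
pca_embed <- function(mat, n_pc = 2L) {
  cp <- log1p(cpm(mat))
  x <- t(as.matrix(cp))
  x <- scale(x, center = TRUE, scale = FALSE)
  n_pc <- min(n_pc, ncol(x) - 1L, nrow(x) - 1L)
  pc <- prcomp(x, center = FALSE, rank. = n_pc)
  emb <- pc$x
  rownames(emb) <- colnames(cp)
  emb
}

# exact kNN (indices exclude self)
knn_index <- function(emb, k) {
  nn <- suppressWarnings(BiocNeighbors::findKNN(emb, k = k))
  nn$index
}

#' Build cell neighborhoods on an embedding
#'
#' Constructs the exact Euclidean kNN graph, samples index cells at the given
#' fraction (seeded), and defines each neighborhood as the index cell plus
#' its k nearest neighbors.
#'
#' @param embedding numeric matrix (cells x dims) with cell ids as rownames
#' @param k neighbors per cell (default 60)
#' @param sample_fraction fraction of cells used as neighborhood index cells
#' @param seed seed for index-cell sampling
#' @return object of class `nhood_set`: embedding, `index_cells`, `members`
#'   (list of integer vectors including the index cell), `k`
#' @export
build_neighborhoods <- function(embedding, k = 60L, sample_fraction = 0.1,
                                seed = 1L) {
  n <- nrow(embedding)
  if (k >= n) stopf("k must be smaller than the number of cells")
  if (is.null(rownames(embedding))) rownames(embedding) <- as.character(seq_len(n))
  nn <- knn_index(embedding, k)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- sort(sample.int(n, max(1L, round(sample_fraction * n))))
  members <- lapply(idx, function(i) c(i, nn[i, ]))
  structure(list(embedding = embedding, index_cells = idx, members = members,
                 k = as.integer(k), knn = nn), class = "nhood_set")
}

#' @export
print.nhood_set <- function(x, ...) {
  cat(sprintf("nhood_set: %d neighborhoods of size %d over %d cells\n",
              length(x$members), x$k + 1L, nrow(x$embedding)))
  invisible(x)
}

#' Test neighborhoods for differential abundance between conditions
#'
#' Counts cells per sample within each neighborhood and fits the
#' negative-binomial likelihood-ratio test ([nb_lrt()]) on the sample counts
#' with log(sample total) offsets; BH correction across neighborhoods.
#' The log fold change is reported on the log2 scale, second condition over
#' first.
#'
#' @param nhoods a [build_neighborhoods()] object
#' @param cell_samples named vector mapping cell id to sample id
#' @param design data.table mapping `sample_id` to `condition`
#' @param config a [de_config()] (dispersion floor, pseudocount)
#' @return data.table: nhood, index_cell, n_members, per-sample counts,
#'   log2fc, p_value, fdr
#' @export
test_neighborhood_abundance <- function(nhoods, cell_samples, design,
                                        config = de_config()) {
  design <- as.data.table(design)
  cells <- rownames(nhoods$embedding)
  samp <- align_labels(cell_samples, cells)
  sample_ids <- design$sample_id
  if (length(unique(design$condition)) != 2L) stopf("exactly two conditions required")
  tot <- table(factor(samp, levels = sample_ids))
  empty <- sample_ids[tot == 0]
  if (length(empty)) {
    warnf("samples with zero cells excluded: %s", paste(empty, collapse = ", "))
    design <- design[!sample_id %in% empty]
    sample_ids <- design$sample_id
    tot <- tot[sample_ids]
  }
  if (any(table(design$condition) < 2L)) stopf("need >= 2 samples per condition")
  cond <- factor(design$condition, levels = unique(design$condition))
  counts <- t(vapply(nhoods$members, function(m)
    as.integer(table(factor(samp[m], levels = sample_ids))),
    integer(length(sample_ids))))
  colnames(counts) <- sample_ids
  res <- lapply(seq_len(nrow(counts)), function(i)
    nb_lrt(counts[i, ], cond, as.numeric(tot), config))
  out <- data.table(nhood = seq_along(nhoods$members),
                    index_cell = cells[nhoods$index_cells],
                    n_members = lengths(nhoods$members))
  out <- cbind(out, as.data.table(counts))
  out[, log2fc := vapply(res, `[[`, numeric(1), "log2fc")]
  out[, p_value := vapply(res, `[[`, numeric(1), "p_value")]
  out[, fdr := p.adjust(p_value, method = "BH")]
  out[]
}

#' Expand neighborhoods by a fixed radius and label by age-group proportion
#'
#' Each neighborhood's membership is expanded to the union of its original
#' members and all cells within `radius` of its index cell's 2-D coordinates.
#' Young/aged proportions are computed on the expanded membership (raw cell
#' counts) and a neighborhood is labeled `<condition>-enriched` only when
#' that condition's proportion strictly exceeds the threshold (default
#' 0.705, so 0.8 is labeled and 0.7 is not).
#'
#' @param nhoods a [build_neighborhoods()] object with a 2-D embedding (only
#'   the first two dimensions are used)
#' @param cell_conditions named vector mapping cell id to condition
#' @param radius expansion radius in embedding units; default is the median
#'   distance from index cells to their k-th neighbor
#' @param threshold strict proportion bound for labeling (default 0.705)
#' @return data.table: nhood, index_cell, expanded size, per-condition
#'   proportions, label (`<cond>-enriched` or NA), plus index-cell
#'   coordinates for density plotting
#' @export
expand_and_label <- function(nhoods, cell_conditions, radius = NULL,
                             threshold = 0.705) {
  emb <- nhoods$embedding[, 1:2, drop = FALSE]
  cells <- rownames(emb)
  cond <- align_labels(cell_conditions, cells)
  lev <- sort(unique(cond))
  if (length(lev) != 2L) stopf("exactly two conditions required")
  if (is.null(radius)) {
    kd <- vapply(seq_along(nhoods$index_cells), function(j) {
      i <- nhoods$index_cells[j]
      sqrt(max(colSums((t(emb[nhoods$members[[j]], , drop = FALSE]) - emb[i, ])^2)))
    }, numeric(1))
    radius <- median(kd)
  }
  if (radius <= 0) stopf("radius must be positive")
  out <- rbindlist(lapply(seq_along(nhoods$index_cells), function(j) {
    i <- nhoods$index_cells[j]
    d2 <- colSums((t(emb) - emb[i, ])^2)
    expanded <- union(nhoods$members[[j]], which(d2 <= radius^2))
    p <- prop.table(table(factor(cond[expanded], levels = lev)))
    lab <- if (p[1] > threshold) paste0(lev[1], "-enriched")
           else if (p[2] > threshold) paste0(lev[2], "-enriched")
           else NA_character_
    data.table(nhood = j, index_cell = cells[i], n_expanded = length(expanded),
               prop_1 = as.numeric(p[1]), prop_2 = as.numeric(p[2]),
               label = lab, x = emb[i, 1], y = emb[i, 2])
  }))
  setnames(out, c("prop_1", "prop_2"), paste0("prop_", lev))
  attr(out, "radius") <- radius
  out[]
}
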