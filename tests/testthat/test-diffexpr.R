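simple_mat <- function(m, kind = "gene") {
  count_matrix(Matrix::Matrix(m, sparse = TRUE), kind)
}

test_that("CPM normalisation is exact and condition means respect symmetry", {
  m <- matrix(c(1, 999, 500, 500), nrow = 2,
              dimnames = list(c("gA", "gB"), c("c1", "c2")))
  cp <- cpm(simple_mat(m))
  expect_equal(cp["gA", "c1"], 1000)          # 1 of 1,000 -> 1,000 CPM
  expect_equal(unname(Matrix::colSums(cp)), c(1e6, 1e6))
  # all-equal cells: condition means equal each cell's CPM
  m2 <- matrix(rep(c(30, 70), 6), nrow = 2,
               dimnames = list(c("gA", "gB"), paste0("c", 1:6)))
  cm <- condition_mean_cpm(simple_mat(m2), rep(c("x", "y"), each = 3))
  expect_equal(unname(cm[, "x"]), unname(cm[, "y"]))
  expect_equal(unname(cm["gA", "x"]), 3e5)
  # zero-total cells are excluded with a warning
  m3 <- cbind(m, c3 = c(0, 0))
  expect_warning(cp3 <- cpm(simple_mat(m3)), "zero-total")
  expect_equal(ncol(cp3), 2L)
})

test_that("nb_lrt returns p ~ 1 for identical groups and respects level order", {
  y <- rep(c(5L, 8L, 2L, 9L), 10)
  sf <- rep(1000, 40)
  lab <- factor(rep(c("young", "aged"), each = 20), levels = c("young", "aged"))
  # identical count pattern in both groups
  res <- nb_lrt(rep(y[1:20], 2), lab, sf)
  expect_gt(res$p_value, 0.9)
  expect_equal(res$log2fc, 0)
  # all-zero feature
  res0 <- nb_lrt(rep(0L, 40), lab, sf)
  expect_equal(res0$p_value, 1)
  expect_equal(res0$log2fc, 0)
  # level order defines the fold-change direction: aged doubled -> positive
  y2 <- c(rep(5L, 20), rep(10L, 20))
  res2 <- nb_lrt(y2, lab, sf)
  expect_gt(res2$log2fc, 0)
  rev_lab <- factor(as.character(lab), levels = c("aged", "young"))
  expect_lt(nb_lrt(y2, rev_lab, sf)$log2fc, 0)
  expect_error(nb_lrt(y2, factor(rep("a", 40)), sf), "two conditions")
})

test_that("nb_lrt recovers a simulated twofold change", {
  set.seed(21)
  n <- 200
  lab <- factor(rep(c("young", "aged"), each = n), levels = c("young", "aged"))
  sf <- rep(1000, 2 * n)
  est <- replicate(40, {
    y <- c(rnbinom(n, mu = 10, size = 2), rnbinom(n, mu = 20, size = 2))
    nb_lrt(y, lab, sf)$log2fc
  })
  expect_lt(abs(mean(est) - 1), 0.15)
})

test_that("combined BH equals the sort-and-scan oracle and exon-only input degenerates", {
  set.seed(8)
  n_cells <- 60
  lab <- rep(c("young", "aged"), each = n_cells / 2)
  gm <- matrix(rnbinom(20 * n_cells, mu = 10, size = 2), nrow = 20,
               dimnames = list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:n_cells)))
  em <- matrix(rnbinom(30 * n_cells, mu = 5, size = 2), nrow = 30,
               dimnames = list(sprintf("g%02d:%d", rep(1:10, 3), rep(1:3, each = 10)),
                               sprintf("c%02d", 1:n_cells)))
  tab <- run_combined_de(simple_mat(gm), simple_mat(em, "exon"), lab)
  expect_equal(tab$fdr, bh_oracle(tab$p_value), tolerance = 1e-12)
  expect_true(all(tab$fdr >= tab$p_value - 1e-12))
  # exon-only run equals exon-wise testing with BH over exons alone
  tab_e <- run_combined_de(NULL, simple_mat(em, "exon"), lab)
  expect_equal(nrow(tab_e), 30L)
  expect_equal(tab_e$fdr, bh_oracle(tab_e$p_value), tolerance = 1e-12)
  # mismatched cells error
  expect_error(run_combined_de(simple_mat(gm),
                               simple_mat(em[, 1:10], "exon"), lab),
               "share the same cells")
})

test_that("permuted labels produce essentially no calls", {
  study <- small_study()
  mats <- build_matrices(study$molecules)
  cells <- study$cells
  sel <- cells[is_doublet == FALSE, cell_id]
  gm <- subset_cells(mats$gene, sel)
  set.seed(14)
  perm_lab <- sample(rep(c("young", "aged"), length.out = ncol(gm$counts)))
  tab <- call_and_classify(run_combined_de(gm, NULL, perm_lab), de_config())
  expect_lte(sum(tab$is_deg), 1L)
})

test_that("DEG/DEE calling implements the CPM re-filter classification rule", {
  mk_row <- function(id, kind, parent, fdr, l2fc, cpm_max) data.table::data.table(
    feature_id = id, kind = kind, parent_gene = parent, p_value = fdr / 2,
    log2fc = l2fc, mean_cpm_young = cpm_max, mean_cpm_aged = cpm_max,
    poisson_fallback = FALSE, max_cpm = cpm_max, fdr = fdr)
  tab <- rbind(
    mk_row("gHi",  "gene", "gHi",  0.01, 1.0, 40),   # clean DEG
    mk_row("gMid", "gene", "gMid", 0.01, 0.8, 12),   # passes only at exon cutoff
    mk_row("gNull","gene", "gNull",0.20, 1.2, 40),   # fails FDR
    mk_row("gLow", "gene", "gLow", 0.01, 1.0, 5),    # below both CPM cutoffs
    mk_row("gHi:1",  "exon", "gHi",  0.01, 1.2, 15),
    mk_row("gMid:1", "exon", "gMid", 0.01, -1.0, 15),
    mk_row("gNull:1","exon", "gNull",0.01, 1.0, 15),
    mk_row("gLow:1", "exon", "gLow", 0.01, 1.0, 15),
    mk_row("gHi:2",  "exon", "gHi",  0.50, 1.0, 15), # fails FDR -> not a DEE
    mk_row("gHi:3",  "exon", "gHi",  0.01, 0.2, 15)) # fails FC -> not a DEE
  res <- call_and_classify(tab, de_config())
  flags <- setNames(res$is_deg, res$feature_id)
  expect_true(flags[["gHi"]])
  expect_false(flags[["gMid"]])   # max CPM 12 < 25
  expect_false(flags[["gNull"]])
  expect_false(flags[["gLow"]])
  dee <- setNames(res$dee_class, res$feature_id)
  expect_identical(dee[["gHi:1"]], "DEG-derived")
  # the key subtlety: parent passes at CPM>10 though it is NOT a DEG (CPM<=25)
  expect_identical(dee[["gMid:1"]], "DEG-derived")
  expect_identical(dee[["gNull:1"]], "non-DEG-derived")
  expect_identical(dee[["gLow:1"]], "non-DEG-derived")
  expect_true(is.na(dee[["gHi:2"]]))
  expect_true(is.na(dee[["gHi:3"]]))
  # no DEE flag outside exons, none below FDR
  expect_true(all(res[is_dee == TRUE, kind] == "exon"))
  # orphan exon errors
  orphan <- rbind(tab, mk_row("gX:1", "exon", "gX", 0.01, 1, 15))
  expect_error(call_and_classify(orphan, de_config()), "no parent gene")
})

test_that("shared fold-change correlation matches the analytic oracle", {
  mk <- function(ids, l2fc, flag = TRUE) data.table::data.table(
    feature_id = ids, kind = "gene", log2fc = l2fc, is_deg = flag,
    is_dee = FALSE)
  ids <- sprintf("g%02d", 1:100)
  set.seed(31)
  a <- rnorm(100); b <- 0.8 * a + rnorm(100, sd = 0.3)
  res <- shared_logfc_correlation(mk(ids, a), mk(ids, b), "is_deg")
  want <- cor.test(a, b)
  expect_equal(res$r, unname(want$estimate), tolerance = 1e-10)
  expect_equal(res$p_value, want$p.value, tolerance = 1e-10)
  expect_equal(res$n_shared, 100L)
  # identity and negation
  expect_equal(shared_logfc_correlation(mk(ids, a), mk(ids, a), "is_deg")$r, 1)
  expect_equal(shared_logfc_correlation(mk(ids, a), mk(ids, -a), "is_deg")$r, -1)
  # too few shared features
  expect_true(is.na(shared_logfc_correlation(mk(ids[1:2], a[1:2]),
                                             mk(ids[1:2], b[1:2]), "is_deg")$r))
})
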