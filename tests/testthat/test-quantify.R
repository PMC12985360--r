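# assignment fixture: three plus-strand genes on chr2
#   up1: 1,000-2,000 (3' end 2,000)
#   up2: 10,000-12,000
#   ov1: 20,000-25,000 and ov2: 24,000-30,000 overlap in 24,000-25,000
#   anti: minus strand 40,000-41,000
assign_fixture_db <- function() {
  g <- data.table::data.table(
    gene_id = c("up1", "up2", "ov1", "ov2", "anti"),
    chrom = "chr2",
    start = c(1000L, 10000L, 20000L, 24000L, 40000L),
    end = c(2000L, 12000L, 25000L, 30000L, 41000L),
    strand = c("+", "+", "+", "+", "-"))
  ex <- data.table::data.table(
    transcript_id = paste0("t_", g$gene_id), gene_id = g$gene_id,
    chrom = "chr2", start = g$start, end = g$end, strand = g$strand)
  annotation_db(g, data.table::data.table(transcript_id = ex$transcript_id,
                                          gene_id = ex$gene_id),
                ex, ex[0])
}

test_that("gene assignment branches: direct, 3'-proximity, upstream boundary, antisense", {
  idx <- build_feature_index(assign_fixture_db())

  # direct: molecule inside exactly one gene
  r <- assign_gene(mk_mol("chr2", 1500, 1559, "+"), idx)
  expect_equal(r$gene_id, "up1")
  expect_equal(r$assign_class, "direct")

  # ambiguous dT molecule in the ov1/ov2 overlap: 3' end of ov1 (25,000) is
  # 500 bp from the molecule's 3'-most base; ov2's (30,000) is 5,500 bp away
  r <- assign_gene(mk_mol("chr2", 24441, 24500, "+", "dT"), idx)
  expect_equal(r$gene_id, "ov1")
  expect_equal(r$assign_class, "direct-3p")

  # the same molecule hexamer-primed is discarded by default
  r <- assign_gene(mk_mol("chr2", 24441, 24500, "+", "hexamer"), idx)
  expect_true(is.na(r$gene_id))
  expect_equal(r$assign_class, "ambiguous")
  # ... unless the closest-3' rule is extended to hexamer molecules
  r <- assign_gene(mk_mol("chr2", 24441, 24500, "+", "hexamer"), idx,
                   assign_config(ambiguous_hexamer = "closest3p"))
  expect_equal(r$gene_id, "ov1")

  # upstream rescue boundary: gene up2 starts at 10,000; a molecule ending
  # at 9,000 sits exactly 1,000 bp upstream and is rescued; 8,999 is not
  r <- assign_gene(mk_mol("chr2", 8941, 9000, "+"), idx)
  expect_equal(r$gene_id, "up2")
  expect_equal(r$assign_class, "upstream-rescued")
  r <- assign_gene(mk_mol("chr2", 8940, 8999, "+"), idx)
  expect_true(is.na(r$gene_id))
  expect_equal(r$assign_class, "unassigned")

  # antisense rescue: plus-strand molecule inside the minus-strand gene
  r <- assign_gene(mk_mol("chr2", 40500, 40559, "+"), idx)
  expect_equal(r$gene_id, "anti")
  expect_equal(r$assign_class, "antisense-rescued")
  r <- assign_gene(mk_mol("chr2", 40500, 40559, "+"), idx,
                   assign_config(antisense_rescue = FALSE))
  expect_true(is.na(r$gene_id))

  # intergenic molecule with no rescue available
  r <- assign_gene(mk_mol("chr2", 5000, 5059, "+"), idx)
  expect_true(is.na(r$gene_id))
})

test_that("with rescue disabled and disjoint genes, assignment equals naive overlap", {
  study <- small_study()
  idx <- build_feature_index(study$annotation$db)
  set.seed(3)
  mol <- study$molecules[sample(.N, 2000)]
  res <- assign_gene(mol, idx, assign_config(upstream_window = 0L,
                                             antisense_rescue = FALSE))
  genes <- study$annotation$db$genes
  naive <- vapply(seq_len(nrow(mol)), function(i) {
    hit <- brute_overlaps(genes, mol$chrom[i], mol$start[i], mol$end[i],
                          mol$strand[i])
    if (nrow(hit) == 1L) hit$gene_id else NA_character_
  }, character(1))
  # simulated genes are disjoint, so every direct hit is unique
  expect_identical(res$gene_id[res$assign_class == "direct"],
                   naive[res$assign_class == "direct"])
  expect_identical(res$gene_id, naive)
})

test_that("exon assignment resolves boundary molecules by overlap length", {
  db <- tiny_db()
  idx <- build_feature_index(db)
  # geneA exons: 101-300, 501-700; a 60-base molecule with 40 bases in the
  # first exon and 20 in the intron
  mol <- mk_mol("chr1", 261, 320, "+")
  r <- assign_exon(assign_gene(mol, idx), idx)
  expect_equal(r$exon_id, "geneA:1")
  # fully intronic molecule
  mol <- mk_mol("chr1", 350, 409, "+")
  r <- assign_exon(assign_gene(mol, idx), idx)
  expect_equal(r$gene_id, "geneA")
  expect_true(is.na(r$exon_id))
  # straddling two exons: 10 bases in exon 1 (291..300), 50 in the gap, then
  # exon 2 wins when the molecule covers more of it
  mol <- mk_mol("chr1", 291, 540, "+")  # 10 bases exon1, 40 bases exon2
  r <- assign_exon(assign_gene(mol, idx), idx)
  expect_equal(r$exon_id, "geneA:2")
})

test_that("count matrices conserve molecules and respect the exon bound", {
  # 1 cell, 3 molecules in one gene: 2 exonic, 1 intronic
  mol <- data.table::data.table(
    cell_id = "c1", molecule_id = 1:3, gene_id = "gA",
    exon_id = c("gA:1", "gA:1", NA))
  m <- build_matrices(mol)
  expect_equal(sum(m$gene$counts), 3)
  expect_equal(sum(m$exon$counts), 2)
  expect_equal(m$gene$cell_totals[["c1"]], 3)

  # empty input yields valid 0x0 matrices
  m0 <- build_matrices(mol[0])
  expect_equal(dim(m0$gene$counts), c(0L, 0L))

  # duplicated (cell, molecule) pairs violate the dedup contract
  expect_error(build_matrices(rbind(mol, mol[1])), "duplicate")

  # synthetic run: gene matrix grand total equals the assigned molecule count
  study <- small_study()
  mm <- build_matrices(study$molecules)
  expect_equal(sum(mm$gene$counts), nrow(study$molecules))
  expect_equal(sum(mm$exon$counts), study$molecules[!is.na(exon_id), .N])
  # per-gene exon totals never exceed gene totals
  gsum <- Matrix::rowSums(mm$gene$counts)
  esum <- tapply(Matrix::rowSums(mm$exon$counts), mm$exon$parent_gene, sum)
  expect_true(all(esum <= gsum[names(esum)] + 1e-9))
})

test_that("intronic fraction test matches a direct t-test oracle", {
  mk <- function(sample, n_int, n_ex) data.table::data.table(
    gene_id = "g", sample_id = sample,
    exon_id = c(rep(NA_character_, n_int), rep("g:1", n_ex)))
  design <- data.table::data.table(
    sample_id = c("y1", "y2", "y3", "a1", "a2", "a3"),
    condition = rep(c("young", "aged"), each = 3))

  # replicate with 3 intronic of 4 total -> fraction 0.75
  mol <- mk("y1", 3, 1)
  res <- intronic_fraction_test(mol, "g", design[sample_id == "y1"])
  expect_equal(res$per_replicate$intron_fraction, 0.75)

  # (0.96, 0.95, 0.97) vs (0.77, 0.78, 0.76) out of 100 molecules each
  mol <- rbind(mk("y1", 96, 4), mk("y2", 95, 5), mk("y3", 97, 3),
               mk("a1", 77, 23), mk("a2", 78, 22), mk("a3", 76, 24))
  res <- intronic_fraction_test(mol, "g", design)
  want <- t.test(c(0.96, 0.95, 0.97), c(0.77, 0.78, 0.76))$p.value
  expect_equal(res$p_value, want, tolerance = 1e-12)
  expect_lt(res$p_value, 0.001)

  # identical groups -> p = 1
  mol <- rbind(mk("y1", 50, 50), mk("y2", 50, 50), mk("a1", 50, 50),
               mk("a2", 50, 50))
  res <- intronic_fraction_test(mol, "g", design[sample_id %in%
                                                   c("y1", "y2", "a1", "a2")])
  expect_equal(res$p_value, 1)

  # a replicate with zero molecules is excluded with a warning
  expect_warning(
    res <- intronic_fraction_test(rbind(mk("y1", 1, 1), mk("a1", 1, 1),
                                        mk("a2", 1, 1)), "g", design),
    "excluded")
  expect_true(is.na(res$p_value))
})
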