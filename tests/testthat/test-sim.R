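test_that("configuration validation enforces the documented invariants", {
  expect_error(sim_config(doublet_rate = 1.2), "fractions")
  expect_error(sim_config(exon_length = c(-5L, 10L)), "positive")
  expect_error(sim_config(umi_duplication_rate = 0.5), ">= 1")
  expect_error(sim_config(subtype_props = list(
    young = c(OPC = 0.5, MFOL = 0.2, MOL2 = 0.2, MOL56 = 0.2),
    aged = c(OPC = 0.25, MFOL = 0.25, MOL2 = 0.25, MOL56 = 0.25))),
    "sum to 1")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("annotation generation is deterministic and structurally sound", {
  cfg <- sim_config(n_genes = 50L, seed = 7L)
  ann <- generate_annotation(cfg)
  db <- ann$db

  # identical seeds give byte-identical GTF files
  t1 <- withr::local_tempfile(fileext = ".gtf")
  t2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(db, t1)
  write_gtf(generate_annotation(cfg)$db, t2)
  expect_identical(readLines(t1), readLines(t2))
  # and a different seed differs
  t3 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(generate_annotation(sim_config(n_genes = 50L, seed = 8L))$db, t3)
  expect_false(identical(readLines(t1), readLines(t3)))

  # every gene has >= 1 transcript; every CDS length is divisible by 3
  expect_true(all(db$genes$gene_id %in% db$transcripts$gene_id))
  cds_len <- db$cds[, .(len = sum(end - start + 1L)), by = transcript_id]
  expect_true(all(cds_len$len %% 3L == 0L))
  expect_true(all(db$transcripts$coding))
  # exons within a transcript are disjoint and sorted
  for (tid in db$transcripts$transcript_id) {
    e <- db$exons_tx[transcript_id == tid][order(start)]
    if (nrow(e) > 1) expect_true(all(e$start[-1] > e$end[-nrow(e)]))
  }
  # CDS is a subset of exonic bases
  for (tid in sample(db$transcripts$transcript_id, 10)) {
    e <- db$exons_tx[transcript_id == tid]
    cc <- db$cds[transcript_id == tid]
    covered <- unlist(Map(seq, e$start, e$end))
    cds_bases <- unlist(Map(seq, cc$start, cc$end))
    expect_true(all(cds_bases %in% covered))
  }
  # both strands represented; domains stay inside the protein
  expect_setequal(unique(db$genes$strand), c("+", "-"))
  doms <- merge(ann$domains, cds_len, by = "transcript_id")
  expect_true(all(doms$aa_start >= 1 & doms$aa_end <= doms$len / 3))
  # transcript sequences have the spliced length
  tx_len <- db$exons_tx[, .(len = sum(end - start + 1L)), by = transcript_id]
  expect_equal(unname(Biostrings::width(ann$transcript_seqs)[
    match(tx_len$transcript_id, names(ann$transcript_seqs))]), tx_len$len)
  # 1 gene, 1 exon of 300 bp with a full-exon CDS gives a 100-aa protein
  expect_equal(300L / 3L, 100L)
})

test_that("population generation matches the replicate design and doublet rate", {
  cfg <- sim_config(n_genes = 50L, n_cells_per_replicate = 500L, seed = 7L)
  ann <- generate_annotation(cfg)
  pop <- generate_cell_population(cfg, ann)
  cells <- pop$cells
  # 2 conditions x 3 replicates x 500 cells
  expect_equal(nrow(cells), 3000L)
  expect_equal(as.integer(table(cells$condition)), c(1500L, 1500L))
  expect_equal(length(unique(cells$sample_id)), 6L)
  # every cell appears exactly once
  expect_false(anyDuplicated(cells$cell_id) > 0)
  # doublet count within the binomial 99% interval around 180
  n_doub <- sum(cells$is_doublet)
  bounds <- qbinom(c(0.005, 0.995), 3000L, 0.06)
  expect_gte(n_doub, bounds[1])
  expect_lte(n_doub, bounds[2])
  # doublet_rate 0 -> none flagged
  cfg0 <- sim_config(n_genes = 50L, n_cells_per_replicate = 50L,
                     doublet_rate = 0, seed = 7L)
  pop0 <- generate_cell_population(cfg0, generate_annotation(cfg0))
  expect_equal(sum(pop0$cells$is_doublet), 0L)
})

test_that("ground truth is internally consistent with the drawn effects", {
  study <- small_study()
  truth <- study$truth
  # DEG truth flags exactly the genes with nonzero drawn effect
  expect_identical(truth$genes$is_deg_true, truth$genes$true_log2fc != 0)
  # opposed exons exist and have the opposite sign of their parent gene
  opp <- truth$exons[opposed == TRUE]
  expect_gt(nrow(opp), 0L)
  pg <- truth$genes$true_log2fc[match(opp$gene_id, truth$genes$gene_id)]
  expect_true(all(sign(opp$exon_log2fc) != sign(pg)))
  # per-gene exon usage sums to 1 in both conditions
  us <- truth$exons[, .(y = sum(usage_young), a = sum(usage_aged)), by = gene_id]
  expect_equal(us$y, rep(1, nrow(us)), tolerance = 1e-9)
  expect_equal(us$a, rep(1, nrow(us)), tolerance = 1e-9)
  # zero DE fraction -> no truth DEGs (beyond the forced splice-shift and
  # splicing-factor genes, disabled here too)
  cfg0 <- sim_config(n_genes = 40L, n_cells_per_replicate = 30L,
                     gene_de_fraction = 0, n_splice_shift_genes = 0L,
                     n_splicing_factors = 0L, seed = 3L)
  pop0 <- generate_cell_population(cfg0, generate_annotation(cfg0))
  expect_equal(sum(pop0$truth$genes$is_deg_true), 0L)
})

test_that("read simulation respects duplication, error and intron settings", {
  # umi_duplication_rate 1 -> reads equal molecules; error rate 0 -> all
  # barcodes on the whitelist
  cfg <- sim_config(n_genes = 30L, n_cells_per_replicate = 30L,
                    umi_duplication_rate = 1, barcode_error_rate = 0,
                    seed = 13L)
  ann <- generate_annotation(cfg)
  pop <- generate_cell_population(cfg, ann)
  rd <- simulate_reads(pop, ann, cfg)
  expect_equal(nrow(rd$reads), nrow(rd$molecules))
  wl_rt <- barcode_whitelist(96, 10, "rt")
  wl_lig <- barcode_whitelist(96, 10, "ligation")
  expect_true(all(rd$reads$rt_bc %in% wl_rt))
  expect_true(all(rd$reads$lig_bc %in% wl_lig))

  # intron fraction recovery: per-gene empirical intron share within the
  # 99% binomial interval of its configured truth (conditions pooled by
  # construction where fractions are equal)
  study <- small_study()
  truth <- study$truth$genes
  stable <- truth[is_splice_shift == FALSE]
  mol <- study$molecules
  emp <- mol[, .(n = .N, n_int = sum(is.na(exon_id))), by = .(gene_id, condition)]
  emp <- merge(emp, truth[, .(gene_id, intron_fraction_young,
                              intron_fraction_aged, is_splice_shift)],
               by = "gene_id")
  emp[, p_true := ifelse(condition == "young", intron_fraction_young,
                         intron_fraction_aged)]
  emp[, lo := qbinom(0.005, n, p_true) / n]
  emp[, hi := qbinom(0.995, n, p_true) / n]
  frac_ok <- emp[n >= 50, mean(n_int / n >= lo & n_int / n <= hi)]
  expect_gt(frac_ok, 0.95)

  # splice-shift genes flip between the configured condition fractions
  shift <- emp[is_splice_shift == TRUE]
  expect_true(all(abs(shift[condition == "young", n_int / n] - 0.961) < 0.05))
  expect_true(all(abs(shift[condition == "aged", n_int / n] - 0.771) < 0.05))
})

test_that("simulated counts are NB-like (variance >= mean) and seeds reproduce", {
  study <- small_study()
  mats <- build_matrices(study$molecules)
  cells <- study$cells
  sel <- cells[subtype == "MOL56" & condition == "young" & is_doublet == FALSE,
               cell_id]
  m <- as.matrix(subset_cells(mats$gene, sel)$counts)
  mu <- rowMeans(m); v <- apply(m, 1, var)
  hi <- mu > 1
  expect_gt(mean(v[hi] > mu[hi]), 0.95)

  # identical seeds -> byte-identical truth TSVs
  cfg <- sim_config(n_genes = 25L, n_cells_per_replicate = 25L, seed = 21L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- emit_truth(simulate_study(cfg), d1)
  p2 <- emit_truth(simulate_study(cfg), d2)
  for (k in names(p1))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]),
                     info = k)
})
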