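test_that("GTF coordinates are 1-based inclusive and round-trip through write/parse", {
  study <- small_study()
  db <- study$annotation$db

  # a single exon written as start 101, end 200 spans 100 bases
  ex1 <- data.table::data.table(transcript_id = "t1", gene_id = "g1",
                                chrom = "chr1", start = 101L, end = 200L,
                                strand = "+")
  db1 <- annotation_db(
    genes = data.table::data.table(gene_id = "g1", chrom = "chr1",
                                   start = 101L, end = 200L, strand = "+"),
    transcripts = data.table::data.table(transcript_id = "t1", gene_id = "g1"),
    exons_tx = ex1, cds = ex1[0])
  expect_equal(db1$exons$end - db1$exons$start + 1L, 100L)

  tmp <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(db, tmp)
  re <- parse_gtf(tmp)
  expect_equal(re$genes[order(gene_id), .(gene_id, chrom, start, end, strand)],
               db$genes[order(gene_id), .(gene_id, chrom, start, end, strand)])
  expect_equal(
    re$exons_tx[order(transcript_id, start), .(transcript_id, start, end)],
    db$exons_tx[order(transcript_id, start), .(transcript_id, start, end)])
  expect_equal(re$cds[order(transcript_id, start), .(transcript_id, start, end)],
               db$cds[order(transcript_id, start), .(transcript_id, start, end)])
  # round trip twice is identity
  tmp2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(re, tmp2)
  expect_identical(parse_gtf(tmp2)$genes, re$genes)
})

test_that("a GTF with only a gene row parses to zero transcripts", {
  tmp <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "test", "gene", "100", "500", ".", "+", ".",
                   'gene_id "gX";', sep = "\t"), tmp)
  db <- parse_gtf(tmp)
  expect_equal(nrow(db$genes), 1L)
  expect_equal(nrow(db$transcripts), 0L)
  expect_equal(nrow(db$exons_tx), 0L)
})

test_that("parse_gtf errors on a missing file", {
  expect_error(parse_gtf("no/such/file.gtf"), "not found")
})

test_that("interval queries match a brute-force scan", {
  study <- small_study()
  db <- study$annotation$db
  idx <- build_feature_index(db)
  set.seed(42)
  chroms <- unique(db$genes$chrom)
  maxpos <- max(db$genes$end) + 2000L
  for (i in seq_len(300)) {
    chrom <- sample(chroms, 1)
    s <- sample.int(maxpos, 1)
    e <- s + sample.int(500, 1)
    strand <- sample(c("+", "-", "*"), 1)
    got <- sort(locate_overlaps(idx, chrom, s, e, strand, "genes")$gene_id)
    want <- sort(brute_overlaps(db$genes, chrom, s, e, strand)$gene_id)
    expect_identical(got, want)
    gote <- sort(locate_overlaps(idx, chrom, s, e, strand, "exons")$exon_id)
    wante <- sort(brute_overlaps(db$exons, chrom, s, e, strand)$exon_id)
    expect_identical(gote, wante)
  }
  # unknown chromosome and intergenic gap yield empty results
  expect_equal(nrow(locate_overlaps(idx, "chrZ", 1, 100)), 0L)
})

test_that("merged gene-level exons are disjoint and indexed in transcription order", {
  study <- small_study()
  ex <- study$annotation$db$exons
  for (g in unique(ex$gene_id)) {
    e <- ex[gene_id == g][order(start)]
    if (nrow(e) > 1L) expect_true(all(e$start[-1] > e$end[-nrow(e)]))
  }
  # minus-strand genes have exon 1 at the highest coordinates
  db <- study$annotation$db
  neg <- db$genes[strand == "-", gene_id]
  for (g in head(neg, 3)) {
    e <- ex[gene_id == g]
    first <- e[exon_id == paste0(g, ":1")]
    expect_equal(first$end, max(e$end))
  }
})

test_that("genomic_to_protein matches the worked fixtures", {
  db <- tiny_db()
  # tA CDS (+): 201-300 then 501-700; query inside first segment
  # offsets 10..24 within the CDS -> codons 4..9
  expect_equal(genomic_to_protein(db, "tA", 211, 225),
               c(aa_start = 4L, aa_end = 9L))
  # query across both CDS segments: bases 290-300 (offsets 89..99) plus
  # 501-520 (offsets 100..119) -> aa 30..40
  expect_equal(genomic_to_protein(db, "tA", 290, 520),
               c(aa_start = 30L, aa_end = 40L))
  # full CDS of tA (300 nt) covers exactly aa 1..100
  expect_equal(genomic_to_protein(db, "tA", 201, 700),
               c(aa_start = 1L, aa_end = 100L))
  # minus strand: first CDS segment in transcription order is 2501-2640
  expect_equal(genomic_to_protein(db, "tB", 2601, 2640),
               c(aa_start = 1L, aa_end = 14L))
  # UTR-only query maps to nothing
  expect_null(genomic_to_protein(db, "tA", 101, 150))
  # non-coding transcript errors
  expect_error(genomic_to_protein(db, "nope", 1, 10), "unknown transcript")
})

test_that("genomic_to_protein agrees with the per-base enumeration oracle", {
  study <- small_study()
  db <- study$annotation$db
  coding <- db$transcripts[coding == TRUE, transcript_id]
  set.seed(7)
  for (tid in head(coding, 50)) {
    seg <- db$cds[transcript_id == tid]
    lo <- min(seg$start) - 150L; hi <- max(seg$end) + 150L
    for (j in seq_len(10)) {
      s <- sample(lo:hi, 1); e <- s + sample.int(400, 1)
      got <- genomic_to_protein(db, tid, s, e)
      want <- aa_oracle(db, tid, s, e)
      expect_equal(got, want, info = sprintf("%s %d-%d", tid, s, e))
    }
  }
})

test_that("coordinate mapping is strand-symmetric", {
  # mirror tiny_db's geneA onto the minus strand at reflected coordinates
  # and check the same transcript-relative query maps to the same codons
  db <- tiny_db()
  L <- 3000L
  refl <- function(s, e) c(L - e + 1L, L - s + 1L)
  ex <- db$exons_tx[transcript_id == "tA"]
  cds <- db$cds[transcript_id == "tA"]
  flip <- function(dt) {
    out <- data.table::copy(dt)
    se <- t(mapply(refl, dt$start, dt$end))
    out$start <- as.integer(se[, 1]); out$end <- as.integer(se[, 2])
    out$strand <- "-"
    out
  }
  db2 <- annotation_db(
    genes = data.table::data.table(gene_id = "geneA", chrom = "chr1",
                                   start = L - 1000L + 1L, end = L - 101L + 1L,
                                   strand = "-"),
    transcripts = data.table::data.table(transcript_id = "tA", gene_id = "geneA"),
    exons_tx = flip(ex), cds = flip(cds))
  q <- refl(211L, 225L)
  expect_equal(genomic_to_protein(db2, "tA", q[1], q[2]),
               c(aa_start = 4L, aa_end = 9L))
})
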