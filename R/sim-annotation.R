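#' Generate a synthetic gene annotation, transcript sequences and domains
#'
#' Builds a multi-chromosome, both-strand annotation with non-overlapping
#' genes: each gene has 1-2 transcripts (a second, exon-skipping isoform for a
#' subset of multi-exon genes), exons separated by introns, a contiguous CDS
#' in transcript coordinates whose length is divisible by 3, and 0-3 protein
#' domains per coding transcript in amino-acid coordinates. Transcript
#' sequences are random DNA of the correct spliced length.
#'
#' @param cfg a [sim_config()]
#' @return list with `db` (an [annotation_db()]), `transcript_seqs`
#'   (named `DNAStringSet`), and `domains` (data.table: transcript_id,
#'   domain_name, aa_start, aa_end; 1-based inclusive)
#' @export
generate_annotation <- function(cfg) {
  validate_sim_config(cfg)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, "annotation"))

  n <- cfg$n_genes
  gene_ids <- sprintf("gene%04d", seq_len(n))
  chroms <- paste0("chr", 1:3)
  gene_chrom <- chroms[(seq_len(n) - 1L) %% 3L + 1L]
  gene_strand <- sample(c("+", "-"), n, replace = TRUE)

  exon_rows <- vector("list", n)
  cds_rows <- vector("list", n)
  tx_rows <- vector("list", n)
  dom_rows <- vector("list", n)
  seqs <- vector("list", n)
  cursor <- setNames(rep(1000L, length(chroms)), chroms)
  dom_pool <- c("protein kinase domain", "SH2 domain", "homeodomain",
                "lipocalin-like domain", "RRM domain", "zinc finger C2H2",
                "ankyrin repeat", "PH domain", "myelin proteolipid protein",
                "WD40 repeat", "EF-hand", "immunoglobulin domain")

  for (i in seq_len(n)) {
    gid <- gene_ids[i]; chrom <- gene_chrom[i]; strand <- gene_strand[i]
    k <- sample(cfg$exons_per_gene[1]:cfg$exons_per_gene[2], 1L)
    elens <- sample(cfg$exon_length[1]:cfg$exon_length[2], k, replace = TRUE)
    ilens <- if (k > 1L) sample(cfg$intron_length[1]:cfg$intron_length[2],
                                k - 1L, replace = TRUE) else integer(0)
    gstart <- cursor[chrom]
    starts <- gstart + cumsum(c(0L, head(elens, -1L) + ilens))
    ends <- starts + elens - 1L
    cursor[chrom] <- ends[k] + sample(1500:5000, 1L)

    # exon genomic intervals in ascending order; transcription order depends
    # on strand
    ex <- data.table(gene_id = gid, chrom = chrom, start = starts, end = ends,
                     strand = strand)
    txs <- list(ex)                       # isoform 1: all exons
    tx_ids <- paste0(gid, ".t1")
    if (k >= 3L && runif(1) < 0.2) {      # isoform 2: skip one internal exon
      skip <- sample(2:(k - 1L), 1L)
      txs <- c(txs, list(ex[-skip]))
      tx_ids <- c(tx_ids, paste0(gid, ".t2"))
    }
    for (j in seq_along(txs)) {
      tid <- tx_ids[j]; txe <- copy(txs[[j]])
      txe[, transcript_id := tid]
      tx_len <- txe[, sum(end - start + 1L)]
      cds_len <- max(3L, (as.integer(tx_len * cfg$cds_fraction) %/% 3L) * 3L)
      utr5 <- if (tx_len > cds_len)
        sample.int(tx_len - cds_len, 1L) - 1L else 0L
      cds_tx <- c(utr5 + 1L, utr5 + cds_len)   # transcript coords, 1-based
      seg <- tx_interval_to_genomic(txe, cds_tx[1], cds_tx[2], strand)
      seg[, `:=`(transcript_id = tid, gene_id = gid, chrom = chrom,
                 strand = strand)]
      cds_rows[[i]] <- rbindlist(list(cds_rows[[i]], seg), use.names = TRUE,
                                 fill = TRUE)
      exon_rows[[i]] <- rbindlist(list(exon_rows[[i]],
        txe[, .(transcript_id, gene_id, chrom, start, end, strand)]))
      tx_rows[[i]] <- rbindlist(list(tx_rows[[i]],
        data.table(transcript_id = tid, gene_id = gid)))
      # protein domains
      L <- cds_len %/% 3L
      nd <- sample(0:3, 1L, prob = c(0.2, 0.4, 0.3, 0.1))
      if (nd > 0L && L > 15L) {
        ds <- sort(sample.int(L - 10L, nd))
        de <- pmin(L, ds + sample(8:60, nd, replace = TRUE))
        dom_rows[[i]] <- rbindlist(list(dom_rows[[i]], data.table(
          transcript_id = tid, domain_name = sample(dom_pool, nd),
          aa_start = ds, aa_end = de)))
      }
      seqs[[i]] <- c(seqs[[i]], setNames(paste(
        sample(c("A", "C", "G", "T"), tx_len, replace = TRUE), collapse = ""),
        tid))
    }
  }

  exons_tx <- rbindlist(exon_rows)
  cds <- rbindlist(cds_rows)[, .(transcript_id, gene_id, chrom, start, end, strand)]
  genes <- exons_tx[, .(start = min(start), end = max(end)),
                    by = .(gene_id, chrom, strand)]
  db <- annotation_db(genes, rbindlist(tx_rows), exons_tx, cds)
  domains <- rbindlist(dom_rows[!vapply(dom_rows, is.null, logical(1))])
  if (!nrow(domains) && is.null(domains$transcript_id))
    domains <- data.table(transcript_id = character(0), domain_name = character(0),
                          aa_start = integer(0), aa_end = integer(0))
  seqv <- unlist(seqs)
  list(db = db,
       transcript_seqs = Biostrings::DNAStringSet(seqv),
       domains = domains)
}

# Map a transcript-coordinate interval (1-based inclusive, 5'->3') to genomic
# segments given the transcript's exons (ascending genomic order, one strand).
tx_interval_to_genomic <- function(exons, tx_start, tx_end, strand) {
  ex <- as.data.table(exons)[order(start)]
  if (strand == "-") ex <- ex[rev(seq_len(.N))]
  w <- ex$end - ex$start + 1L
  off <- cumsum(c(0L, head(w, -1L)))         # transcript offset of each exon
  out <- list()
  for (i in seq_len(nrow(ex))) {
    s <- max(tx_start, off[i] + 1L); e <- min(tx_end, off[i] + w[i])
    if (s > e) next
    if (strand == "+") {
      gs <- ex$start[i] + (s - off[i] - 1L); ge <- ex$start[i] + (e - off[i] - 1L)
    } else {
      ge <- ex$end[i] - (s - off[i] - 1L); gs <- ex$end[i] - (e - off[i] - 1L)
    }
    out[[length(out) + 1L]] <- data.table(start = gs, end = ge)
  }
  rbindlist(out)
}

#' Write annotation artifacts to disk
#'
#' Writes the GTF, transcript FASTA and the protein-domain TSV
#' (transcript_id, domain_name, aa_start, aa_end; 1-based inclusive).
#'
#' @param ann result of [generate_annotation()]
#' @param dir output directory (created if needed)
#' @return named character vector of file paths
#' @export
write_annotation <- function(ann, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(gtf = file.path(dir, "annotation.gtf"),
             fasta = file.path(dir, "transcripts.fa"),
             domains = file.path(dir, "domains.tsv"))
  write_gtf(ann$db, paths["gtf"])
  Biostrings::writeXStringSet(ann$transcript_seqs, paths["fasta"])
  fwrite(ann$domains, paths["domains"], sep = "\t")
  paths
}
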