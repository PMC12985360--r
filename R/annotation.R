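#' Annotation database for gene models
#'
#' An `annotation_db` bundles genes, transcripts, per-transcript exons, merged
#' gene-level exon features, and CDS segments, all as `data.table`s in 1-based
#' inclusive genomic coordinates (the GTF/GRanges convention). Gene-level exon
#' features are the merged union of all transcript exons of a gene, identified
#' as `gene:index` with indices assigned in transcription order; exon-level
#' counting in this package is always against these merged features.
#'
#' @param genes data.table with gene_id, chrom, start, end, strand
#' @param transcripts data.table with transcript_id, gene_id
#' @param exons_tx data.table of per-transcript exons
#'   (transcript_id, gene_id, chrom, start, end, strand)
#' @param cds data.table of CDS segments (transcript_id, gene_id, chrom,
#'   start, end, strand); may be empty
#' @return object of class `annotation_db`
#' @export
annotation_db <- function(genes, transcripts, exons_tx, cds) {
  genes <- as.data.table(genes); transcripts <- as.data.table(transcripts)
  exons_tx <- as.data.table(exons_tx); cds <- as.data.table(cds)
  setorder(genes, gene_id)
  # gene 3' end: max end on + strand, min start on - strand
  genes[, end3 := ifelse(strand == "+", end, start)]
  # transcription-order exon rank and frame check
  if (nrow(exons_tx)) {
    setorder(exons_tx, transcript_id, start)
    exons_tx[, exon_rank := seq_len(.N), by = transcript_id]
    exons_tx[strand == "-", exon_rank := rev(exon_rank), by = transcript_id]
  } else exons_tx[, exon_rank := integer(0)]
  if (nrow(cds)) {
    cds_len <- cds[, .(len = sum(end - start + 1L)), by = transcript_id]
    transcripts <- merge(transcripts, cds_len, by = "transcript_id", all.x = TRUE)
    transcripts[, coding := !is.na(len) & len %% 3L == 0L]
    transcripts[, len := NULL]
  } else transcripts[, coding := FALSE]
  db <- structure(list(
    genes = genes, transcripts = transcripts, exons_tx = exons_tx,
    cds = cds, exons = merge_gene_exons(genes, exons_tx)
  ), class = "annotation_db")
  db
}

#' @export
print.annotation_db <- function(x, ...) {
  cat(sprintf("annotation_db: %d genes, %d transcripts, %d merged exon features, %d CDS segments\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons), nrow(x$cds)))
  invisible(x)
}

# Merge overlapping transcript exons into gene-level exon features gene:index.
merge_gene_exons <- function(genes, exons_tx) {
  if (!nrow(exons_tx)) {
    return(data.table(exon_id = character(0), gene_id = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  gr <- GenomicRanges::GRanges(exons_tx$chrom,
                               IRanges::IRanges(exons_tx$start, exons_tx$end),
                               strand = exons_tx$strand)
  merged <- lapply(split(seq_len(nrow(exons_tx)), exons_tx$gene_id), function(i) {
    red <- GenomicRanges::reduce(gr[i])
    data.table(chrom = as.character(GenomicRanges::seqnames(red)),
               start = GenomicRanges::start(red), end = GenomicRanges::end(red),
               strand = as.character(GenomicRanges::strand(red)))
  })
  out <- rbindlist(merged, idcol = "gene_id")
  # index in transcription order: ascending for +, descending for -
  setorder(out, gene_id, start)
  out[, exon_rank := if (strand[1] == "+") seq_len(.N) else rev(seq_len(.N)), by = gene_id]
  out[, exon_id := paste0(gene_id, ":", exon_rank)]
  out[, exon_rank := NULL]
  setcolorder(out, c("exon_id", "gene_id", "chrom", "start", "end", "strand"))
  out[]
}

#' Parse a GTF file into an annotation database
#'
#' Reads Ensembl-dialect GTF (1-based inclusive) rows of type gene,
#' transcript, exon and CDS. Transcripts without CDS rows are marked
#' non-coding; transcripts whose total CDS length is not divisible by 3 are
#' flagged out-of-frame and excluded from protein-coordinate mapping.
#'
#' @param path GTF file path
#' @return an [annotation_db()]
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) stopf("GTF not found: %s", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stopf("malformed GTF '%s': %s", path, conditionMessage(e)))
  dt <- as.data.table(gr)
  setnames(dt, "seqnames", "chrom")
  dt[, chrom := as.character(chrom)]
  dt[, strand := as.character(strand)]
  need <- c("type", "gene_id")
  if (!all(need %in% names(dt))) stopf("GTF lacks required attributes: %s", path)
  genes <- dt[type == "gene", .(gene_id, chrom, start, end, strand)]
  if (!nrow(genes)) {
    # fall back to deriving gene spans from exons
    genes <- dt[type == "exon", .(start = min(start), end = max(end)),
                by = .(gene_id, chrom, strand)]
  }
  has_tx <- "transcript_id" %in% names(dt)
  transcripts <- if (has_tx) unique(dt[type %in% c("transcript", "exon", "CDS") & !is.na(transcript_id),
                                       .(transcript_id, gene_id)])
                 else data.table(transcript_id = character(0), gene_id = character(0))
  exons_tx <- if (has_tx) dt[type == "exon" & !is.na(transcript_id),
                             .(transcript_id, gene_id, chrom, start, end, strand)]
              else data.table(transcript_id = character(0), gene_id = character(0),
                              chrom = character(0), start = integer(0),
                              end = integer(0), strand = character(0))
  cds <- if (has_tx) dt[type == "CDS" & !is.na(transcript_id),
                        .(transcript_id, gene_id, chrom, start, end, strand)]
         else exons_tx[0]
  annotation_db(genes, transcripts, exons_tx, cds)
}

#' Write an annotation database to GTF
#'
#' Inverse of [parse_gtf()]: `parse_gtf(write_gtf(db))` reproduces `db`.
#'
#' @param db an [annotation_db()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gtf <- function(db, path) {
  rows <- rbindlist(list(
    db$genes[, .(chrom, start, end, strand, type = "gene", gene_id,
                 transcript_id = NA_character_)],
    merge(db$transcripts[, .(transcript_id, gene_id)],
          db$exons_tx[, .(start = min(start), end = max(end)),
                      by = .(transcript_id, chrom, strand)],
          by = "transcript_id")[, .(chrom, start, end, strand,
                                    type = "transcript", gene_id, transcript_id)],
    db$exons_tx[, .(chrom, start, end, strand, type = "exon", gene_id, transcript_id)],
    db$cds[, .(chrom, start, end, strand, type = "CDS", gene_id, transcript_id)]
  ), use.names = TRUE)
  # GTF phase for CDS rows: bases to skip to reach the next codon start
  rows[, phase := NA_integer_]
  if (nrow(db$cds)) {
    ph <- rbindlist(lapply(unique(db$cds$transcript_id), function(tid) {
      seg <- cds_segments(db, tid)
      seg[, .(transcript_id = tid, start, end,
              phase = as.integer((3L - cds_off %% 3L) %% 3L))]
    }))
    rows[ph, on = c("transcript_id", "start", "end"),
         phase := ifelse(type == "CDS", i.phase, NA_integer_)]
  }
  setorder(rows, chrom, start, end, type)
  gr <- GenomicRanges::GRanges(rows$chrom, IRanges::IRanges(rows$start, rows$end),
                               strand = rows$strand)
  S4Vectors::mcols(gr)$type <- rows$type
  S4Vectors::mcols(gr)$gene_id <- rows$gene_id
  S4Vectors::mcols(gr)$transcript_id <- rows$transcript_id
  S4Vectors::mcols(gr)$phase <- rows$phase
  S4Vectors::mcols(gr)$source <- "exonsci"
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Build a strand-aware interval index over genes and exons
#'
#' @param db an [annotation_db()]
#' @return object of class `feature_index` holding `GRanges` for genes and
#'   merged exons
#' @export
build_feature_index <- function(db) {
  g <- GenomicRanges::GRanges(db$genes$chrom,
                              IRanges::IRanges(db$genes$start, db$genes$end),
                              strand = db$genes$strand)
  S4Vectors::mcols(g)$gene_id <- db$genes$gene_id
  S4Vectors::mcols(g)$end3 <- db$genes$end3
  e <- GenomicRanges::GRanges(db$exons$chrom,
                              IRanges::IRanges(db$exons$start, db$exons$end),
                              strand = db$exons$strand)
  S4Vectors::mcols(e)$exon_id <- db$exons$exon_id
  S4Vectors::mcols(e)$gene_id <- db$exons$gene_id
  structure(list(genes = g, exons = e, db = db), class = "feature_index")
}

#' Query features overlapping a genomic interval
#'
#' Returns every gene (or exon) feature overlapping the query by at least one
#' base on the given strand; equivalent to a brute-force linear scan.
#'
#' @param index a [build_feature_index()] object
#' @param chrom chromosome
#' @param start,end 1-based inclusive interval
#' @param strand `"+"`, `"-"`, or `"*"` for either strand
#' @param what `"genes"` or `"exons"`
#' @return data.table of overlapping features (possibly empty)
#' @export
locate_overlaps <- function(index, chrom, start, end, strand = "*",
                            what = c("genes", "exons")) {
  what <- match.arg(what)
  gr <- index[[what]]
  if (!chrom %in% unique(as.character(GenomicRanges::seqnames(gr)))) {
    return(as.data.table(S4Vectors::mcols(gr))[0])
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
  hits <- GenomicRanges::findOverlaps(q, gr, ignore.strand = (strand == "*"))
  as.data.table(S4Vectors::mcols(gr[S4Vectors::subjectHits(hits)]))
}

# Ordered CDS segments of a transcript with cumulative CDS-space offsets,
# in transcription order (5'->3').
cds_segments <- function(db, tid) {
  seg <- db$cds[db$cds$transcript_id == tid]
  if (!nrow(seg)) return(seg)
  if (seg$strand[1] == "+") setorder(seg, start) else setorder(seg, -start)
  seg[, width := end - start + 1L]
  seg[, cds_off := cumsum(c(0L, head(width, -1L)))]
  seg[]
}

#' Map a genomic interval to protein (amino-acid) coordinates
#'
#' Intersects the interval with the transcript's CDS segments, converts the
#' overlap to CDS-relative nucleotide offsets respecting strand, and returns
#' the bounding amino-acid interval, 1-based inclusive. Partial codons are
#' included (floor/ceil), which is conservative for domain overlap.
#'
#' @param db an [annotation_db()]
#' @param transcript_id transcript with an in-frame CDS
#' @param start,end 1-based inclusive genomic interval
#' @return integer `c(aa_start, aa_end)` or `NULL` when the interval touches
#'   no coding base (UTR/intron-only)
#' @export
genomic_to_protein <- function(db, transcript_id, start, end) {
  tid <- transcript_id
  tx <- db$transcripts[db$transcripts$transcript_id == tid]
  if (!nrow(tx)) stopf("unknown transcript: %s", tid)
  if (!tx$coding[1]) stopf("transcript %s has no in-frame CDS", tid)
  seg <- cds_segments(db, tid)
  lo <- NA_integer_; hi <- NA_integer_
  for (i in seq_len(nrow(seg))) {
    s <- max(start, seg$start[i]); e <- min(end, seg$end[i])
    if (s > e) next
    if (seg$strand[i] == "+") {
      o1 <- seg$cds_off[i] + (s - seg$start[i])       # 0-based first coding nt
      o2 <- seg$cds_off[i] + (e - seg$start[i])       # 0-based last coding nt
    } else {
      o1 <- seg$cds_off[i] + (seg$end[i] - e)
      o2 <- seg$cds_off[i] + (seg$end[i] - s)
    }
    lo <- min(lo, o1, na.rm = TRUE); hi <- max(hi, o2, na.rm = TRUE)
  }
  if (is.na(lo)) return(NULL)
  c(aa_start = lo %/% 3L + 1L, aa_end = hi %/% 3L + 1L)
}
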