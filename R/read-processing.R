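#' Demultiplexing configuration
#'
#' @param rt_whitelist,lig_whitelist character vectors of valid fixed-length
#'   barcodes (unique, equal length)
#' @param rt_to_sample data.frame/data.table mapping `rt_bc` to `sample_id`
#' @param max_dist maximum correction distance (default 1: a barcode is
#'   corrected to its unique whitelist entry at distance < 2, else the read is
#'   excluded)
#' @param metric `"hamming"` (default; equal-length substitutions) or
#'   `"levenshtein"` (via [utils::adist()])
#' @return object of class `demux_config`
#' @export
demux_config <- function(rt_whitelist, lig_whitelist, rt_to_sample,
                         max_dist = 1L, metric = c("hamming", "levenshtein")) {
  metric <- match.arg(metric)
  for (wl in list(rt_whitelist, lig_whitelist)) {
    if (anyDuplicated(wl)) stopf("whitelist entries must be unique")
    if (length(unique(nchar(wl))) != 1L) stopf("whitelist entries must have equal length")
  }
  structure(list(rt_whitelist = rt_whitelist, lig_whitelist = lig_whitelist,
                 rt_to_sample = as.data.table(rt_to_sample),
                 max_dist = as.integer(max_dist), metric = metric),
            class = "demux_config")
}

#' Correct one barcode against a whitelist
#'
#' Exact matches return themselves; otherwise the unique whitelist entry at
#' distance 1 is returned. Ambiguity (two entries at distance 1) or distance
#' >= 2 returns `NA` and the read is excluded downstream.
#'
#' @param observed observed barcode (same length as whitelist entries)
#' @param whitelist character vector of valid barcodes
#' @param metric `"hamming"` or `"levenshtein"`
#' @return corrected barcode, or `NA_character_`
#' @export
correct_barcode <- function(observed, whitelist, metric = "hamming") {
  if (observed %in% whitelist) return(observed)
  d <- if (metric == "hamming") hamming_dist(whitelist, observed)
       else as.integer(utils::adist(whitelist, observed))
  hit <- which(d == 1L)
  if (length(hit) == 1L) whitelist[hit] else NA_character_
}

# Vectorised corrector: precomputes every single-substitution neighbour of
# the whitelist; neighbours claimed by more than one entry are ambiguous and
# map to NA.
build_barcode_map <- function(whitelist) {
  len <- nchar(whitelist[1])
  bases <- c("A", "C", "G", "T")
  neigh <- list(data.table(obs = whitelist, corrected = whitelist))
  for (p in seq_len(len)) {
    cur <- substring(whitelist, p, p)
    for (b in bases) {
      mut <- whitelist
      substring(mut, p, p) <- b
      keep <- cur != b
      neigh[[length(neigh) + 1L]] <- data.table(obs = mut[keep],
                                                corrected = whitelist[keep])
    }
  }
  map <- rbindlist(neigh)
  # exact whitelist entries always map to themselves, even if they are a
  # neighbour of another entry; other collisions are ambiguous
  map[, exact := obs == corrected]
  map <- map[order(-exact)]
  amb <- map[, .N, by = obs][N > 1L][!obs %in% whitelist, obs]
  map <- unique(map, by = "obs")
  map[obs %in% amb, corrected := NA_character_]
  setkey(map, obs)
  map
}

correct_barcodes_vec <- function(observed, map) {
  map[list(observed), corrected]
}

#' Demultiplex reads into per-sample streams
#'
#' Corrects RT and ligation barcodes against their whitelists (unique
#' distance-1 correction; ties and distance >= 2 are rejected), then routes
#' each read to the sample its corrected RT barcode encodes. Every input read
#' lands in exactly one sample stream or the rejection log.
#'
#' @param reads data.table with at least `rt_bc` and `lig_bc` columns
#' @param config a [demux_config()]
#' @return list with `assigned` (reads plus corrected barcodes and
#'   `sample_id`) and `rejected` (reads plus a `reason` column)
#' @export
demultiplex <- function(reads, config) {
  stopifnot(inherits(config, "demux_config"))
  reads <- as.data.table(reads)
  if (config$metric == "hamming") {
    rt_map <- build_barcode_map(config$rt_whitelist)
    lig_map <- build_barcode_map(config$lig_whitelist)
    rt_cor <- correct_barcodes_vec(reads$rt_bc, rt_map)
    lig_cor <- correct_barcodes_vec(reads$lig_bc, lig_map)
  } else {
    rt_cor <- vapply(reads$rt_bc, correct_barcode, character(1),
                     whitelist = config$rt_whitelist, metric = "levenshtein",
                     USE.NAMES = FALSE)
    lig_cor <- vapply(reads$lig_bc, correct_barcode, character(1),
                      whitelist = config$lig_whitelist, metric = "levenshtein",
                      USE.NAMES = FALSE)
  }
  smap <- config$rt_to_sample
  sample_id <- smap$sample_id[match(rt_cor, smap$rt_bc)]
  reason <- rep(NA_character_, nrow(reads))
  reason[is.na(lig_cor)] <- "uncorrectable ligation barcode"
  reason[is.na(rt_cor)] <- "uncorrectable RT barcode"
  reason[!is.na(rt_cor) & !is.na(lig_cor) & is.na(sample_id)] <-
    "RT barcode not mapped to a sample"
  keep <- is.na(reason)
  assigned <- reads[keep]
  assigned[, rt_bc := rt_cor[keep]]
  assigned[, lig_bc := lig_cor[keep]]
  assigned[, sample_id := sample_id[keep]]
  rejected <- reads[!keep]
  rejected[, reason := reason[!keep]]
  list(assigned = assigned[], rejected = rejected[])
}

#' Collapse PCR duplicates to molecules
#'
#' One molecule per distinct key (RT barcode, ligation barcode, UMI,
#' tagmentation site); the representative read is the first encountered after
#' a deterministic sort by genomic position. Idempotent by construction.
#'
#' The ligation barcode is part of the key because cell identity in
#' combinatorial indexing is the barcode combination; set
#' `include_ligation = FALSE` to collapse on the RT barcode alone.
#'
#' @param reads data.table with `rt_bc`, `lig_bc`, `umi`, `tag_chrom`,
#'   `tag_pos`, `tag_strand`, `chrom`, `start`
#' @param include_ligation include the ligation barcode in the key
#' @return data.table of molecules (one representative read each, plus
#'   `n_reads` support)
#' @export
deduplicate <- function(reads, include_ligation = TRUE) {
  reads <- as.data.table(reads)
  key <- c("rt_bc", if (include_ligation) "lig_bc", "umi",
           "tag_chrom", "tag_pos", "tag_strand")
  miss <- setdiff(c(key, "chrom", "start"), names(reads))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  out <- copy(reads)
  setorderv(out, c("chrom", "start", key))
  if (!"n_reads" %in% names(out)) out[, n_reads := 1L]
  out[, n_reads := sum(n_reads), by = key]
  out <- unique(out, by = key)
  setorderv(out, c("chrom", "start", key))
  out[]
}

#' Write reads to SAM
#'
#' Single-end, unpaired SAM with tags: CB (combined cell barcode
#' RT+ligation), UB (UMI), XP (primer type), XT (tagmentation site
#' chrom:pos:strand). Sequence is not simulated, so SEQ/QUAL are `*`.
#'
#' @param reads data.table from [simulate_reads()] or compatible
#' @param path output SAM path
#' @param chrom_lengths named integer vector for the header (defaults to max
#'   end per chromosome)
#' @return `path`, invisibly
#' @export
write_sam <- function(reads, path, chrom_lengths = NULL) {
  reads <- as.data.table(reads)
  if (is.null(chrom_lengths)) {
    cl <- reads[, .(len = max(end) + 1000L), by = chrom]
    chrom_lengths <- setNames(cl$len, cl$chrom)
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths), chrom_lengths))
  flag <- ifelse(reads$strand == "-", 16L, 0L)
  body <- sprintf(
    "read%d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*\tCB:Z:%s\tUB:Z:%s\tXP:Z:%s\tXT:Z:%s:%d:%s",
    seq_len(nrow(reads)), flag, reads$chrom, reads$start,
    reads$end - reads$start + 1L, paste(reads$rt_bc, reads$lig_bc, sep = "."),
    reads$umi, reads$primer, reads$tag_chrom, reads$tag_pos, reads$tag_strand)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file written by [write_sam()] back into the tabular dialect
#'
#' @param path SAM path
#' @return data.table with the read-record columns
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  tagf <- function(prefix, i) sub(prefix, "", f[[i]], fixed = TRUE)
  cb <- tagf("CB:Z:", 12L)
  cbs <- data.table::tstrsplit(cb, ".", fixed = TRUE)
  xt <- data.table::tstrsplit(tagf("XT:Z:", 15L), ":", fixed = TRUE)
  width <- as.integer(sub("M", "", f[[6]], fixed = TRUE))
  data.table(
    read_id = seq_along(lines), chrom = f[[3]],
    start = as.integer(f[[4]]), end = as.integer(f[[4]]) + width - 1L,
    strand = ifelse(bitwAnd(as.integer(f[[2]]), 16L) > 0L, "-", "+"),
    rt_bc = cbs[[1]], lig_bc = cbs[[2]], umi = tagf("UB:Z:", 13L),
    primer = tagf("XP:Z:", 14L), tag_chrom = xt[[1]],
    tag_pos = as.integer(xt[[2]]), tag_strand = xt[[3]])
}
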