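#' HCR split-probe design configuration
#'
#' Filters follow the split-initiator convention: candidate windows start
#' after the first 100 bp of the transcript (when length permits), each
#' window holds two 25-nt half-sites around a 2-nt gap, homopolymer runs of
#' A/T are limited to 5 and of C/G to 4 bases, each half-site's GC content
#' must lie in [45, 60]% and the two half-sites within 6 percentage points of
#' one another.
#'
#' @param skip_5prime bp skipped at the transcript 5' end (100)
#' @param half_length half-site length in nt (25)
#' @param gap nt between the half-sites (2)
#' @param max_at_run,max_cg_run maximum homopolymer runs (5 / 4)
#' @param gc_range allowed GC percentage range (c(45, 60))
#' @param max_gc_diff maximum GC difference between half-sites in
#'   percentage points (6)
#' @param n_pairs_range pairs selected per gene (5 to 11)
#' @return object of class `probe_config`
#' @export
probe_config <- function(skip_5prime = 100L, half_length = 25L, gap = 2L,
                         max_at_run = 5L, max_cg_run = 4L,
                         gc_range = c(45, 60), max_gc_diff = 6,
                         n_pairs_range = c(5L, 11L)) {
  stopifnot(half_length > 0, gap >= 0, skip_5prime >= 0,
            all(gc_range >= 0 & gc_range <= 100), gc_range[1] <= gc_range[2])
  structure(as.list(environment()), class = "probe_config")
}

gc_percent <- function(seqs) {
  n <- nchar(seqs)
  gc <- nchar(gsub("[AT]", "", seqs))
  100 * gc / n
}

# homopolymer run of either base longer than max_run (e.g. AAAAAA or TTTTTT
# for chars = c("A", "T"))
has_run <- function(seqs, chars, max_run) {
  pat <- paste(sprintf("%s{%d,}", chars, max_run + 1L), collapse = "|")
  grepl(pat, seqs)
}

#' Enumerate split-probe pair candidates along a transcript
#'
#' Slides a window of `2 * half_length + gap` nt starting at `skip_5prime`
#' (or position 1 when the transcript is too short to skip), splits each
#' window into two half-sites around the gap, and evaluates every filter
#' independently; all candidates are returned with per-filter flags and a
#' conjunctive `pass`.
#'
#' @param sequence transcript sequence (character or `DNAString`)
#' @param config a [probe_config()]
#' @param transcript_id id recorded in the output
#' @return data.table of candidates: window_start (1-based transcript
#'   coordinate), half-site sequences, GC percentages, per-filter flags,
#'   `pass`; empty (with a warning) when the sequence is too short
#' @export
enumerate_candidates <- function(sequence, config = probe_config(),
                                 transcript_id = NA_character_) {
  seq <- toupper(as.character(sequence))
  win <- 2L * config$half_length + config$gap
  skip <- config$skip_5prime
  len <- nchar(seq)
  if (len < skip + win) skip <- 0L                 # skip only when length permits
  if (len < win) {
    warnf("sequence shorter than one probe window (%d < %d)", len, win)
    return(data.table(transcript_id = character(0), window_start = integer(0),
                      half1 = character(0), half2 = character(0),
                      gc1 = numeric(0), gc2 = numeric(0),
                      pass_at_run = logical(0), pass_cg_run = logical(0),
                      pass_gc_range = logical(0), pass_gc_diff = logical(0),
                      pass = logical(0)))
  }
  starts <- (skip + 1L):(len - win + 1L)
  half1 <- substring(seq, starts, starts + config$half_length - 1L)
  half2 <- substring(seq, starts + config$half_length + config$gap,
                     starts + win - 1L)
  gc1 <- gc_percent(half1); gc2 <- gc_percent(half2)
  both <- paste0(half1, half2)
  pass_at <- !(has_run(half1, c("A", "T"), config$max_at_run) |
               has_run(half2, c("A", "T"), config$max_at_run))
  pass_cg <- !(has_run(half1, c("C", "G"), config$max_cg_run) |
               has_run(half2, c("C", "G"), config$max_cg_run))
  pass_range <- gc1 >= config$gc_range[1] & gc1 <= config$gc_range[2] &
                gc2 >= config$gc_range[1] & gc2 <= config$gc_range[2]
  pass_diff <- abs(gc1 - gc2) <= config$max_gc_diff
  data.table(transcript_id = transcript_id, window_start = starts,
             half1 = half1, half2 = half2, gc1 = gc1, gc2 = gc2,
             pass_at_run = pass_at, pass_cg_run = pass_cg,
             pass_gc_range = pass_range, pass_gc_diff = pass_diff,
             pass = pass_at & pass_cg & pass_range & pass_diff)
}

# maximum minimal spacing of n points chosen from sorted positions:
# binary search on the spacing + greedy feasibility, exact for points on a
# line; returns chosen indices (leftmost greedy at the optimal spacing)
max_min_spacing <- function(pos, n) {
  pos <- sort(pos)
  if (n <= 1L) return(pos[1])
  feasible <- function(d) {
    chosen <- pos[1]; cnt <- 1L
    for (p in pos[-1]) {
      if (p - chosen >= d) { chosen <- p; cnt <- cnt + 1L }
      if (cnt >= n) return(TRUE)
    }
    cnt >= n
  }
  lo <- 0L; hi <- pos[length(pos)] - pos[1]
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (feasible(mid)) lo <- mid else hi <- mid - 1L
  }
  chosen <- pos[1]; out <- pos[1]; d <- lo
  for (p in pos[-1]) {
    if (length(out) >= n) break
    if (p - chosen >= d) { chosen <- p; out <- c(out, p) }
  }
  out
}

#' Select a spaced probe set from passing candidates
#'
#' Deterministically picks `n_pairs` passing, non-overlapping candidates that
#' maximise the minimum inter-pair start distance (exact via binary search +
#' greedy feasibility on the sorted positions), returned position-sorted.
#'
#' @param candidates output of [enumerate_candidates()]
#' @param n_pairs pairs to select (defaults to the upper end of the
#'   configured range, capped at availability)
#' @param config a [probe_config()]
#' @return data.table subset of passing candidates, position-sorted; warns
#'   and returns all passing candidates when fewer than `n_pairs` pass
#' @export
select_module_set <- function(candidates, n_pairs = NULL,
                              config = probe_config()) {
  cand <- as.data.table(candidates)[pass == TRUE]
  if (!nrow(cand)) stopf("no passing probe candidates")
  if (is.null(n_pairs)) n_pairs <- config$n_pairs_range[2]
  setorder(cand, window_start)
  # enforce non-overlap first: windows closer than one window length overlap
  win <- 2L * config$half_length + config$gap
  keep <- integer(0); last <- -Inf
  for (i in seq_len(nrow(cand))) {
    if (cand$window_start[i] - last >= win) { keep <- c(keep, i); last <- cand$window_start[i] }
  }
  cand <- cand[keep]
  if (nrow(cand) < n_pairs) {
    warnf("only %d non-overlapping passing candidates (requested %d)",
          nrow(cand), n_pairs)
    return(cand[])
  }
  sel <- max_min_spacing(cand$window_start, n_pairs)
  cand[window_start %in% sel][]
}

#' Export probe candidates as FASTA for external off-target screening
#'
#' @param candidates data.table from [enumerate_candidates()] or
#'   [select_module_set()]
#' @param path FASTA path
#' @return `path`, invisibly
#' @export
export_probe_fasta <- function(candidates, path) {
  cand <- as.data.table(candidates)
  seqs <- c(setNames(cand$half1, sprintf("%s_w%d_h1", cand$transcript_id,
                                         cand$window_start)),
            setNames(cand$half2, sprintf("%s_w%d_h2", cand$transcript_id,
                                         cand$window_start)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
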