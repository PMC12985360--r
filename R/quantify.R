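#' Gene-assignment configuration
#'
#' @param upstream_window bp window for upstream rescue (default 1000: a
#'   molecule up to 1,000 bp upstream of a gene's start on the same strand is
#'   rescued; 1,001 bp is not)
#' @param antisense_rescue rescue molecules overlapping a unique gene on the
#'   opposite strand when no same-strand assignment exists
#' @param ambiguous_hexamer `"discard"` (default: the closest-3'-end rule is
#'   applied only to oligo-dT molecules) or `"closest3p"` to apply it to
#'   hexamer-primed molecules too
#' @return object of class `assign_config`
#' @export
assign_config <- function(upstream_window = 1000L, antisense_rescue = TRUE,
                          ambiguous_hexamer = c("discard", "closest3p")) {
  if (upstream_window < 0) stopf("upstream_window must be >= 0")
  structure(list(upstream_window = as.integer(upstream_window),
                 antisense_rescue = isTRUE(antisense_rescue),
                 ambiguous_hexamer = match.arg(ambiguous_hexamer)),
            class = "assign_config")
}

# 3'-most aligned base of each molecule, strand-aware
mol_3prime <- function(molecules) {
  ifelse(molecules$strand == "+", molecules$end, molecules$start)
}

#' Assign molecules to genes
#'
#' Implements the four-branch assignment rule: (1) direct same-strand overlap;
#' (2) among multiple direct overlaps, an oligo-dT molecule goes to the gene
#' whose annotated 3' end is closest to the molecule's 3'-most base (ties
#' broken lexicographically by gene id; ambiguous hexamer molecules are
#' discarded by default); (3) with no direct overlap, the unique gene starting
#' within `upstream_window` bp downstream of the molecule on the same strand
#' is rescued, else the unique antisense-overlapping gene; (4) otherwise the
#' molecule is unassigned.
#'
#' @param molecules data.table with `chrom`, `start`, `end`, `strand`,
#'   `primer`
#' @param index a [build_feature_index()]
#' @param config an [assign_config()]
#' @return the input with `gene_id` (NA when discarded) and
#'   `assign_class` (`direct`, `direct-3p`, `upstream-rescued`,
#'   `antisense-rescued`, `unassigned`, `ambiguous`) columns appended
#' @export
assign_gene <- function(molecules, index, config = assign_config()) {
  mol <- as.data.table(molecules)
  n <- nrow(mol)
  mol[, .mol_row := seq_len(n)]
  gr <- GenomicRanges::GRanges(mol$chrom, IRanges::IRanges(mol$start, mol$end),
                               strand = mol$strand)
  genes <- index$genes
  gid <- S4Vectors::mcols(genes)$gene_id
  gend3 <- S4Vectors::mcols(genes)$end3

  out_gene <- rep(NA_character_, n)
  out_class <- rep("unassigned", n)

  ## (1)-(2) direct overlap, same strand
  h <- GenomicRanges::findOverlaps(gr, genes, ignore.strand = FALSE)
  if (length(h)) {
    hd <- data.table(mrow = S4Vectors::queryHits(h),
                     gene_id = gid[S4Vectors::subjectHits(h)],
                     end3 = gend3[S4Vectors::subjectHits(h)])
    hd[, nhit := .N, by = mrow]
    uniq <- hd[nhit == 1L]
    out_gene[uniq$mrow] <- uniq$gene_id
    out_class[uniq$mrow] <- "direct"
    multi <- hd[nhit > 1L]
    if (nrow(multi)) {
      multi[, primer := mol$primer[mrow]]
      multi[, p3 := mol_3prime(mol)[mrow]]
      use3p <- multi$primer == "dT" | config$ambiguous_hexamer == "closest3p"
      pick <- multi[use3p]
      if (nrow(pick)) {
        pick[, dist3p := abs(p3 - end3)]
        setorder(pick, mrow, dist3p, gene_id)
        pick <- unique(pick, by = "mrow")
        out_gene[pick$mrow] <- pick$gene_id
        out_class[pick$mrow] <- "direct-3p"
      }
      amb <- unique(multi[!use3p, mrow])
      out_class[amb] <- "ambiguous"
    }
  }

  ## (3) upstream rescue then antisense, for still-unassigned molecules
  todo <- which(out_class == "unassigned")
  if (length(todo) && config$upstream_window > 0L) {
    hu <- GenomicRanges::findOverlaps(gr[todo], genes,
                                      maxgap = config$upstream_window,
                                      ignore.strand = FALSE)
    if (length(hu)) {
      hd <- data.table(mrow = todo[S4Vectors::queryHits(hu)],
                       sj = S4Vectors::subjectHits(hu))
      hd[, gene_id := gid[sj]]
      gs <- GenomicRanges::start(genes)[hd$sj]
      ge <- GenomicRanges::end(genes)[hd$sj]
      st <- mol$strand[hd$mrow]
      gap <- ifelse(st == "+", gs - mol$end[hd$mrow], mol$start[hd$mrow] - ge)
      hd <- hd[gap >= 1L & gap <= config$upstream_window]
      if (nrow(hd)) {
        hd[, nhit := .N, by = mrow]
        uniq <- hd[nhit == 1L]
        out_gene[uniq$mrow] <- uniq$gene_id
        out_class[uniq$mrow] <- "upstream-rescued"
      }
    }
  }
  todo <- which(out_class == "unassigned")
  if (length(todo) && config$antisense_rescue) {
    ha <- GenomicRanges::findOverlaps(gr[todo], genes, ignore.strand = TRUE)
    if (length(ha)) {
      hd <- data.table(mrow = todo[S4Vectors::queryHits(ha)],
                       sj = S4Vectors::subjectHits(ha))
      gstr <- as.character(GenomicRanges::strand(genes))[hd$sj]
      hd <- hd[gstr != mol$strand[hd$mrow]]
      if (nrow(hd)) {
        hd[, gene_id := gid[sj]]
        hd[, nhit := .N, by = mrow]
        uniq <- hd[nhit == 1L]
        out_gene[uniq$mrow] <- uniq$gene_id
        out_class[uniq$mrow] <- "antisense-rescued"
      }
    }
  }

  res <- copy(mol)[, .mol_row := NULL]
  res[, gene_id := out_gene]
  res[, assign_class := out_class]
  res[]
}

#' Assign gene-assigned molecules to merged exon features
#'
#' A molecule gets the exon of its assigned gene whose merged interval
#' overlaps it; ambiguity is broken by greatest overlap length, then (for
#' oligo-dT molecules) proximity of the exon to the molecule's 3'-most base,
#' then exon id. Molecules overlapping no exon of their gene are intronic
#' (`exon_id` NA).
#'
#' @param molecules output of [assign_gene()] (needs `gene_id`)
#' @param index a [build_feature_index()]
#' @return input with an `exon_id` column appended (NA = intronic)
#' @export
assign_exon <- function(molecules, index) {
  mol <- as.data.table(molecules)
  if (!"gene_id" %in% names(mol)) stopf("molecules must be gene-assigned first")
  n <- nrow(mol)
  out_exon <- rep(NA_character_, n)
  has_gene <- which(!is.na(mol$gene_id))
  if (length(has_gene)) {
    gr <- GenomicRanges::GRanges(mol$chrom[has_gene],
                                 IRanges::IRanges(mol$start[has_gene],
                                                  mol$end[has_gene]))
    ex <- index$exons
    h <- GenomicRanges::findOverlaps(gr, ex, ignore.strand = TRUE)
    if (length(h)) {
      qh <- S4Vectors::queryHits(h); sj <- S4Vectors::subjectHits(h)
      hd <- data.table(mrow = has_gene[qh],
                       exon_id = S4Vectors::mcols(ex)$exon_id[sj],
                       exon_gene = S4Vectors::mcols(ex)$gene_id[sj],
                       ex_start = GenomicRanges::start(ex)[sj],
                       ex_end = GenomicRanges::end(ex)[sj])
      hd <- hd[exon_gene == mol$gene_id[mrow]]
      if (nrow(hd)) {
        hd[, ov := pmin(ex_end, mol$end[mrow]) - pmax(ex_start, mol$start[mrow]) + 1L]
        p3 <- mol_3prime(mol)
        ex3 <- ifelse(mol$strand[hd$mrow] == "+", hd$ex_end, hd$ex_start)
        hd[, d3 := ifelse(mol$primer[mrow] == "dT",
                          abs(p3[mrow] - ex3), 0L)]
        setorder(hd, mrow, -ov, d3, exon_id)
        hd <- unique(hd, by = "mrow")
        out_exon[hd$mrow] <- hd$exon_id
      }
    }
  }
  res <- copy(mol)
  res[, exon_id := out_exon]
  res[]
}

#' A sparse cells-by-features count container
#'
#' Features are rows, cells are columns (the Bioconductor orientation).
#'
#' @param counts feature x cell matrix (coerced to `dgCMatrix`)
#' @param kind `"gene"` or `"exon"`
#' @return object of class `count_matrix` with `counts`, `kind`,
#'   `cell_totals`; exon matrices also carry `parent_gene`
#' @export
count_matrix <- function(counts, kind = c("gene", "exon")) {
  kind <- match.arg(kind)
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stopf("counts must be non-negative integers")
  obj <- structure(list(counts = counts, kind = kind,
                        cell_totals = Matrix::colSums(counts)),
                   class = "count_matrix")
  if (kind == "exon")
    obj$parent_gene <- sub(":[0-9]+$", "", rownames(counts))
  obj
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix (%s): %d features x %d cells, %.0f total counts\n",
              x$kind, nrow(x$counts), ncol(x$counts), sum(x$cell_totals)))
  invisible(x)
}

#' Build gene and exon count matrices from assigned molecules
#'
#' Gene totals per cell equal the number of assigned molecules of that cell;
#' intronic molecules are counted at the gene level only, so each exon-matrix
#' gene total is bounded by the corresponding gene count.
#'
#' @param molecules output of [assign_exon()]: one row per molecule with
#'   `cell_id`, `gene_id`, `exon_id`
#' @return list with `gene` and `exon` [count_matrix()] objects and an
#'   `assignment_summary` data.table of assignment-class counts
#' @export
build_matrices <- function(molecules) {
  mol <- as.data.table(molecules)
  if ("molecule_id" %in% names(mol) &&
      anyDuplicated(mol[, .(cell_id, molecule_id)]))
    stopf("duplicate (cell, molecule) pairs: deduplication contract violated")
  asg <- mol[!is.na(gene_id)]
  cells <- sort(unique(mol$cell_id))
  make <- function(dt, feature_col, kind) {
    feats <- sort(unique(dt[[feature_col]]))
    if (!length(feats) || !length(cells)) {
      m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(length(feats), length(cells)),
                                dimnames = list(feats, cells))
      return(count_matrix(m, kind))
    }
    tab <- dt[, .N, by = c(feature_col, "cell_id")]
    m <- Matrix::sparseMatrix(
      i = match(tab[[feature_col]], feats), j = match(tab$cell_id, cells),
      x = tab$N, dims = c(length(feats), length(cells)),
      dimnames = list(feats, cells))
    count_matrix(m, kind)
  }
  summary <- if ("assign_class" %in% names(mol))
    mol[, .N, by = assign_class] else data.table()
  list(gene = make(asg, "gene_id", "gene"),
       exon = make(asg[!is.na(exon_id)], "exon_id", "exon"),
       assignment_summary = summary)
}

#' Intronic read fraction per replicate with a two-group t test
#'
#' For one gene, computes per-replicate intronic fractions (gene-assigned
#' molecules with no exon assignment over all gene-assigned molecules), the
#' per-condition mean and SEM, and an unpaired two-sided t test across
#' replicate fractions.
#'
#' @param molecules assigned molecules (`gene_id`, `exon_id`, `sample_id`)
#' @param gene gene id
#' @param design data.table mapping `sample_id` to `condition`
#' @return list with `per_replicate`, `group_stats`, `p_value` (NA when fewer
#'   than two replicates per group remain)
#' @export
intronic_fraction_test <- function(molecules, gene, design) {
  mol <- as.data.table(molecules)[gene_id == gene]
  design <- as.data.table(design)
  per <- mol[, .(n_total = .N, n_intronic = sum(is.na(exon_id))), by = sample_id]
  per <- merge(design, per, by = "sample_id", all.x = TRUE)
  zero <- per[is.na(n_total) | n_total == 0L, sample_id]
  if (length(zero))
    warnf("replicates with no molecules for %s excluded: %s", gene,
          paste(zero, collapse = ", "))
  per <- per[!is.na(n_total) & n_total > 0L]
  per[, intron_fraction := n_intronic / n_total]
  gs <- per[, .(mean = mean(intron_fraction),
                sem = sd(intron_fraction) / sqrt(.N), n = .N), by = condition]
  p <- if (nrow(gs) == 2L && all(gs$n >= 2L)) {
    grp <- split(per$intron_fraction, per$condition)
    if (sd(per$intron_fraction) == 0) 1
    else t.test(grp[[1]], grp[[2]], var.equal = FALSE)$p.value
  } else NA_real_
  list(per_replicate = per[], group_stats = gs[], p_value = p)
}
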