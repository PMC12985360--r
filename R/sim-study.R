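#' Generate the simulated cell population and ground truth
#'
#' Draws replicate/condition/subtype labels and barcode combinations for every
#' cell, flags doublets at the configured rate (a doublet barcode receives the
#' molecules of two independently drawn cells), and draws the study's ground
#' truth: per-gene condition effects, per-exon usage shifts (including exons
#' forced to oppose their parent gene's direction), per-gene intronic read
#' fractions (condition-dependent for splicing-shift genes), splicing-factor
#' identities and CLIP target membership.
#'
#' True effects are drawn first and counts sampled afterwards (gamma-Poisson),
#' so estimates recover the recorded truth only within sampling error. The
#' truth table records both the drawn gene effect (`true_log2fc`) and the
#' realized mean-model log2 fold change per subtype
#' (`realized_log2fc_<subtype>`), which accounts for the compositional shift
#' that library-size normalisation induces.
#'
#' @param cfg a [sim_config()]
#' @param ann result of [generate_annotation()] (for the exon structure)
#' @return list with `cells` (one row per cell) and `truth` (list of
#'   `genes`, `exons`, `clip_targets` data.tables)
#' @export
generate_cell_population <- function(cfg, ann) {
  validate_sim_config(cfg)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, "population"))

  gene_ids <- ann$db$genes$gene_id
  n_genes <- length(gene_ids)
  subtypes <- cfg$subtypes

  ## ---- gene-level truth -------------------------------------------------
  base_w <- rlnorm(n_genes, meanlog = 0, sdlog = 1)
  marker_subtype <- rep(NA_character_, n_genes)
  # leave room for splice-shift and splicing-factor genes in small gene sets
  reserve <- cfg$n_splice_shift_genes + cfg$n_splicing_factors + 2L
  n_mark <- min(cfg$n_marker_genes,
                max(0L, (n_genes - reserve) %/% length(subtypes)))
  free <- seq_len(n_genes)
  for (s in subtypes) {
    pick <- sample(free, min(n_mark, length(free)))
    marker_subtype[pick] <- s
    free <- setdiff(free, pick)
  }
  n_de <- round(cfg$gene_de_fraction * n_genes)
  de_idx <- sample(seq_len(n_genes), n_de)
  fc <- numeric(n_genes)
  fc[de_idx] <- sample(cfg$gene_log2fc, n_de, replace = TRUE) *
    sample(c(-1, 1), n_de, replace = TRUE)

  # splicing-shift genes: condition-dependent intron fraction, gene-level
  # decline with age (exon signal can then rise against the gene trend)
  shift_idx <- sample(setdiff(seq_len(n_genes), which(!is.na(marker_subtype))),
                      cfg$n_splice_shift_genes)
  fc[shift_idx] <- -1
  intron_y <- runif(n_genes, cfg$intron_fraction_range[1], cfg$intron_fraction_range[2])
  intron_a <- intron_y
  intron_y[shift_idx] <- cfg$splice_shift_fractions[["young"]]
  intron_a[shift_idx] <- cfg$splice_shift_fractions[["aged"]]

  # splicing factors: DE-up genes outside markers/splice-shift set
  sf_idx <- sample(setdiff(seq_len(n_genes),
                           c(which(!is.na(marker_subtype)), shift_idx)),
                   cfg$n_splicing_factors)
  fc[sf_idx] <- abs(cfg$gene_log2fc[length(cfg$gene_log2fc)])

  genes <- data.table(
    gene_id = gene_ids, base_weight = base_w, marker_subtype = marker_subtype,
    true_log2fc = fc, is_deg_true = fc != 0,
    is_splice_shift = seq_len(n_genes) %in% shift_idx,
    is_splicing_factor = seq_len(n_genes) %in% sf_idx,
    intron_fraction_young = intron_y, intron_fraction_aged = intron_a)

  # realized per-subtype gene log2FC of the normalised mean model
  for (s in subtypes) {
    w_s <- base_w * ifelse(!is.na(marker_subtype) & marker_subtype == s,
                           cfg$marker_boost, 1)
    wy <- w_s; wa <- w_s * 2^fc
    realized <- fc - log2(sum(wa) / sum(wy))
    genes[, paste0("realized_log2fc_", s) := realized]
  }

  ## ---- exon-level truth -------------------------------------------------
  ex <- copy(ann$db$exons)[, .(exon_id, gene_id)]
  ex[, usage_young := {
    g <- stats::rgamma(.N, shape = 5); g / sum(g)
  }, by = gene_id]
  n_ex_de <- round(cfg$exon_de_fraction * nrow(ex))
  usage_shift <- numeric(nrow(ex))
  de_ex <- sample(seq_len(nrow(ex)), n_ex_de)
  usage_shift[de_ex] <- sample(cfg$exon_log2fc, n_ex_de, replace = TRUE) *
    sample(c(-1, 1), n_ex_de, replace = TRUE)
  # force a fraction of shifted exons in DE genes to oppose the gene trend
  parent_fc <- genes$true_log2fc[match(ex$gene_id, genes$gene_id)]
  in_de_gene <- de_ex[parent_fc[de_ex] != 0]
  n_opp <- round(cfg$opposed_exon_fraction * length(in_de_gene))
  if (n_opp > 0L) {
    opp <- sample(in_de_gene, n_opp)
    usage_shift[opp] <- -sign(parent_fc[opp]) *
      (abs(parent_fc[opp]) + max(cfg$exon_log2fc))
  }
  ex[, usage_shift := usage_shift]
  ex[, usage_aged := {
    u <- usage_young * 2^usage_shift; u / sum(u)
  }, by = gene_id]

  gmap <- genes[, .(gene_id, true_log2fc, intron_fraction_young, intron_fraction_aged)]
  ex <- merge(ex, gmap, by = "gene_id", sort = FALSE)
  ex[, delta_log2fc := log2((1 - intron_fraction_aged) * usage_aged) -
                       log2((1 - intron_fraction_young) * usage_young)]
  ex[, exon_log2fc := true_log2fc + delta_log2fc]
  ex[, is_dee_true := abs(exon_log2fc) > 0.25]
  ex[, opposed := is_dee_true & true_log2fc != 0 &
       sign(exon_log2fc) != sign(true_log2fc)]
  exons <- ex[, .(exon_id, gene_id, usage_young, usage_aged, usage_shift,
                  delta_log2fc, exon_log2fc, is_dee_true, opposed)]

  ## ---- CLIP targets -----------------------------------------------------
  dee_parents <- unique(exons[is_dee_true == TRUE, gene_id])
  clip <- rbindlist(lapply(gene_ids[sf_idx], function(f) {
    p <- ifelse(gene_ids %in% dee_parents,
                pmin(1, cfg$clip_target_rate * cfg$clip_target_odds),
                cfg$clip_target_rate)
    hit <- runif(n_genes) < p
    hit[gene_ids == f] <- FALSE
    data.table(factor_id = f, gene_id = gene_ids[hit])
  }))

  ## ---- cells ------------------------------------------------------------
  rt_wl <- barcode_whitelist(96L, cfg$barcode_length, "rt")
  lig_wl <- barcode_whitelist(96L, cfg$barcode_length, "ligation")
  n_rep <- cfg$replicates_per_condition
  samples <- CJ(condition = cfg$conditions, replicate = seq_len(n_rep),
                sorted = FALSE)
  samples[, sample_id := paste0(condition, "_r", replicate)]
  rt_per_sample <- split(rt_wl[seq_len(nrow(samples) * (96L %/% nrow(samples)))],
                         rep(seq_len(nrow(samples)), each = 96L %/% nrow(samples)))

  cell_list <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    nc <- cfg$n_cells_per_replicate
    rts <- rt_per_sample[[i]]
    combos <- CJ(rt_bc = rts, lig_bc = lig_wl, sorted = FALSE)
    if (nc > nrow(combos)) stopf("too many cells per replicate for the barcode space")
    combos <- combos[sample(.N, nc)]
    cell_list[[i]] <- data.table(
      sample_id = samples$sample_id[i], condition = samples$condition[i],
      replicate = samples$replicate[i], rt_bc = combos$rt_bc,
      lig_bc = combos$lig_bc)
  }
  cells <- rbindlist(cell_list)
  cells[, cell_id := paste(rt_bc, lig_bc, sep = ".")]
  # subtype draw per condition
  for (cond in cfg$conditions) {
    idx <- which(cells$condition == cond)
    cells[idx, subtype := sample(subtypes, length(idx), replace = TRUE,
                                 prob = cfg$subtype_props[[cond]])]
  }
  cells[, size_factor := rlnorm(.N, meanlog = 0, sdlog = cfg$umi_sd_log)]
  cells[, is_doublet := runif(.N) < cfg$doublet_rate]
  cells[, partner_subtype := NA_character_]
  cells[, partner_size_factor := NA_real_]
  for (cond in cfg$conditions) {
    idx <- which(cells$condition == cond & cells$is_doublet)
    if (length(idx)) {
      cells[idx, partner_subtype := sample(subtypes, length(idx), replace = TRUE,
                                           prob = cfg$subtype_props[[cond]])]
      cells[idx, partner_size_factor := rlnorm(length(idx), 0, cfg$umi_sd_log)]
    }
  }
  setcolorder(cells, c("cell_id", "sample_id", "condition", "replicate",
                       "rt_bc", "lig_bc", "subtype", "is_doublet"))

  list(cells = cells,
       truth = list(genes = genes, exons = exons, clip_targets = clip,
                    rt_to_sample = data.table(
                      rt_bc = unlist(rt_per_sample),
                      sample_id = rep(samples$sample_id,
                                      lengths(rt_per_sample)))))
}

#' Simulate molecules and aligned reads for a cell population
#'
#' Draws per-cell, per-gene molecule counts from the negative-binomial mean
#' model, splits each gene's molecules across its merged exons and intronic
#' space with per-condition probabilities, places each molecule's aligned
#' footprint inside the chosen feature, attaches UMI, barcodes, primer type
#' and tagmentation site, emits PCR duplicates at the configured rate, and
#' injects single-substitution barcode errors.
#'
#' @param population result of [generate_cell_population()]
#' @param ann result of [generate_annotation()]
#' @param cfg the same [sim_config()]
#' @return list with `molecules` (one row per true molecule) and `reads`
#'   (one row per read; PCR copies share all molecule fields)
#' @export
simulate_reads <- function(population, ann, cfg) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, "reads"))

  cells <- population$cells
  truth <- population$truth
  genes <- truth$genes
  n_genes <- nrow(genes)

  # one expression profile per cell, two for doublets
  prof <- rbindlist(list(
    cells[, .(cell_id, sample_id, condition, replicate, rt_bc, lig_bc,
              subtype, size_factor)],
    cells[is_doublet == TRUE,
          .(cell_id, sample_id, condition, replicate, rt_bc, lig_bc,
            subtype = partner_subtype, size_factor = partner_size_factor)]))

  ## per-profile, per-gene counts
  mol_list <- list()
  for (s in cfg$subtypes) {
    w_s <- genes$base_weight *
      ifelse(!is.na(genes$marker_subtype) & genes$marker_subtype == s,
             cfg$marker_boost, 1)
    for (cond in cfg$conditions) {
      w <- if (cond == cfg$conditions[1]) w_s else w_s * 2^genes$true_log2fc
      p <- w / sum(w)
      pr <- prof[subtype == s & condition == cond]
      if (!nrow(pr)) next
      mu <- outer(pr$size_factor * cfg$mean_umis_per_cell, p)  # cells x genes
      cnt <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
                    nrow = nrow(mu))
      nz <- which(cnt > 0, arr.ind = TRUE)
      if (!nrow(nz)) next
      mol_list[[length(mol_list) + 1L]] <- data.table(
        cell_row = rep(nz[, 1], cnt[nz]) , gene_idx = rep(nz[, 2], cnt[nz]),
        prof_key = paste0(s, ".", cond))[
          , .(cell_id = pr$cell_id[cell_row], sample_id = pr$sample_id[cell_row],
              condition = cond, replicate = pr$replicate[cell_row],
              rt_bc = pr$rt_bc[cell_row], lig_bc = pr$lig_bc[cell_row],
              subtype = s, gene_id = genes$gene_id[gene_idx])]
    }
  }
  mol <- rbindlist(mol_list)
  setorder(mol, cell_id, gene_id)
  mol[, molecule_id := seq_len(.N)]

  ## split molecules into exon / intron categories per gene x condition
  exons <- ann$db$exons
  ex_truth <- truth$exons
  mol[, exon_id := NA_character_]
  for (g in genes$gene_id) {
    exg <- ex_truth[gene_id == g]
    for (cond in cfg$conditions) {
      rows <- which(mol$gene_id == g & mol$condition == cond)
      if (!length(rows)) next
      ref <- cond == cfg$conditions[1]   # "young" columns = first condition
      p_int <- if (ref) genes$intron_fraction_young[genes$gene_id == g]
               else genes$intron_fraction_aged[genes$gene_id == g]
      u <- if (ref) exg$usage_young else exg$usage_aged
      cat <- sample(c(NA_character_, exg$exon_id), length(rows), replace = TRUE,
                    prob = c(p_int, (1 - p_int) * u))
      mol[rows, exon_id := cat]
    }
  }

  ## genomic placement
  rl <- cfg$read_length
  gtab <- ann$db$genes
  mol <- merge(mol, gtab[, .(gene_id, chrom, strand)], by = "gene_id", sort = FALSE)
  # exonic molecules: uniform start within the exon
  mol <- merge(mol, exons[, .(exon_id, ex_start = start, ex_end = end)],
               by = "exon_id", all.x = TRUE, sort = FALSE)
  is_ex <- !is.na(mol$exon_id)
  mol[is_ex, start := ex_start +
        floor(runif(sum(is_ex)) * pmax(1L, ex_end - ex_start + 1L - rl + 1L))]
  # intronic molecules: length-weighted intron, uniform start within it
  introns <- exons[, {
    o <- order(start)
    s <- start[o]; e <- end[o]
    if (.N > 1L) list(i_start = e[-.N] + 1L, i_end = s[-1L] - 1L)
    else list(i_start = integer(0), i_end = integer(0))
  }, by = gene_id]
  introns <- introns[i_end - i_start + 1L >= rl]
  for (g in unique(mol[!is_ex, gene_id])) {
    rows <- which(!is_ex & mol$gene_id == g)
    ig <- introns[gene_id == g]
    if (!nrow(ig)) { # no intron can hold a read: place in first exon instead
      exg <- exons[gene_id == g][1]
      mol[rows, start := exg$start +
            floor(runif(length(rows)) * (exg$end - exg$start + 1L - rl + 1L))]
      mol[rows, exon_id := NA_character_]
      next
    }
    wl <- ig$i_end - ig$i_start + 1L - rl + 1L
    pick <- sample(seq_len(nrow(ig)), length(rows), replace = TRUE,
                   prob = wl / sum(wl))
    mol[rows, start := ig$i_start[pick] + floor(runif(length(rows)) * wl[pick])]
  }
  mol[, start := as.integer(start)]
  mol[, end := start + rl - 1L]
  mol[, c("ex_start", "ex_end") := NULL]

  ## molecule identity fields
  mol[, umi := random_dna(.N, cfg$umi_length)]
  mol[, primer := ifelse(runif(.N) < cfg$dt_primer_fraction, "dT", "hexamer")]
  mol[, tag_chrom := chrom]
  mol[, tag_pos := start]
  mol[, tag_strand := strand]
  setcolorder(mol, c("molecule_id", "cell_id", "sample_id", "condition",
                     "replicate", "subtype", "gene_id", "exon_id", "chrom",
                     "start", "end", "strand"))

  ## PCR duplication and barcode errors
  copies <- 1L + rpois(nrow(mol), cfg$umi_duplication_rate - 1)
  read_cols <- c("molecule_id", "chrom", "start", "end", "strand", "rt_bc",
                 "lig_bc", "umi", "primer", "tag_chrom", "tag_pos",
                 "tag_strand")
  reads <- mol[rep(seq_len(nrow(mol)), copies), read_cols, with = FALSE]
  reads[, read_id := seq_len(.N)]
  err <- runif(nrow(reads)) < cfg$barcode_error_rate
  if (any(err)) {
    which_bc <- runif(sum(err)) < 0.5
    ri <- which(err)
    rt_rows <- ri[which_bc]; lig_rows <- ri[!which_bc]
    if (length(rt_rows)) reads[rt_rows, rt_bc := mutate_barcode(rt_bc)]
    if (length(lig_rows)) reads[lig_rows, lig_bc := mutate_barcode(lig_bc)]
  }
  list(molecules = mol, reads = reads)
}

#' Run the whole synthetic study generator
#'
#' Convenience wrapper: annotation, population + truth, molecules and reads,
#' all from one config and seed.
#'
#' @param cfg a [sim_config()]
#' @return list with `config`, `annotation`, `cells`, `truth`, `molecules`,
#'   `reads`
#' @export
simulate_study <- function(cfg = sim_config()) {
  ann <- generate_annotation(cfg)
  pop <- generate_cell_population(cfg, ann)
  rd <- simulate_reads(pop, ann, cfg)
  list(config = cfg, annotation = ann, cells = pop$cells, truth = pop$truth,
       molecules = rd$molecules, reads = rd$reads)
}

#' Write machine-readable ground truth tables
#'
#' Emits TSV files (genes, exons, cells, clip_targets, molecules) used by
#' parameter-recovery tests.
#'
#' @param study result of [simulate_study()]
#' @param dir output directory
#' @return named vector of file paths
#' @export
emit_truth <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genes = file.path(dir, "truth_genes.tsv"),
             exons = file.path(dir, "truth_exons.tsv"),
             cells = file.path(dir, "truth_cells.tsv"),
             clip_targets = file.path(dir, "truth_clip_targets.tsv"),
             molecules = file.path(dir, "truth_molecules.tsv"))
  fwrite(study$truth$genes, paths["genes"], sep = "\t")
  fwrite(study$truth$exons, paths["exons"], sep = "\t")
  fwrite(study$cells, paths["cells"], sep = "\t")
  fwrite(study$truth$clip_targets, paths["clip_targets"], sep = "\t")
  fwrite(study$molecules[, .(molecule_id, cell_id, gene_id, exon_id)],
         paths["molecules"], sep = "\t")
  paths
}
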