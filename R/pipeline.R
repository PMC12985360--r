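#' Pipeline configuration
#'
#' One config drives the end-to-end run. By default the pipeline simulates
#' the packaged synthetic study; supply `study = NULL` and input paths to run
#' on external data written in the same formats.
#'
#' @param out_dir run directory (created; stage outputs + manifest inside)
#' @param seed global seed; per-stage seeds are derived with [derive_seed()]
#' @param sim a [sim_config()] for the synthetic study (its own seed is
#'   overridden by `seed`)
#' @param qc a [qc_config()]
#' @param assign an [assign_config()]
#' @param de a [de_config()]
#' @param de_groups subtypes tested young-vs-aged (default the two mature
#'   subtypes)
#' @param abundance_k,abundance_fraction,abundance_threshold neighborhood
#'   parameters (k = 60; labeling threshold 0.705)
#' @param n_probe_transcripts transcripts given probe sets in the probe stage
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(out_dir = tempfile("exonsci_run_"),
                            seed = 1L,
                            sim = sim_config(),
                            qc = qc_config("brain"),
                            assign = assign_config(),
                            de = de_config(),
                            de_groups = c("MOL2", "MOL56"),
                            abundance_k = 60L,
                            abundance_fraction = 0.1,
                            abundance_threshold = 0.705,
                            n_probe_transcripts = 3L) {
  sim$seed <- as.integer(seed)
  qc$seed <- derive_seed(seed, "doublets")
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 qc = qc, assign = assign, de = de, de_groups = de_groups,
                 abundance_k = as.integer(abundance_k),
                 abundance_fraction = abundance_fraction,
                 abundance_threshold = abundance_threshold,
                 n_probe_transcripts = as.integer(n_probe_transcripts)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `sim`, `qc`,
#' `assign` and `de` entries are passed to their constructors.
#'
#' @param path YAML file
#' @return a [pipeline_config()]
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("out_dir", "seed", "de_groups", "abundance_k",
               "abundance_fraction", "abundance_threshold",
               "n_probe_transcripts"))
    if (!is.null(y[[nm, exact = TRUE]])) args[[nm]] <- y[[nm]]
  if (!is.null(y[["sim"]])) args$sim <- do.call(sim_config, y[["sim"]])
  if (!is.null(y[["qc"]])) args$qc <- do.call(qc_config, y[["qc"]])
  if (!is.null(y[["assign"]])) args$assign <- do.call(assign_config, y[["assign"]])
  if (!is.null(y[["de"]])) args$de <- do.call(de_config, y[["de"]])
  do.call(pipeline_config, args)
}

write_mtx <- function(mat, dir, prefix) {
  Matrix::writeMM(mat$counts, file.path(dir, paste0(prefix, "_matrix.mtx")))
  writeLines(rownames(mat$counts), file.path(dir, paste0(prefix, "_features.tsv")))
  writeLines(colnames(mat$counts), file.path(dir, paste0(prefix, "_barcodes.tsv")))
}

#' Run the full pipeline
#'
#' Stage order: simulate, process (demultiplex + deduplicate + quantify),
#' qc, de, domains, splice_enrich, abundance, probes. Each stage writes its
#' outputs under `out_dir` and registers them (with md5 checksums and
#' parameters) in `manifest.yaml`. Reruns with an identical config reproduce
#' identical outputs. A stage failure aborts with the stage name; outputs of
#' completed stages are retained.
#'
#' @param config a [pipeline_config()]
#' @return (invisibly) list with all in-memory stage results and `manifest`
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  res <- list(config = config)
  t0 <- Sys.time()
  register <- function(stage, files, params = list()) {
    manifest$stages[[stage]] <<- list(
      outputs = as.list(setNames(unname(tools::md5sum(files)), basename(files))),
      params = params)
    yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e)
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  ## -- simulate ----------------------------------------------------------
  run_stage("simulate", function() {
    res$study <<- simulate_study(config$sim)
    ad <- file.path(config$out_dir, "simulate")
    paths <- write_annotation(res$study$annotation, ad)
    tpaths <- emit_truth(res$study, ad)
    fwrite(res$study$truth$clip_targets, file.path(ad, "clip_targets.tsv"), sep = "\t")
    register("simulate", c(paths, tpaths),
             params = list(seed = config$sim$seed,
                           n_cells = nrow(res$study$cells)))
  })

  ## -- process: demultiplex, deduplicate, quantify ------------------------
  run_stage("process", function() {
    study <- res$study
    dmx_cfg <- demux_config(
      rt_whitelist = barcode_whitelist(96L, config$sim$barcode_length, "rt"),
      lig_whitelist = barcode_whitelist(96L, config$sim$barcode_length, "ligation"),
      rt_to_sample = study$truth$rt_to_sample)
    dmx <- demultiplex(study$reads, dmx_cfg)
    mols <- deduplicate(dmx$assigned)
    index <- build_feature_index(study$annotation$db)
    asg <- assign_exon(assign_gene(mols, index, config$assign), index)
    asg[, cell_id := paste(rt_bc, lig_bc, sep = ".")]
    mats <- build_matrices(asg[!is.na(gene_id)])
    pd <- file.path(config$out_dir, "process")
    dir.create(pd, showWarnings = FALSE)
    write_mtx(mats$gene, pd, "gene")
    write_mtx(mats$exon, pd, "exon")
    fwrite(mats$assignment_summary, file.path(pd, "assignment_summary.tsv"), sep = "\t")
    fwrite(dmx$rejected[, .N, by = reason], file.path(pd, "rejections.tsv"), sep = "\t")
    res$demux <<- list(n_assigned = nrow(dmx$assigned), n_rejected = nrow(dmx$rejected))
    res$molecules <<- asg
    res$matrices <<- mats
    n_reads <- nrow(study$reads); n_molecules <- nrow(mols)
    # free the raw reads to bound memory; simulate_study(config$sim)
    # regenerates them bit-identically from the seed
    res$study$reads <<- NULL
    rm(study, dmx, mols); gc(FALSE)
    register("process", list.files(pd, full.names = TRUE),
             params = list(n_reads = n_reads, n_molecules = n_molecules))
  })

  ## -- qc ------------------------------------------------------------------
  run_stage("qc", function() {
    flt <- filter_cells(res$matrices$gene, config$qc)
    ds <- doublet_scores(flt$matrix, config$qc)
    keep <- ds[is_doublet_call == FALSE, cell_id]
    res$qc <<- list(filter = flt, doublets = ds, kept_cells = keep)
    res$gene_mat <<- subset_cells(flt$matrix, keep)
    res$exon_mat <<- subset_cells(res$matrices$exon, keep)
    qd <- file.path(config$out_dir, "qc")
    dir.create(qd, showWarnings = FALSE)
    fwrite(flt$report, file.path(qd, "qc_report.tsv"), sep = "\t")
    fwrite(ds, file.path(qd, "doublet_scores.tsv"), sep = "\t")
    register("qc", list.files(qd, full.names = TRUE),
             params = list(min_umis = config$qc$min_umis,
                           n_kept = length(keep)))
  })

  ## -- de -------------------------------------------------------------------
  run_stage("de", function() {
    cells <- res$study$cells
    meta <- cells[match(colnames(res$gene_mat$counts), cells$cell_id)]
    dd <- file.path(config$out_dir, "de")
    dir.create(dd, showWarnings = FALSE)
    de_list <- list()
    for (g in config$de_groups) {
      sel <- meta[subtype == g, cell_id]
      gm <- subset_cells(res$gene_mat, sel)
      em <- subset_cells(res$exon_mat, sel)
      labs <- setNames(factor(meta$condition, levels = config$sim$conditions),
                       meta$cell_id)
      tab <- call_and_classify(
        run_combined_de(gm, em, labs[colnames(gm$counts)], config$de), config$de)
      fwrite(tab, file.path(dd, paste0("de_", g, ".tsv")), sep = "\t")
      de_list[[g]] <- tab
    }
    res$de <<- de_list
    if (length(de_list) >= 2L) {
      res$shared_deg <<- shared_logfc_correlation(de_list[[1]], de_list[[2]], "is_deg")
      res$shared_dee <<- shared_logfc_correlation(de_list[[1]], de_list[[2]], "is_dee")
    }
    # intron-fraction contrast for the splicing-shift genes
    shift_genes <- res$study$truth$genes[is_splice_shift == TRUE, gene_id]
    design <- unique(cells[, .(sample_id, condition)])
    mol_kept <- res$molecules[cell_id %in% colnames(res$gene_mat$counts)]
    mol_kept[, sample_id := res$study$cells$sample_id[
      match(cell_id, res$study$cells$cell_id)]]
    res$intron_tests <<- lapply(setNames(shift_genes, shift_genes), function(g)
      intronic_fraction_test(mol_kept, g, design))
    itab <- rbindlist(lapply(res$intron_tests, function(x)
      cbind(x$per_replicate, p_value = x$p_value)), idcol = "gene_id")
    fwrite(itab, file.path(dd, "intron_fractions.tsv"), sep = "\t")
    register("de", list.files(dd, full.names = TRUE),
             params = list(groups = config$de_groups))
  })

  ## -- domains ---------------------------------------------------------------
  run_stage("domains", function() {
    dees <- unique(unlist(lapply(res$de, function(t)
      as.data.table(t)[is_dee == TRUE, feature_id])))
    hits <- map_dees_to_domains(dees, res$study$annotation$db,
                                res$study$annotation$domains)
    res$domain_hits <<- hits
    dd <- file.path(config$out_dir, "domains")
    dir.create(dd, showWarnings = FALSE)
    fwrite(hits, file.path(dd, "dee_domain_hits.tsv"), sep = "\t")
    if (nrow(hits))
      fwrite(summarise_domain_hits(hits), file.path(dd, "dee_domain_summary.tsv"),
             sep = "\t")
    register("domains", list.files(dd, full.names = TRUE),
             params = list(n_dees = length(dees)))
  })

  ## -- splice_enrich ---------------------------------------------------------
  run_stage("splice_enrich", function() {
    tab1 <- res$de[[1]]
    sf_set <- res$study$truth$genes[is_splicing_factor == TRUE, gene_id]
    de_sf <- select_de_splicing_factors(tab1, sf_set)
    universe <- as.data.table(tab1)[kind == "gene", feature_id]
    dee_parents <- unique(as.data.table(tab1)[is_dee == TRUE, parent_gene])
    dee_parents <- intersect(dee_parents, universe)
    enr <- fisher_target_enrichment(dee_parents, universe,
                                    res$study$truth$clip_targets)
    res$splice_enrichment <<- list(de_factors = de_sf, enrichment = enr)
    sd <- file.path(config$out_dir, "splice_enrich")
    dir.create(sd, showWarnings = FALSE)
    fwrite(de_sf, file.path(sd, "de_splicing_factors.tsv"), sep = "\t")
    fwrite(enr, file.path(sd, "target_enrichment.tsv"), sep = "\t")
    register("splice_enrich", list.files(sd, full.names = TRUE),
             params = list(n_factors = length(sf_set)))
  })

  ## -- abundance --------------------------------------------------------------
  run_stage("abundance", function() {
    emb <- pca_embed(res$gene_mat, 2L)
    nh <- build_neighborhoods(emb, k = config$abundance_k,
                              sample_fraction = config$abundance_fraction,
                              seed = derive_seed(config$seed, "nhoods"))
    cells <- res$study$cells
    samp <- setNames(cells$sample_id, cells$cell_id)
    cond <- setNames(cells$condition, cells$cell_id)
    design <- unique(cells[, .(sample_id, condition)])
    da <- test_neighborhood_abundance(nh, samp, design, config$de)
    lab <- expand_and_label(nh, cond, threshold = config$abundance_threshold)
    res$abundance <<- list(nhoods = nh, da = da, labels = lab)
    ad <- file.path(config$out_dir, "abundance")
    dir.create(ad, showWarnings = FALSE)
    fwrite(data.table(cell_id = rownames(emb), x = emb[, 1], y = emb[, 2]),
           file.path(ad, "embedding.tsv"), sep = "\t")
    fwrite(da, file.path(ad, "neighborhood_da.tsv"), sep = "\t")
    fwrite(lab, file.path(ad, "neighborhood_labels.tsv"), sep = "\t")
    register("abundance", list.files(ad, full.names = TRUE),
             params = list(k = config$abundance_k,
                           threshold = config$abundance_threshold))
  })

  ## -- probes ------------------------------------------------------------------
  run_stage("probes", function() {
    seqs <- res$study$annotation$transcript_seqs
    pick <- head(names(seqs)[order(-Biostrings::width(seqs))],
                 config$n_probe_transcripts)
    pcfg <- probe_config()
    sets <- rbindlist(lapply(pick, function(tid) {
      cand <- enumerate_candidates(seqs[[tid]], pcfg, transcript_id = tid)
      if (!any(cand$pass)) return(cand[0])
      tryCatch(select_module_set(cand, config = pcfg), error = function(e) cand[0])
    }))
    res$probes <<- sets
    pd <- file.path(config$out_dir, "probes")
    dir.create(pd, showWarnings = FALSE)
    fwrite(sets, file.path(pd, "probe_sets.tsv"), sep = "\t")
    if (nrow(sets)) export_probe_fasta(sets, file.path(pd, "probe_candidates.fa"))
    register("probes", list.files(pd, full.names = TRUE),
             params = list(n_transcripts = length(pick)))
  })

  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  res$manifest <- manifest
  invisible(res)
}

#' Generate the packaged demo study and its checksums
#'
#' Produces the default synthetic study (two age conditions, three replicate
#' animals each, ~3,000 barcodes pre-QC), writes its artifacts to `dir` and
#' returns md5 checksums so reruns can be compared.
#'
#' @param seed integer seed
#' @param dir output directory
#' @return list with `study`, `files`, `checksums`
#' @export
make_demo <- function(seed = 1L, dir = tempfile("exonsci_demo_")) {
  cfg <- sim_config(seed = as.integer(seed))
  study <- simulate_study(cfg)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_annotation(study$annotation, dir)
  tpaths <- emit_truth(study, dir)
  sam <- file.path(dir, "reads.sam")
  write_sam(study$reads, sam)
  files <- c(paths, tpaths, reads = sam)
  list(study = study, files = files, checksums = tools::md5sum(files))
}
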