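#' Map differentially expressed exons to protein domains
#'
#' For every (DEE, transcript-of-parent-gene) pair with an in-frame CDS, the
#' exon's genomic interval is converted to its amino-acid footprint with
#' [genomic_to_protein()] and intersected with the transcript's annotated
#' domain intervals; one hit is emitted per overlapping domain (minimum
#' overlap 1 aa). Exons touching no coding base (UTR/intron-only) emit
#' nothing, as do transcripts absent from the domain table.
#'
#' @param dees character vector of exon ids (`gene:index`) to map
#' @param db an [annotation_db()]
#' @param domains data.table (transcript_id, domain_name, aa_start, aa_end;
#'   1-based inclusive)
#' @return data.table of hits: exon_id, transcript_id, exon aa footprint,
#'   domain name and interval, overlap_aa; sorted by (exon, transcript,
#'   domain)
#' @export
map_dees_to_domains <- function(dees, db, domains) {
  domains <- as.data.table(domains)
  ex <- db$exons[exon_id %in% dees]
  hits <- list()
  for (i in seq_len(nrow(ex))) {
    e <- ex[i]
    txs <- db$transcripts[gene_id == e$gene_id & coding == TRUE, transcript_id]
    for (tid in txs) {
      aa <- genomic_to_protein(db, tid, e$start, e$end)
      if (is.null(aa)) next
      dom <- domains[transcript_id == tid]
      if (!nrow(dom)) next
      ov_s <- pmax(aa[1], dom$aa_start); ov_e <- pmin(aa[2], dom$aa_end)
      sel <- ov_s <= ov_e
      if (!any(sel)) next
      hits[[length(hits) + 1L]] <- data.table(
        exon_id = e$exon_id, transcript_id = tid,
        exon_aa_start = aa[[1]], exon_aa_end = aa[[2]],
        domain_name = dom$domain_name[sel],
        domain_aa_start = dom$aa_start[sel], domain_aa_end = dom$aa_end[sel],
        overlap_aa = (ov_e - ov_s + 1L)[sel])
    }
  }
  out <- if (length(hits)) rbindlist(hits) else data.table(
    exon_id = character(0), transcript_id = character(0),
    exon_aa_start = integer(0), exon_aa_end = integer(0),
    domain_name = character(0), domain_aa_start = integer(0),
    domain_aa_end = integer(0), overlap_aa = integer(0))
  setorder(out, exon_id, transcript_id, domain_name)
  out[]
}

#' Summarise domain hits per exon
#'
#' One row per DEE listing the union of domain names it maps to across
#' isoforms.
#'
#' @param hits output of [map_dees_to_domains()]
#' @return data.table: exon_id, n_domains, domain names (comma separated)
#' @export
summarise_domain_hits <- function(hits) {
  as.data.table(hits)[, .(n_domains = data.table::uniqueN(domain_name),
                          domains = paste(sort(unique(domain_name)),
                                          collapse = ",")),
                      by = exon_id]
}
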