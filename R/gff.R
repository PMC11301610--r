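# GFF3 / FASTA output for IES and breakpoint calls, plus a lenient reader
# for junction annotations.

.gff_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x
}

.gff_header <- function(params) {
  c("##gff-version 3",
    if (length(params)) {
      paste0("#", names(params), "=",
             vapply(params, function(v) paste(format(v), collapse = ","), ""))
    })
}

#' Write IES records to GFF3
#'
#' One feature per IES, type `internal_eliminated_sequence_junction`, with
#' 1-based `start == end` at the first MAC base after the junction (0-based
#' junction + 1). Run parameters passed in `params` are echoed as `#` header
#' comments for provenance.
#'
#' @param records IES record data.frame from [call_iess()] (`$records`).
#' @param path Output path.
#' @param params Optional named list of run parameters for the header.
#' @export
write_gff3 <- function(records, path, params = list()) {
  lines <- .gff_header(params)
  if (nrow(records)) {
    attrs <- sprintf(
      "ID=%s;IES_length=%d;pointer=%s;ta_bound=%s;support=%d;spanning_total=%d;retention_score=%s",
      .gff_escape(records$id), records$length, .gff_escape(records$pointer),
      ifelse(records$ta_bound, "true", "false"), records$support,
      records$spanning_total,
      ifelse(is.na(records$retention_score), "NA",
             sprintf("%.4f", records$retention_score)))
    lines <- c(lines, paste(
      records$contig, "iesweave", "internal_eliminated_sequence_junction",
      records$junction + 1L, records$junction + 1L,
      ifelse(is.na(records$retention_score), ".",
             sprintf("%.4f", records$retention_score)),
      ".", ".", attrs, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write called IES sequences to FASTA
#'
#' @inheritParams write_gff3
#' @export
write_ies_fasta <- function(records, path) {
  x <- Biostrings::DNAStringSet(records$ies_seq)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a cluster report to TSV
#'
#' @param clusters Cluster report from [call_iess()] (`$clusters`).
#' @param path Output path.
#' @param params Optional named list echoed as `#` comments.
#' @export
write_cluster_report <- function(clusters, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(params)) {
    writeLines(paste0("#", names(params), "=",
                      vapply(params, function(v) paste(format(v),
                                                       collapse = ","), "")),
               con)
  }
  utils::write.table(clusters, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read junction annotations from GFF3
#'
#' Accepts GFF3 written by [write_gff3()] or any ParTIES-style annotation of
#' IES junctions as zero-width features (`start == end`, the 1-based first
#' MAC base after the junction).
#'
#' @param path GFF3 file.
#' @return Data.frame with `contig` and 0-based `junction`, plus `id` when
#'   present.
#' @export
read_junction_gff <- function(path) {
  gr <- as.data.frame(rtracklayer::import(path, format = "gff3"))
  gr <- gr[gr$start == gr$end, , drop = FALSE]
  id <- if ("ID" %in% names(gr) && !all(is.na(gr$ID))) {
    as.character(gr$ID)
  } else {
    sprintf("junction_%d", seq_len(nrow(gr)))
  }
  out <- data.frame(
    id = id,
    contig = as.character(gr$seqnames),
    junction = gr$start - 1L
  )
  rownames(out) <- NULL
  out
}

#' Write chromosome breakage sites to GFF3
#'
#' One feature per site, type `chromosome_breakage_site`, 1-based
#' `start == end` at the base adjacent to the telomere addition.
#'
#' @param records Breakpoint data.frame from [call_breakpoints()].
#' @param path Output path.
#' @param params Optional named list echoed as `#` comments.
#' @export
write_breakpoint_gff <- function(records, path, params = list()) {
  lines <- .gff_header(params)
  if (nrow(records)) {
    attrs <- sprintf(
      "ID=BRK_%s_%d_%s;side=%s;support=%d;mean_motif_fraction=%.4f",
      .gff_escape(records$contig), records$position + 1L, records$side,
      records$side, records$support, records$mean_motif_fraction)
    lines <- c(lines, paste(
      records$contig, "iesweave", "chromosome_breakage_site",
      records$position + 1L, records$position + 1L,
      sprintf("%.4f", records$mean_motif_fraction), ".", ".", attrs,
      sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
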