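#' Per-site IES retention scores
#'
#' For every annotated junction, classifies every primary read spanning it
#' as retaining the IES (carries an insertion near the junction) or excised,
#' and reports the retention score: retained / (retained + excised). Sites
#' with no spanning read are reported with a missing score.
#'
#' @param bam Coordinate-sorted BAM of reads mapped to the MAC assembly.
#' @param annotation Data.frame with `contig` and 0-based `junction` columns
#'   (e.g. from [read_junction_gff()]).
#' @param buffer Spanning buffer in bp (default 15); both flanks of the
#'   junction must be covered for a read to count as spanning.
#' @param min_insert_len Minimum insertion length counted as retention.
#' @param min_mapq Minimum mapping quality.
#' @return Data.frame with one row per site: `contig`, `junction`,
#'   `ies_plus`, `ies_minus`, `score` (`NA` when no read spans the site).
#' @export
site_retention <- function(bam, annotation, buffer = 15L,
                           min_insert_len = 10L, min_mapq = 1L) {
  st <- .retention_status(bam, annotation, buffer, min_insert_len, min_mapq)
  out <- annotation[, c("contig", "junction")]
  out$ies_plus <- 0L
  out$ies_minus <- 0L
  if (nrow(st)) {
    key <- paste(st$contig, st$junction)
    okey <- paste(out$contig, out$junction)
    plus <- tapply(st$status == "retained", key, sum)
    tot <- tapply(rep(1L, nrow(st)), key, sum)
    i <- match(names(plus), okey)
    out$ies_plus[i] <- as.integer(plus)
    out$ies_minus[i] <- as.integer(tot) - as.integer(plus)
  }
  denom <- out$ies_plus + out$ies_minus
  out$score <- ifelse(denom > 0, out$ies_plus / denom, NA_real_)
  rownames(out) <- NULL
  out
}

#' Per-read IES retention scores
#'
#' For every primary read, counts the annotated IES sites it spans and the
#' subset at which the IES is retained; the per-read retention score is
#' their ratio. Reads from the germline (MIC) genome score near 1, somatic
#' (MAC) reads near 0. Reads spanning no annotated site are `"unscored"`.
#'
#' @inheritParams site_retention
#' @return Data.frame with one row per read that produced a primary
#'   alignment: `read_id`, `sites_spanned`, `sites_retained`,
#'   `per_read_score` (`NA` when unscored), `bin` (placeholder `"unscored"`
#'   until [bin_reads()] thresholds are applied).
#' @export
read_retention <- function(bam, annotation, buffer = 15L,
                           min_insert_len = 10L, min_mapq = 1L) {
  st <- .retention_status(bam, annotation, buffer, min_insert_len, min_mapq)
  aln <- read_alignments(bam, min_mapq = min_mapq)
  ids <- unique(aln$read_id)
  out <- data.frame(read_id = ids, sites_spanned = 0L, sites_retained = 0L)
  if (nrow(st)) {
    sp <- tapply(rep(1L, nrow(st)), st$read_id, sum)
    rt <- tapply(st$status == "retained", st$read_id, sum)
    i <- match(names(sp), out$read_id)
    out$sites_spanned[i] <- as.integer(sp)
    out$sites_retained[i] <- as.integer(rt)
  }
  out$per_read_score <- ifelse(out$sites_spanned > 0,
                               out$sites_retained / out$sites_spanned,
                               NA_real_)
  out$bin <- ifelse(out$sites_spanned > 0, "scored", "unscored")
  rownames(out) <- NULL
  out
}

# Spanning/retained status for every (read, site) pair, all contigs.
.retention_status <- function(bam, annotation, buffer, min_insert_len,
                              min_mapq) {
  stopifnot(all(c("contig", "junction") %in% names(annotation)))
  targets <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  absent <- setdiff(unique(annotation$contig), names(targets))
  if (length(absent)) {
    stop("annotation contig(s) absent from BAM header: ",
         paste(utils::head(absent, 5), collapse = ", "))
  }
  aln <- read_alignments(bam, min_mapq = min_mapq)
  rows <- lapply(unique(annotation$contig), function(ctg) {
    st <- .span_status_table(aln[aln$contig == ctg, , drop = FALSE],
                             sort(annotation$junction[annotation$contig == ctg]),
                             buffer, min_insert_len)
    if (is.null(st) || nrow(st) == 0L) return(NULL)
    st$contig <- ctg
    st
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(aln_idx = integer(0), read_id = character(0),
                      junction = integer(0), status = character(0),
                      contig = character(0))
  }
  out
}

#' Bin reads by per-read retention score
#'
#' Splits a sequence library into germline-like (`mic_like`, score >= `hi`),
#' somatic-like (`mac_like`, score <= `lo`) and `ambiguous` sets, for
#' example to enrich IES-containing reads before a germline-genome
#' assembly. Boundaries are inclusive outward. Unscored reads are omitted
#' (their count is reported in a message).
#'
#' @param records Output of [read_retention()].
#' @param reads Path to the read library (FASTA or FASTQ; FASTQ detected by
#'   extension `.fastq`/`.fq`).
#' @param out_prefix Output prefix; files `<prefix>.mic_like.<ext>`,
#'   `<prefix>.mac_like.<ext>`, `<prefix>.ambiguous.<ext>` are written in
#'   the input format.
#' @param hi,lo Binning thresholds (defaults 0.9 and 0.1, `lo < hi`).
#' @return Invisibly, a named integer vector of bin sizes.
#' @export
bin_reads <- function(records, reads, out_prefix, hi = 0.9, lo = 0.1) {
  stopifnot(lo < hi)
  fastq <- grepl("\\.(fastq|fq)(\\.gz)?$", reads, ignore.case = TRUE)
  # the quality-scaled reader warns that FASTQ metadata columns are
  # dropped during construction; nothing here uses them
  lib <- withCallingHandlers(
    if (fastq) {
      Biostrings::readQualityScaledDNAStringSet(reads)
    } else {
      Biostrings::readDNAStringSet(reads)
    },
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  names(lib) <- sub("\\s.*$", "", names(lib))
  scored <- records[records$sites_spanned > 0, , drop = FALSE]
  n_unscored <- sum(records$sites_spanned == 0)
  if (n_unscored > 0) {
    message(n_unscored, " unscored read(s) omitted from binning")
  }
  missing <- setdiff(scored$read_id, names(lib))
  if (length(missing)) {
    stop("scored read(s) absent from sequence source: ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  bin <- ifelse(scored$per_read_score >= hi, "mic_like",
                ifelse(scored$per_read_score <= lo, "mac_like", "ambiguous"))
  ext <- if (fastq) "fastq" else "fasta"
  counts <- integer(0)
  for (b in c("mic_like", "mac_like", "ambiguous")) {
    ids <- scored$read_id[bin == b]
    path <- sprintf("%s.%s.%s", out_prefix, b, ext)
    # subsetting a QualityScaledDNAStringSet warns about dropped metadata
    # columns; nothing here uses them
    sub <- withCallingHandlers(lib[ids], warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
    if (fastq) {
      Biostrings::writeQualityScaledXStringSet(sub, path)
    } else {
      Biostrings::writeXStringSet(sub, path)
    }
    counts[b] <- length(ids)
  }
  invisible(counts)
}
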