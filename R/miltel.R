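#' Fraction of a sequence covered by a telomere motif
#'
#' Computes the fraction of positions covered by exact, possibly
#' overlapping, occurrences of any rotation of `motif` or of its reverse
#' complement's rotations. Rotation invariance means the phase of the
#' repeat in a clipped read does not matter; including the reverse
#' complement covers clips reported on either strand.
#'
#' @param seq DNA sequence (character scalar).
#' @param motif Telomere repeat unit, length >= 2 (default `"TTGGGG"`, the
#'   ciliate G4T2 repeat).
#' @return Covered fraction in `[0, 1]`.
#' @export
telomere_fraction <- function(seq, motif = "TTGGGG") {
  stopifnot(nchar(motif) >= 2L, nchar(seq) >= 1L)
  pats <- .motif_rotations(motif)
  s <- Biostrings::DNAString(seq)
  hits <- IRanges::IRanges()
  for (p in pats) {
    m <- Biostrings::matchPattern(p, s)
    if (length(m)) hits <- c(hits, methods::as(m, "IRanges"))
  }
  if (!length(hits)) return(0)
  sum(IRanges::width(IRanges::reduce(hits))) / nchar(seq)
}

.motif_rotations <- function(motif) {
  motif <- toupper(motif)
  k <- nchar(motif)
  rot <- vapply(seq_len(k), function(i) {
    paste0(substring(motif, i, k), substring(motif, 1L, i - 1L))
  }, "")
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  rrc <- vapply(seq_len(k), function(i) {
    paste0(substring(rc, i, k), substring(rc, 1L, i - 1L))
  }, "")
  unique(c(rot, rrc))
}

#' Call alternative chromosome breakage sites from telomeric soft clips
#'
#' During somatic genome development, germline chromosomes are fragmented
#' and telomeres are added at the new ends. Reads crossing such a site map
#' to the assembly up to the breakpoint and carry the unaligned telomeric
#' repeat as a soft clip. This call collects soft clips whose telomere motif
#' coverage is at least `min_motif_fraction`, clusters them per contig and
#' clip side by single linkage, and reports clusters with sufficient read
#' support at their modal breakpoint.
#'
#' @param bam Coordinate-sorted BAM of reads mapped to the MAC assembly.
#' @param ref Reference from [read_reference()].
#' @param motif Telomere repeat unit(s); a character vector is allowed for
#'   mixed-repeat species, a clip matching any motif qualifies.
#' @param min_clip_len Minimum soft-clip length considered (default 24).
#' @param min_motif_fraction Minimum motif-covered fraction of the clip
#'   (default 0.7; absorbs sequencing errors in noisy reads).
#' @param max_cluster_dist Single-linkage distance between breakpoints
#'   (default 10).
#' @param min_break_coverage Minimum supporting reads per site (default 3).
#' @param min_mapq Minimum mapping quality.
#' @return Data.frame with one row per site: `contig`, `position` (0-based
#'   modal breakpoint), `side`, `support`, `mean_motif_fraction`.
#' @export
call_breakpoints <- function(bam, ref, motif = "TTGGGG",
                             min_clip_len = 24L, min_motif_fraction = 0.7,
                             max_cluster_dist = 10L, min_break_coverage = 3L,
                             min_mapq = 1L) {
  aln <- read_alignments(bam, min_mapq = min_mapq, ref = ref)
  ce <- clip_evidence(aln, min_clip_len)
  empty <- data.frame(contig = character(0), position = integer(0),
                      side = character(0), support = integer(0),
                      mean_motif_fraction = numeric(0))
  if (nrow(ce) == 0L) return(empty)
  ce$motif_fraction <- vapply(ce$clip_seq, function(s) {
    max(vapply(motif, function(m) telomere_fraction(s, m), 0))
  }, 0, USE.NAMES = FALSE)
  ce <- ce[ce$motif_fraction >= min_motif_fraction, , drop = FALSE]
  if (nrow(ce) == 0L) return(empty)
  out <- list()
  for (grp in split(ce, list(ce$contig, ce$side), drop = TRUE)) {
    grp <- grp[order(grp$breakpoint, grp$read_id), , drop = FALSE]
    gap <- c(Inf, diff(grp$breakpoint))
    grp$cluster <- cumsum(gap > max_cluster_dist)
    for (m in split(grp, grp$cluster)) {
      sup <- length(unique(m$read_id))
      if (sup < min_break_coverage) next
      tab <- table(m$breakpoint)
      out[[length(out) + 1L]] <- data.frame(
        contig = m$contig[1],
        position = as.integer(names(tab)[which.max(tab)]),
        side = m$side[1], support = sup,
        mean_motif_fraction = mean(m$motif_fraction))
    }
  }
  if (!length(out)) return(empty)
  out <- do.call(rbind, out)
  out <- out[order(match(out$contig, names(ref)), out$position, out$side), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
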