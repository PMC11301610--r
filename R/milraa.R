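#' Cluster insertion evidence by single linkage
#'
#' Partitions insertion evidence on one contig into clusters of adjacent
#' junctions: a new cluster starts whenever the gap to the previous junction
#' exceeds `max_cluster_dist` (single linkage, so every within-distance pair
#' is transitively connected). Within a cluster, multiple inserts from one
#' read are collapsed to the longest, so each read is counted once.
#'
#' @param evidence Data.frame from [insert_evidence()], all rows on one
#'   contig.
#' @param max_cluster_dist Maximum junction gap joining two neighbours.
#' @return The evidence rows (per-read deduplicated), sorted by junction,
#'   with an integer `cluster` column.
#' @export
cluster_inserts <- function(evidence, max_cluster_dist) {
  if (nrow(evidence) == 0L) {
    evidence$cluster <- integer(0)
    return(evidence)
  }
  stopifnot(length(unique(evidence$contig)) == 1L)
  evidence <- evidence[order(evidence$junction, evidence$read_id), ,
                       drop = FALSE]
  gap <- c(Inf, diff(evidence$junction))
  evidence$cluster <- cumsum(gap > max_cluster_dist)
  # collapse duplicate reads within a cluster to their longest insert
  len <- nchar(evidence$insert_seq)
  o <- order(evidence$cluster, evidence$read_id, -len, evidence$junction)
  ev <- evidence[o, , drop = FALSE]
  keep <- !duplicated(ev[, c("cluster", "read_id")])
  ev <- ev[keep, , drop = FALSE]
  ev <- ev[order(ev$junction, ev$read_id), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Summarise clusters
#'
#' @param clustered Output of [cluster_inserts()].
#' @return One row per cluster: `cluster`, `contig`, `n_reads`, `span_min`,
#'   `span_max`, `mode_junction` (most frequent member junction, ties to the
#'   leftmost).
#' @export
cluster_table <- function(clustered) {
  if (nrow(clustered) == 0L) {
    return(data.frame(cluster = integer(0), contig = character(0),
                      n_reads = integer(0), span_min = integer(0),
                      span_max = integer(0), mode_junction = integer(0)))
  }
  sp <- split(clustered, clustered$cluster)
  out <- do.call(rbind, lapply(sp, function(m) {
    tab <- table(m$junction)
    mode_j <- as.integer(names(tab)[which.max(tab)])  # ties -> leftmost
    data.frame(cluster = m$cluster[1], contig = m$contig[1],
               n_reads = length(unique(m$read_id)),
               span_min = min(m$junction), span_max = max(m$junction),
               mode_junction = mode_j)
  }))
  rownames(out) <- NULL
  out
}

#' Drop clusters below a coverage cutoff
#'
#' @param clustered Output of [cluster_inserts()].
#' @param min_coverage Minimum number of distinct supporting reads.
#' @return Subset of `clustered` restricted to clusters meeting the cutoff;
#'   order preserved.
#' @export
filter_clusters <- function(clustered, min_coverage) {
  if (nrow(clustered) == 0L) return(clustered)
  nn <- tapply(clustered$read_id, clustered$cluster,
               function(x) length(unique(x)))
  keep <- names(nn)[nn >= min_coverage]
  out <- clustered[clustered$cluster %in% as.integer(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Split one cluster's members into insert-length classes when lengths are
# multimodal (ratio > 2 between consecutive sorted lengths); guards the
# consensus against chimeras of co-located but distinct inserts.
.split_by_length <- function(members) {
  o <- order(nchar(members$insert_seq))
  m <- members[o, , drop = FALSE]
  len <- nchar(m$insert_seq)
  brk <- c(FALSE, len[-1] > 2L * len[-length(len)])
  split(m, cumsum(brk))
}

#' Extract flank-anchored segments for a cluster
#'
#' For each cluster member, slices the read sequence around the insert:
#' up to `flank_len` bp of read sequence on each side plus the insert
#' itself. Flanks are truncated (never padded) at read ends. The flanking
#' sequence anchors the cluster consensus during realignment.
#'
#' @param members Cluster member rows (from [cluster_inserts()]).
#' @param alignments Alignment table covering every member read.
#' @param flank_len Flank width in bp (default 100).
#' @return Data.frame with `read_id` and `seq` (flank + insert + flank).
#' @export
extract_flanked_segments <- function(members, alignments, flank_len = 100L) {
  idx <- match(members$read_id, alignments$read_id)
  if (anyNA(idx)) {
    stop("read(s) missing from alignment table: ",
         paste(utils::head(members$read_id[is.na(idx)], 3), collapse = ", "))
  }
  qseq <- alignments$seq[idx]
  qlen <- nchar(qseq)
  ilen <- nchar(members$insert_seq)
  from <- pmax(1L, members$query_start + 1L - flank_len)
  to <- pmin(qlen, members$query_start + ilen + flank_len)
  data.frame(read_id = members$read_id, seq = substring(qseq, from, to))
}

#' Call IESs de novo from a mapped long-read library
#'
#' The full reconstruction pipeline, per contig: extract insertion evidence
#' from primary alignments, cluster it by single linkage, drop clusters
#' below the coverage cutoff, split length-multimodal clusters, then derive
#' one IES record per surviving cluster. In `"ccs"` mode (accurate reads)
#' the junction is the modal member junction and the insert consensus is
#' taken over member insert sequences directly. In `"subread"` mode (noisy
#' reads) flank-anchored segments are extracted, assembled to a consensus,
#' and realigned to the reference to recover the junction and insert
#' jointly. Pointers and TA boundaries are then annotated and a per-site
#' retention score is computed from all primary reads spanning the junction.
#'
#' @param bam Path to a coordinate-sorted BAM of long reads mapped to `ref`.
#' @param ref Reference from [read_reference()].
#' @param mode `"subread"` (default) or `"ccs"`.
#' @param min_coverage Minimum distinct reads per cluster (default 5).
#' @param max_cluster_dist Single-linkage distance; defaults to 10 for
#'   subreads (junction jitter) and 3 for CCS.
#' @param flank_len Flank width for segment extraction (default 100).
#' @param min_insert_len Minimum insert length (default 10).
#' @param min_mapq Minimum mapping quality (default 1).
#' @param buffer Junction-spanning buffer for retention scoring (default 15).
#' @param contig Optional single contig to restrict the run to.
#' @return `list(records, clusters)`: `records` is one row per called IES
#'   (`id`, `contig`, `junction` 0-based, `ies_seq`, `length`, `pointer`,
#'   `ta_bound`, `support`, `spanning_total`, `retention_score`, `mode`),
#'   sorted by contig then junction; `clusters` is a per-cluster report
#'   including rejected clusters with the rejection reason.
#' @export
call_iess <- function(bam, ref, mode = c("subread", "ccs"),
                      min_coverage = 5L, max_cluster_dist = NULL,
                      flank_len = 100L, min_insert_len = 10L,
                      min_mapq = 1L, buffer = 15L, contig = NULL) {
  mode <- match.arg(mode)
  if (is.null(max_cluster_dist)) {
    max_cluster_dist <- if (mode == "ccs") 3L else 10L
  }
  aln_all <- read_alignments(bam, min_mapq = min_mapq, ref = ref)
  contigs <- if (is.null(contig)) {
    intersect(names(ref), unique(aln_all$contig))
  } else {
    stopifnot(contig %in% names(ref))
    contig
  }
  records <- list()
  reports <- list()
  for (ctg in contigs) {
    aln <- aln_all[aln_all$contig == ctg, , drop = FALSE]
    ev <- insert_evidence(aln, min_insert_len)
    cl <- cluster_inserts(ev, max_cluster_dist)
    ctab <- cluster_table(cl)
    recs <- list()
    for (ci in seq_len(nrow(ctab))) {
      members <- cl[cl$cluster == ctab$cluster[ci], , drop = FALSE]
      if (ctab$n_reads[ci] < min_coverage) {
        reports[[length(reports) + 1L]] <- cbind(
          ctab[ci, ], status = "rejected", reason = "below_min_coverage")
        next
      }
      for (sub in .split_by_length(members)) {
        if (length(unique(sub$read_id)) < min_coverage) {
          reports[[length(reports) + 1L]] <- cbind(
            ctab[ci, ], status = "rejected",
            reason = "length_class_below_min_coverage")
          next
        }
        res <- .call_one_cluster(sub, aln, ref, ctg, mode, flank_len,
                                 min_insert_len)
        if (is.null(res)) {
          reports[[length(reports) + 1L]] <- cbind(
            ctab[ci, ], status = "rejected",
            reason = "no_insertion_in_realignment")
          next
        }
        ann <- detect_pointer(res$ies_seq, ref, ctg, res$junction)
        recs[[length(recs) + 1L]] <- data.frame(
          contig = ctg, junction = ann$junction, ies_seq = ann$ies_seq,
          length = nchar(ann$ies_seq), pointer = ann$pointer,
          ta_bound = detect_ta(ann$pointer),
          support = length(unique(sub$read_id)), mode = mode)
        reports[[length(reports) + 1L]] <- cbind(
          ctab[ci, ], status = "called", reason = "")
      }
    }
    if (!length(recs)) next
    rec <- do.call(rbind, recs)
    st <- .span_status_table(aln, rec$junction, buffer, min_insert_len)
    for (k in seq_len(nrow(rec))) {
      sk <- st[st$junction == rec$junction[k], , drop = FALSE]
      rec$support[k] <- sum(sk$status == "retained")
      rec$spanning_total[k] <- nrow(sk)
    }
    rec$retention_score <- ifelse(rec$spanning_total > 0,
                                  rec$support / rec$spanning_total, NA_real_)
    # a called IES must keep min_coverage spanning reads that carry the
    # insert near the refined junction; clusters of scattered error
    # insertions fail this even when their raw member count passed
    low <- rec$support < min_coverage
    if (any(low)) {
      for (k in which(low)) {
        reports[[length(reports) + 1L]] <- data.frame(
          cluster = NA_integer_, contig = ctg, n_reads = rec$support[k],
          span_min = rec$junction[k], span_max = rec$junction[k],
          mode_junction = rec$junction[k], status = "rejected",
          reason = "support_below_min_coverage")
      }
      rec <- rec[!low, , drop = FALSE]
    }
    if (nrow(rec)) records[[length(records) + 1L]] <- rec
  }
  records <- if (length(records)) do.call(rbind, records) else
    data.frame(contig = character(0), junction = integer(0),
               ies_seq = character(0), length = integer(0),
               pointer = character(0), ta_bound = logical(0),
               support = integer(0), mode = character(0),
               spanning_total = integer(0), retention_score = numeric(0))
  records <- records[order(match(records$contig, names(ref)),
                           records$junction), , drop = FALSE]
  rownames(records) <- NULL
  if (nrow(records)) {
    records <- cbind(
      id = sprintf("IES_%s_%d", records$contig, records$junction + 1L),
      records)
  } else {
    records <- cbind(id = character(0), records)
  }
  clusters <- if (length(reports)) do.call(rbind, reports) else
    data.frame(cluster = integer(0), contig = character(0),
               n_reads = integer(0), span_min = integer(0),
               span_max = integer(0), mode_junction = integer(0),
               status = character(0), reason = character(0))
  rownames(clusters) <- NULL
  list(records = records, clusters = clusters)
}

.call_one_cluster <- function(members, aln, ref, ctg, mode, flank_len,
                              min_insert_len) {
  if (mode == "ccs") {
    tab <- table(members$junction)
    junction <- as.integer(names(tab)[which.max(tab)])
    seqs <- members$insert_seq
    # consensus over members at the modal junction keeps lengths consistent
    at_mode <- members$junction == junction
    if (sum(at_mode) >= 2L) seqs <- members$insert_seq[at_mode]
    ies_seq <- consensus_seq(seqs)
    if (nchar(ies_seq) < min_insert_len) return(NULL)
    return(list(junction = junction, ies_seq = ies_seq))
  }
  segs <- extract_flanked_segments(members, aln, flank_len)
  cons <- consensus_seq(segs$seq)
  window <- c(min(members$junction) - flank_len - 50L,
              max(members$junction) + flank_len + 50L)
  realign_consensus(cons, ref, ctg, window, min_insert_len)
}
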