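#' Evaluate IES calls against a simulated truth table
#'
#' Matches predictions to truth one-to-one by greedy nearest-junction
#' pairing within `tol_bp` (closest pairs first; ties resolved to the
#' leftmost truth junction, then leftmost prediction). Reports recall and
#' precision, and for matched pairs the insert-sequence accuracy: the
#' number assembled exactly and the number within at most one mismatch and
#' one indel base (global alignment).
#'
#' @param predicted Data.frame of calls with `contig`, `junction` (0-based)
#'   and `ies_seq` (e.g. `call_iess()$records`).
#' @param truth Truth table from [make_genomes()].
#' @param tol_bp Junction-matching tolerance in bp (default 5).
#' @return List with `recall`, `precision`, `n_truth`, `n_pred`,
#'   `n_matched`, `n_exact_seq`, `n_seq_1mm1indel`, and the `matches`
#'   data.frame (`truth_idx`, `pred_idx`, `dist`).
#' @export
evaluate_calls <- function(predicted, truth, tol_bp = 5L) {
  pairs <- list()
  for (ctg in unique(truth$contig)) {
    ti <- which(truth$contig == ctg)
    pi <- which(predicted$contig == ctg)
    if (!length(ti) || !length(pi)) next
    d <- abs(outer(truth$junction[ti], predicted$junction[pi], "-"))
    ok <- which(d <= tol_bp, arr.ind = TRUE)
    if (!nrow(ok)) next
    pairs[[length(pairs) + 1L]] <- data.frame(
      truth_idx = ti[ok[, 1]], pred_idx = pi[ok[, 2]],
      dist = d[ok])
  }
  matches <- data.frame(truth_idx = integer(0), pred_idx = integer(0),
                        dist = integer(0))
  if (length(pairs)) {
    cand <- do.call(rbind, pairs)
    cand <- cand[order(cand$dist, truth$junction[cand$truth_idx],
                       predicted$junction[cand$pred_idx]), , drop = FALSE]
    used_t <- logical(nrow(truth))
    used_p <- logical(nrow(predicted))
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      t <- cand$truth_idx[i]
      p <- cand$pred_idx[i]
      if (!used_t[t] && !used_p[p]) {
        keep[i] <- TRUE
        used_t[t] <- TRUE
        used_p[p] <- TRUE
      }
    }
    matches <- cand[keep, , drop = FALSE]
    rownames(matches) <- NULL
  }
  n_exact <- 0L
  n_close <- 0L
  for (i in seq_len(nrow(matches))) {
    ts <- truth$ies_seq[matches$truth_idx[i]]
    ps <- predicted$ies_seq[matches$pred_idx[i]]
    if (identical(ts, ps)) {
      n_exact <- n_exact + 1L
      n_close <- n_close + 1L
    } else {
      ed <- .edit_counts(ps, ts)
      if (ed$mismatches <= 1L && ed$indel_bases <= 1L) n_close <- n_close + 1L
    }
  }
  list(
    recall = if (nrow(truth)) nrow(matches) / nrow(truth) else NA_real_,
    precision = if (nrow(predicted)) nrow(matches) / nrow(predicted)
                else NA_real_,
    n_truth = nrow(truth), n_pred = nrow(predicted),
    n_matched = nrow(matches), n_exact_seq = n_exact,
    n_seq_1mm1indel = n_close, matches = matches)
}

# mismatch and indel-base counts from a Levenshtein-style global alignment
.edit_counts <- function(a, b) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = sm, gapOpening = 0, gapExtension = 1)
  ni <- Biostrings::nindel(aln)
  list(mismatches = Biostrings::nmismatch(aln),
       indel_bases = sum(Biostrings::insertion(ni)[, "WidthSum"],
                         Biostrings::deletion(ni)[, "WidthSum"]))
}
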