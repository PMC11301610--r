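#' Consensus of a set of flank-anchored segments
#'
#' Computes a star-alignment consensus: the member of median length is the
#' backbone, every other sequence is globally aligned to it, and each
#' backbone column is called by majority vote (substitutions vote bases,
#' deletions vote gaps). Bases inserted relative to the backbone are kept
#' only when more than half of all sequences insert at the same backbone
#' junction, in which case the most frequent inserted string is used. This
#' makes the consensus robust to insertion-dominated long-read noise:
#' independent error insertions never reach majority, while a genuine base
#' the backbone happens to lack is recovered from the other reads.
#'
#' A single input sequence is returned verbatim. All tie-breaks are fixed
#' (base order A < C < G < T < N, a base beats a gap, insertion strings by
#' count then lexicographic order), so the result is deterministic for a
#' given input order.
#'
#' @param seqs Character vector of DNA sequences (>= 1).
#' @param rounds Polishing rounds: after the first vote the consensus
#'   replaces the backbone and all members are realigned and re-voted,
#'   which corrects gap-placement wobble left by a raw backbone (default 2).
#' @param match,mismatch,gap_open,gap_extend Star-alignment scores.
#' @return Consensus sequence (uppercase character scalar).
#' @export
consensus_seq <- function(seqs, rounds = 2L, match = 2, mismatch = -4,
                          gap_open = 4, gap_extend = 2) {
  n <- length(seqs)
  if (n == 0L) stop("consensus of zero sequences is undefined")
  seqs <- toupper(seqs)
  if (n == 1L || length(unique(seqs)) == 1L) return(seqs[[1]])
  o <- order(nchar(seqs), seq_along(seqs))
  cons <- seqs[o[ceiling(n / 2)]]  # median-length member seeds the backbone
  for (r in seq_len(max(1L, rounds))) {
    nxt <- .star_vote(cons, seqs, match, mismatch, gap_open, gap_extend)
    if (identical(nxt, cons)) break
    cons <- nxt
  }
  cons
}

# One polishing round: align every member to the backbone and call each
# backbone column (and each insertion junction) by majority over members.
.star_vote <- function(backbone, seqs, match, mismatch, gap_open,
                       gap_extend) {
  n <- length(seqs)
  L <- nchar(backbone)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(seqs), Biostrings::DNAString(backbone),
    type = "global", substitutionMatrix = sm,
    gapOpening = gap_open, gapExtension = gap_extend)
  # pattern()/subject() give the gapped strings of the aligned region and
  # are far faster than alignedPattern()/alignedSubject(); they trim
  # unaligned terminal overhangs, so backbone coordinates need the aligned
  # subject start as an offset (terminal overhang bases simply cast no vote)
  pa <- as.character(Biostrings::pattern(aln))
  sa <- as.character(Biostrings::subject(aln))
  soff <- Biostrings::start(Biostrings::subject(aln))
  lev <- c("A", "C", "G", "T", "N", "-")
  votes <- matrix(0L, length(lev), L, dimnames = list(lev, NULL))
  ins_votes <- list()
  for (k in seq_along(pa)) {
    pv <- strsplit(pa[k], "")[[1]]
    sv <- strsplit(sa[k], "")[[1]]
    bpos <- soff[k] - 1L + cumsum(sv != "-")
    at <- sv != "-"
    ch <- pv[at]
    ch[!ch %in% lev] <- "N"
    ij <- cbind(match(ch, lev), bpos[at])
    votes[ij] <- votes[ij] + 1L
    if (any(!at)) {
      grp <- tapply(pv[!at], bpos[!at], paste, collapse = "")
      for (j in names(grp)) ins_votes[[j]] <- c(ins_votes[[j]], grp[[j]])
    }
  }
  call <- lev[apply(votes, 2L, which.max)]  # first max: fixed tie order
  parts <- character(0)
  for (j in 0:L) {
    iv <- ins_votes[[as.character(j)]]
    if (!is.null(iv) && length(iv) > n / 2) {
      tab <- table(iv)
      best <- sort(names(tab)[tab == max(tab)])[1]
      parts <- c(parts, best)
    }
    if (j > 0L && call[j] != "-") parts <- c(parts, call[j])
  }
  paste(parts, collapse = "")
}

#' Realign a consensus to the reference and locate the insert
#'
#' Globally aligns the flank-anchored consensus against a reference window
#' (affine gap penalties; match +2, mismatch -4, gap open -12, gap extend
#' -2 by default). The stiff gap-opening penalty keeps a genuine insertion
#' in one contiguous run: in AT-rich ciliate sequence a weakly penalised
#' aligner profitably fragments an insert to collect chance 6-mer matches
#' from the flank, splitting one IES into several short runs. The longest
#' consensus-only (insertion) run in the traceback is reported; ties go to
#' the leftmost such run. The junction is left-normalised to its leftmost
#' shift-equivalent position.
#'
#' @param consensus Consensus sequence (character scalar).
#' @param ref Reference genome from [read_reference()].
#' @param contig Contig name.
#' @param window Integer vector `c(start, end)`, 0-based half-open window on
#'   the contig that covers the cluster span plus flanks.
#' @param min_insert_len Minimum insertion-run length to accept; shorter runs
#'   mean the cluster is rejected (returns `NULL`).
#' @param match,mismatch,gap_open,gap_extend Alignment scores (penalties as
#'   positive magnitudes for the gap parameters).
#' @return `list(junction, ies_seq)` with the 0-based left-normalised
#'   junction, or `NULL` when no sufficient insertion run exists.
#' @export
realign_consensus <- function(consensus, ref, contig, window,
                              min_insert_len = 10L,
                              match = 2, mismatch = -4,
                              gap_open = 12, gap_extend = 2) {
  stopifnot(nzchar(consensus), contig %in% names(ref))
  w0 <- max(0L, as.integer(window[1]))
  w1 <- min(nchar(ref[[contig]]), as.integer(window[2]))
  refwin <- substring(ref[[contig]], w0 + 1L, w1)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(consensus), Biostrings::DNAString(refwin),
    type = "global", substitutionMatrix = sm,
    gapOpening = gap_open, gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  soff <- Biostrings::start(Biostrings::subject(aln))
  runs <- rle(sa == "-")
  if (!any(runs$values)) return(NULL)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ins <- which(runs$values)
  best <- ins[which.max(runs$lengths[ins])]  # first max == leftmost on ties
  if (runs$lengths[best] < min_insert_len) return(NULL)
  cols <- starts[best]:ends[best]
  ies_seq <- paste(pa[cols], collapse = "")
  junction <- w0 + soff - 1L + sum(sa[seq_len(starts[best] - 1L)] != "-")
  norm <- normalize_insertion(ies_seq, ref, contig, junction)
  list(junction = norm$junction, ies_seq = norm$ies_seq)
}

#' Left-normalise an insertion
#'
#' An insertion adjacent to a repeat has several shift-equivalent placements
#' that imply the same inserted-form (MIC) sequence. The canonical placement
#' used throughout the package is the leftmost: while the last inserted base
#' equals the reference base immediately left of the junction, the insertion
#' is rotated one position left.
#'
#' @inheritParams realign_consensus
#' @param ies_seq Inserted sequence.
#' @param junction 0-based junction (first reference base after the insert).
#' @return `list(junction, ies_seq)` at the leftmost equivalent placement.
#' @export
normalize_insertion <- function(ies_seq, ref, contig, junction) {
  refseq <- ref[[contig]]
  n <- nchar(ies_seq)
  while (junction > 0L &&
         substring(refseq, junction, junction) ==
         substring(ies_seq, n, n)) {
    ies_seq <- paste0(substring(refseq, junction, junction),
                      substring(ies_seq, 1L, n - 1L))
    junction <- junction - 1L
  }
  list(junction = junction, ies_seq = ies_seq)
}

#' Annotate the pointer repeat at an IES junction
#'
#' After left-normalisation, the pointer is the longest prefix `p` of the
#' inserted sequence that also matches the reference immediately right of
#' the junction. One copy of the pointer remains in the MAC after excision;
#' the repeat makes the junction coordinate ambiguous up to a shift, which
#' is why the insertion is normalised first.
#'
#' @inheritParams normalize_insertion
#' @return `list(pointer, junction, ies_seq)`; `pointer` is `""` when no
#'   repeat is present; `junction`/`ies_seq` are the normalised values.
#' @export
detect_pointer <- function(ies_seq, ref, contig, junction) {
  norm <- normalize_insertion(ies_seq, ref, contig, junction)
  refseq <- ref[[contig]]
  j <- norm$junction
  s <- norm$ies_seq
  kmax <- min(nchar(s), nchar(refseq) - j)
  k <- 0L
  while (k < kmax &&
         substring(s, k + 1L, k + 1L) ==
         substring(refseq, j + k + 1L, j + k + 1L)) {
    k <- k + 1L
  }
  list(pointer = if (k > 0L) substring(s, 1L, k) else "",
       junction = j, ies_seq = s)
}

#' Is an IES TA-bounded?
#'
#' TA-bounded excision (the signature of domesticated piggyBac-family
#' excisases) leaves exactly the pointer `"TA"`: the insert starts with TA
#' and one TA copy is retained at the MAC junction.
#'
#' @param pointer Pointer string from [detect_pointer()].
#' @return Logical scalar.
#' @export
detect_ta <- function(pointer) {
  identical(toupper(pointer), "TA")
}
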