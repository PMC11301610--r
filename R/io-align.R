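#' Read a MAC reference genome from FASTA
#'
#' Loads all records, normalises sequences to uppercase, and replaces IUPAC
#' ambiguity codes other than N with N (with a warning). All downstream
#' coordinates refer to this assembly.
#'
#' @param path Path to a FASTA file (plain or bgzip).
#' @return A named character vector of uppercase A/C/G/T/N sequences, one per
#'   contig. Names are contig names (first whitespace-delimited token).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgtACGT"), fa)
#' read_reference(fa)
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  dss <- Biostrings::readDNAStringSet(path)
  if (length(dss) == 0L) stop("reference FASTA is empty: ", path)
  nm <- sub("\\s.*$", "", names(dss))
  if (any(nm == "")) stop("reference FASTA contains an unnamed record")
  if (anyDuplicated(nm)) {
    stop("duplicate contig name(s) in reference: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(dss))
  amb <- grepl("[^ACGTN]", seqs)
  if (any(amb)) {
    warning(sum(amb), " contig(s) contain IUPAC ambiguity codes; replaced by N")
    seqs[amb] <- gsub("[^ACGTN]", "N", seqs[amb])
  }
  names(seqs) <- nm
  seqs
}

#' Read primary alignments from a BAM file
#'
#' Unmapped, secondary and supplementary records are skipped, as are records
#' below `min_mapq`. Only primary alignments contribute evidence anywhere in
#' the package, so one sequenced molecule is counted once.
#'
#' @param bam Path to a coordinate-sorted BAM file.
#' @param region Optional region string `"contig"` or `"contig:start-end"`
#'   (1-based, as in samtools). Requires a BAM index.
#' @param min_mapq Minimum mapping quality (default 1; set 0 to keep
#'   multimappers).
#' @param ref Optional reference from [read_reference()]; if given, BAM header
#'   contigs are validated against it and a mismatch is a hard error.
#' @return A data.frame with one row per alignment: `read_id`, `contig`,
#'   `ref_start` (0-based leftmost reference position), `mapq`, `cigar`,
#'   `seq` (query sequence as stored in the BAM, reference orientation).
#' @export
read_alignments <- function(bam, region = NULL, min_mapq = 1L, ref = NULL) {
  if (!file.exists(bam)) stop("BAM file not found: ", bam)
  targets <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!is.null(ref)) {
    missing <- setdiff(names(targets), names(ref))
    if (length(missing)) {
      stop("BAM/reference contig-name mismatch; BAM contigs absent from ",
           "reference: ", paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  if (is.null(region)) {
    param <- Rsamtools::ScanBamParam(what = what, flag = flag)
  } else {
    idx <- paste0(bam, ".bai")
    if (!file.exists(idx) && !file.exists(sub("\\.bam$", ".bai", bam))) {
      stop("region query on BAM without index: ", bam,
           " -- create one with Rsamtools::indexBam() or `samtools index`")
    }
    gr <- .parse_region(region, targets)
    param <- Rsamtools::ScanBamParam(what = what, flag = flag, which = gr)
  }
  res <- Rsamtools::scanBam(bam, param = param)
  res <- do.call(Map, c(list(f = c), res))  # merge region chunks
  keep <- res$mapq >= min_mapq & !is.na(res$pos)
  out <- data.frame(
    read_id = as.character(res$qname)[keep],
    contig = as.character(res$rname)[keep],
    ref_start = as.integer(res$pos)[keep] - 1L,
    mapq = as.integer(res$mapq)[keep],
    cigar = as.character(res$cigar)[keep],
    seq = as.character(res$seq)[keep]
  )
  if (!is.null(region)) out <- out[!duplicated(out$read_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.parse_region <- function(region, targets) {
  m <- regmatches(region, regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1]]
  if (length(m) == 0L || m[1] == "") stop("malformed region string: ", region)
  contig <- m[2]
  if (!contig %in% names(targets)) {
    stop("region contig not in BAM header: ", contig)
  }
  if (m[3] == "") {
    rng <- IRanges::IRanges(1L, unname(targets[contig]))
  } else {
    rng <- IRanges::IRanges(as.integer(m[4]), as.integer(m[5]))
  }
  gr <- IRanges::IRangesList(rng)
  names(gr) <- contig
  gr
}

#' Extract insertion evidence from alignments
#'
#' One evidence row per CIGAR `I` operation of length at least
#' `min_insert_len`. The junction is the 0-based reference coordinate of the
#' first reference base *after* the insertion; insertions are zero-width
#' events between reference bases `junction - 1` and `junction`.
#'
#' @param alignments Data.frame from [read_alignments()] (or a compatible
#'   one-row-per-alignment table with `read_id`, `contig`, `ref_start`,
#'   `cigar`, `seq`).
#' @param min_insert_len Minimum insert length to report (default 10, which
#'   separates IES-scale inserts from sequencing-error indels).
#' @return Data.frame with columns `read_id`, `contig`, `junction`,
#'   `insert_seq`, `query_start` (0-based offset of the insert in `seq`).
#' @export
insert_evidence <- function(alignments, min_insert_len = 10L) {
  rows <- lapply(seq_len(nrow(alignments)), function(i) {
    a <- alignments[i, ]
    ops <- parse_cigar(a$cigar)
    if (nrow(ops) == 0L) return(NULL)
    wk <- cigar_walk(ops, a$ref_start)
    sel <- which(wk$op == "I" & wk$len >= min_insert_len)
    if (!length(sel)) return(NULL)
    qs <- wk$qry_at[sel]
    if (any(qs + wk$len[sel] > nchar(a$seq))) {
      stop("corrupt record: insertion beyond query sequence in read ",
           a$read_id)
    }
    data.frame(
      read_id = a$read_id, contig = a$contig,
      junction = wk$ref_at[sel],
      insert_seq = substring(a$seq, qs + 1L, qs + wk$len[sel]),
      query_start = qs
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(read_id = character(0), contig = character(0),
                      junction = integer(0), insert_seq = character(0),
                      query_start = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Extract soft-clip evidence from alignments
#'
#' Reports terminal soft clips (CIGAR `S`) of length at least `min_clip_len`.
#' Hard clips carry no sequence and are ignored. The breakpoint of a left
#' clip is the reference start of the aligned block; of a right clip, the
#' reference end (0-based, exclusive end == first base after the block).
#'
#' @inheritParams insert_evidence
#' @param min_clip_len Minimum clip length to report.
#' @return Data.frame with columns `read_id`, `contig`, `breakpoint`,
#'   `side` (`"left"` or `"right"`), `clip_seq`.
#' @export
clip_evidence <- function(alignments, min_clip_len = 24L) {
  rows <- lapply(seq_len(nrow(alignments)), function(i) {
    a <- alignments[i, ]
    ops <- parse_cigar(a$cigar)
    n <- nrow(ops)
    if (n == 0L) return(NULL)
    soft <- ops[ops$op != "H", , drop = FALSE]
    m <- nrow(soft)
    out <- NULL
    if (m >= 1L && soft$op[1] == "S" && soft$len[1] >= min_clip_len) {
      out <- rbind(out, data.frame(
        read_id = a$read_id, contig = a$contig,
        breakpoint = a$ref_start, side = "left",
        clip_seq = substring(a$seq, 1L, soft$len[1])))
    }
    if (m >= 2L && soft$op[m] == "S" && soft$len[m] >= min_clip_len) {
      qlen <- nchar(a$seq)
      out <- rbind(out, data.frame(
        read_id = a$read_id, contig = a$contig,
        breakpoint = a$ref_start + cigar_ref_span(ops), side = "right",
        clip_seq = substring(a$seq, qlen - soft$len[m] + 1L, qlen)))
    }
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(read_id = character(0), contig = character(0),
                      breakpoint = integer(0), side = character(0),
                      clip_seq = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Classify whether an alignment spans an IES junction
#'
#' A read spans a junction when its aligned reference interval covers
#' `[junction - buffer, junction + buffer]`. A spanning read is `"retained"`
#' if it carries an insertion of length >= `min_insert_len` within `buffer`
#' bp of the junction, `"excised"` otherwise, and `"not_spanning"` when the
#' flanks are not both covered.
#'
#' @param alignment One row of [read_alignments()] output.
#' @param junction 0-based junction coordinate.
#' @param buffer Flank width in bp that must be covered on both sides
#'   (default 15).
#' @param min_insert_len Minimum insertion length counted as retention.
#' @return One of `"retained"`, `"excised"`, `"not_spanning"`.
#' @export
spans_junction <- function(alignment, junction, buffer = 15L,
                           min_insert_len = 10L) {
  stopifnot(buffer >= 1L)
  ops <- parse_cigar(alignment$cigar)
  ref_end <- alignment$ref_start + cigar_ref_span(ops)
  if (alignment$ref_start > junction - buffer || ref_end < junction + buffer) {
    return("not_spanning")
  }
  wk <- cigar_walk(ops, alignment$ref_start)
  ins <- wk$op == "I" & wk$len >= min_insert_len &
    abs(wk$ref_at - junction) <= buffer
  if (any(ins)) "retained" else "excised"
}

# Vectorised spanning-status classification of every alignment against every
# annotated site on one contig. Shared code path for retention scoring in
# milraa and milcor: per-site and per-read tallies are aggregations of this
# one table, so they agree by construction (and are tested independently).
#
# Returns a data.frame (aln_idx, read_id, junction, status) restricted to
# spanning reads; status is "retained" or "excised".
.span_status_table <- function(alignments, junctions, buffer = 15L,
                               min_insert_len = 10L) {
  stopifnot(buffer >= 1L)
  n <- nrow(alignments)
  if (n == 0L || length(junctions) == 0L) {
    return(data.frame(aln_idx = integer(0), read_id = character(0),
                      junction = integer(0), status = character(0)))
  }
  opsl <- lapply(alignments$cigar, parse_cigar)
  ref_end <- alignments$ref_start + vapply(opsl, cigar_ref_span, 0)
  ev <- insert_evidence(alignments, min_insert_len)
  rows <- lapply(junctions, function(j) {
    sp <- which(alignments$ref_start <= j - buffer & ref_end >= j + buffer)
    if (!length(sp)) return(NULL)
    ret_reads <- unique(ev$read_id[abs(ev$junction - j) <= buffer])
    data.frame(
      aln_idx = sp,
      read_id = alignments$read_id[sp],
      junction = j,
      status = ifelse(alignments$read_id[sp] %in% ret_reads,
                      "retained", "excised")
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
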