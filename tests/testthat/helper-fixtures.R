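# Fixtures are built in code at test time: tiny references, hand-specified
# alignments written as SAM text and converted to indexed BAM, and naive
# oracles for CIGAR walking used to cross-check the production extractors.

# Write a named sequence vector as FASTA and return the path.
write_test_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n),
                                                      seqs[[n]]))), path)
  path
}

# Build a coordinate-sorted indexed BAM from alignment specs.
# rows: list of lists with qname, flag (default 0), rname, pos (1-based),
# mapq (default 60), cigar, seq.
make_test_bam <- function(rows, ref, prefix = tempfile()) {
  fill <- function(r) {
    r$flag <- if (is.null(r$flag)) 0L else r$flag
    r$mapq <- if (is.null(r$mapq)) 60L else r$mapq
    r
  }
  rows <- lapply(rows, fill)
  pos <- vapply(rows, function(r) r$pos, 0)
  rn <- vapply(rows, function(r) r$rname, "")
  rows <- rows[order(match(rn, names(ref)), pos)]
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(ref), nchar(ref)))
  body <- vapply(rows, function(r) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
            r$qname, r$flag, r$rname, r$pos, r$mapq, r$cigar, r$seq,
            strrep("I", nchar(r$seq)))
  }, "")
  sam <- tempfile(fileext = ".sam")
  writeLines(c(header, body), sam)
  Rsamtools::asBam(sam, prefix, overwrite = TRUE, indexDestination = TRUE)
}

# Random reference sequence (AT-rich by default, like a ciliate MAC genome).
rand_seq <- function(n, gc = 0.28) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Random CIGAR string with its implied query length; used for oracle tests.
# Structure: optional leading/trailing S, alternating M with interior I/D.
rand_cigar <- function() {
  parts <- character(0)
  if (runif(1) < 0.3) parts <- c(parts, paste0(sample(5:50, 1), "S"))
  n_block <- sample(1:6, 1)
  for (b in seq_len(n_block)) {
    parts <- c(parts, paste0(sample(5:200, 1), "M"))
    if (b < n_block) {
      parts <- c(parts, paste0(sample(1:60, 1), sample(c("I", "D"), 1)))
    }
  }
  if (runif(1) < 0.3) parts <- c(parts, paste0(sample(5:50, 1), "S"))
  paste(parts, collapse = "")
}

# Naive per-base CIGAR walk: expands every op one base at a time, tracking
# reference and query cursors independently of the production code. Returns
# insertion and clip events.
naive_cigar_events <- function(cigar, ref_start) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  op <- substring(toks, nchar(toks), nchar(toks))
  len <- as.integer(substring(toks, 1, nchar(toks) - 1))
  refc <- 0L
  qryc <- 0L
  ins <- list()
  clips <- list()
  first_real <- TRUE
  for (i in seq_along(op)) {
    if (op[i] == "S") {
      side <- if (first_real) "left" else "right"
      bp <- if (side == "left") ref_start else ref_start + refc
      clips[[length(clips) + 1L]] <- list(side = side, breakpoint = bp,
                                          len = len[i], query_start = qryc)
      for (k in seq_len(len[i])) qryc <- qryc + 1L
    } else if (op[i] %in% c("M", "=", "X")) {
      first_real <- FALSE
      for (k in seq_len(len[i])) {
        refc <- refc + 1L
        qryc <- qryc + 1L
      }
    } else if (op[i] %in% c("D", "N")) {
      first_real <- FALSE
      for (k in seq_len(len[i])) refc <- refc + 1L
    } else if (op[i] == "I") {
      first_real <- FALSE
      ins[[length(ins) + 1L]] <- list(junction = ref_start + refc,
                                      query_start = qryc, len = len[i])
      for (k in seq_len(len[i])) qryc <- qryc + 1L
    }
  }
  list(ins = ins, clips = clips, ref_span = refc, query_len = qryc)
}

# Query sequence of the right length for a CIGAR.
seq_for_cigar <- function(cigar) {
  rand_seq(naive_cigar_events(cigar, 0L)$query_len, gc = 0.5)
}
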