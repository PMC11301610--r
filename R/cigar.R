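#' Parse a CIGAR string into operations
#'
#' @param cigar Character scalar, e.g. `"10M30I10M"`.
#' @return A data.frame with columns `op` (character) and `len` (integer),
#'   one row per CIGAR operation in order.
#' @keywords internal
parse_cigar <- function(cigar) {
  stopifnot(is.character(cigar), length(cigar) == 1L, !is.na(cigar))
  if (cigar == "" || cigar == "*") {
    return(data.frame(op = character(0), len = integer(0)))
  }
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) {
    stop("malformed CIGAR string: ", cigar)
  }
  data.frame(
    op = substring(toks, nchar(toks), nchar(toks)),
    len = as.integer(substring(toks, 1L, nchar(toks) - 1L))
  )
}

# Which ops consume reference / query coordinates (SAM spec).
REF_OPS <- c("M", "=", "X", "D", "N")
QRY_OPS <- c("M", "=", "X", "I", "S")

#' Reference length consumed by a CIGAR
#' @keywords internal
cigar_ref_span <- function(ops) sum(ops$len[ops$op %in% REF_OPS])

#' Per-op coordinate offsets for a CIGAR walk
#'
#' Returns, for each operation, the 0-based reference coordinate and the
#' 0-based query offset at which the operation starts.
#' @keywords internal
cigar_walk <- function(ops, ref_start) {
  refc <- ops$len * (ops$op %in% REF_OPS)
  qryc <- ops$len * (ops$op %in% QRY_OPS)
  data.frame(
    op = ops$op, len = ops$len,
    ref_at = ref_start + cumsum(refc) - refc,
    qry_at = cumsum(qryc) - qryc
  )
}
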