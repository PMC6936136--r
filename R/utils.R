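# Internal low-level helpers shared across modules.

#' Reverse complement of DNA strings
#'
#' Plain-character reverse complement; IUPAC bases other than ACGTN are
#' mapped through unchanged by complementation rules of [chartr()].
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  if (length(x) > 32L) {
    # C-speed path for bulk reverse complementation
    return(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
  }
  out <- chartr("ACGTacgtN", "TGCAtgcaN", x)
  vapply(out, function(s) {
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

# reverse plain strings (e.g. quality strings of reverse-strand records)
str_reverse <- function(x) {
  if (length(x) == 0L) return(character(0))
  if (length(x) > 32L) {
    return(as.character(Biostrings::reverse(Biostrings::BStringSet(x))))
  }
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' Parse a CIGAR string into operations
#'
#' @param cigar a single CIGAR string, e.g. "40M100N60M". "*" yields a
#'   zero-row result.
#' @return data.frame with columns `op` (character) and `len` (integer).
#' @keywords internal
#' @noRd
parse_cigar <- function(cigar) {
  if (is.na(cigar) || identical(cigar, "*")) {
    return(data.frame(op = character(0), len = integer(0)))
  }
  ml <- gregexpr("(\\d+)([MIDNSHP=X])", cigar, perl = TRUE)
  m <- ml[[1]]
  if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(cigar)) {
    stop("malformed CIGAR string: ", cigar)
  }
  toks <- regmatches(cigar, ml)[[1]]
  data.frame(
    op = substring(toks, nchar(toks), nchar(toks)),
    len = as.integer(substring(toks, 1L, nchar(toks) - 1L)),
    stringsAsFactors = FALSE
  )
}

# Reference bases consumed by a CIGAR (M, D, N, =, X consume reference).
cigar_reference_length <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
}

# Vectorized reference-consumption lengths for many CIGARs.
cigar_reference_lengths <- function(cigars) {
  if (!length(cigars)) return(integer(0))
  toks <- regmatches(cigars, gregexpr("(\\d+)([MIDNSHP=X])", cigars, perl = TRUE))
  ntok <- lengths(toks)
  check(all(ntok > 0L), "malformed CIGAR string among records")
  flat <- unlist(toks, use.names = FALSE)
  op <- substring(flat, nchar(flat), nchar(flat))
  len <- as.integer(substring(flat, 1L, nchar(flat) - 1L))
  len[!op %in% c("M", "D", "N", "=", "X")] <- 0L
  as.integer(rowsum(len, rep.int(seq_along(cigars), ntok)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stopifnot() with a formatted message
check <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

# Deterministic version of order() over character columns, independent of
# the user's collation locale.
c_order <- function(...) {
  args <- lapply(list(...), function(x) {
    if (is.character(x)) xtfrm(factor(x, levels = sort(unique(x), method = "radix"))) else x
  })
  do.call(order, args)
}
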