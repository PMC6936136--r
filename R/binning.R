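# Genomic binning of alignment records for parallel assembly.
#
# Bin i on a chromosome spans [i*S, (i+1)*S + V) in 0-based half-open
# coordinates (S = bin size, V = overlap), truncated at the chromosome
# end: consecutive bins share exactly V bases, so any interval of length
# <= V+1 lies wholly inside at least one bin. Bins extend past their
# core only on the right; a symmetric extension would double the
# duplication without improving that containment guarantee.

#' Define a binning scheme
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param bin_size core bin span S in bp (default 1 Mb).
#' @param overlap right-extension V in bp shared with the next bin
#'   (default 100 kb); must satisfy `0 <= overlap < bin_size`.
#' @return object of class `bin_scheme`.
#' @export
bin_scheme <- function(chrom_lengths, bin_size = 1e6, overlap = 1e5) {
  check(is.numeric(bin_size) && bin_size >= 1, "bin_size must be positive")
  check(is.numeric(overlap) && overlap >= 0 && overlap < bin_size,
        "overlap must satisfy 0 <= overlap < bin_size")
  check(!is.null(names(chrom_lengths)) && all(nzchar(names(chrom_lengths))),
        "chrom_lengths must be named")
  structure(list(bin_size = as.integer(bin_size), overlap = as.integer(overlap),
                 chrom_lengths = vapply(chrom_lengths, as.integer, integer(1))),
            class = "bin_scheme")
}

#' Enumerate the bins of a scheme
#'
#' @param scheme a `bin_scheme`.
#' @param chrom optional single chromosome to restrict to.
#' @return data.frame with columns `bin` (name `"chrom:index"`),
#'   `chrom`, `index`, `start`, `end` (0-based half-open, truncated at
#'   the chromosome end), in (chrom, index) order.
#' @export
bin_table <- function(scheme, chrom = NULL) {
  chroms <- if (is.null(chrom)) names(scheme$chrom_lengths) else chrom
  parts <- lapply(chroms, function(cn) {
    L <- scheme$chrom_lengths[[cn]]
    n <- max(1L, as.integer(ceiling(L / scheme$bin_size)))
    i <- 0:(n - 1L)
    data.frame(bin = paste0(cn, ":", i), chrom = cn, index = i,
               start = i * scheme$bin_size,
               end = pmin(L, (i + 1L) * scheme$bin_size + scheme$overlap),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

# Total order on bin names: (chrom, index), chromosome in C locale.
order_bin_names <- function(bins) {
  parts <- strsplit(bins, ":", fixed = TRUE)
  chrom <- vapply(parts, `[`, character(1), 1L)
  idx <- as.integer(vapply(parts, `[`, character(1), 2L))
  bins[c_order(chrom, idx)]
}

#' Reference span of mapped alignment records
#'
#' The genomic interval an alignment consumes: `[pos-1, pos-1 + len)` in
#' 0-based half-open coordinates, where `len` sums the M, D and N (and
#' `=`/`X`) CIGAR operation lengths. Soft clips consume no reference.
#'
#' @param records alignment record data.frame (all rows mapped).
#' @return data.frame with columns `start`, `end` (0-based half-open).
#' @export
reference_span <- function(records) {
  check(!anyNA(records$chrom) && !anyNA(records$pos),
        "reference_span is undefined for unmapped records")
  len <- cigar_reference_lengths(records$cigar)
  data.frame(start = records$pos - 1L, end = records$pos - 1L + len)
}

#' Bins overlapped by one mapped record
#'
#' Returns exactly the bins whose spans intersect the record's reference
#' span, in ascending index order.
#'
#' @param record one-row alignment record data.frame.
#' @param scheme a `bin_scheme`.
#' @return character vector of bin names (non-empty).
#' @export
bins_for_record <- function(record, scheme) {
  check(record$chrom[1] %in% names(scheme$chrom_lengths),
        "record chromosome '%s' unknown to the bin scheme", record$chrom[1])
  span <- reference_span(record[1, , drop = FALSE])
  bin_indices_for_span(span$start, span$end, record$chrom[1], scheme)
}

# Vectorized bin-range computation; returns names for one span.
bin_indices_for_span <- function(s, e, chrom, scheme) {
  S <- scheme$bin_size; V <- scheme$overlap
  L <- scheme$chrom_lengths[[chrom]]
  n_bins <- max(1L, as.integer(ceiling(L / S)))
  i0 <- max(0L, as.integer((s - V) %/% S))
  i1 <- min(n_bins - 1L, as.integer((e - 1L) %/% S))
  check(i1 >= i0, "record span [%d,%d) intersects no bin on %s", s, e, chrom)
  paste0(chrom, ":", i0:i1)
}

#' Strip sequence payloads from alignment records
#'
#' Sets `seq` and `qual` to `"*"` (they are not used by assembly); all
#' other fields are untouched.
#'
#' @param records alignment record data.frame.
#' @return the stripped records.
#' @export
strip_payload <- function(records) {
  records$seq <- rep("*", nrow(records))
  records$qual <- rep("*", nrow(records))
  records
}

#' Emit (bin, stripped record) pairs for a set of alignment records
#'
#' Unmapped records are dropped (they carry no positional evidence); a
#' mapped record is emitted once per bin its full reference span —
#' introns included — overlaps.
#'
#' @param records alignment record data.frame.
#' @param scheme a `bin_scheme`.
#' @return data.frame of stripped records with a leading `bin` column;
#'   one row per (record, bin) incidence.
#' @export
assign_bins <- function(records, scheme) {
  records <- records[!is.na(records$chrom), , drop = FALSE]
  if (nrow(records) == 0L) {
    out <- cbind(bin = character(0), strip_payload(empty_records()))
    return(out)
  }
  unknown <- setdiff(unique(records$chrom), names(scheme$chrom_lengths))
  check(length(unknown) == 0L, "record chromosome '%s' unknown to the bin scheme",
        paste(unknown, collapse = ", "))
  span <- reference_span(records)
  S <- scheme$bin_size; V <- scheme$overlap
  n_bins <- pmax(1L, as.integer(ceiling(scheme$chrom_lengths[records$chrom] / S)))
  i0 <- pmax(0L, as.integer((span$start - V) %/% S))
  i1 <- pmin(n_bins - 1L, as.integer((span$end - 1L) %/% S))
  reps <- i1 - i0 + 1L
  check(all(reps >= 1L), "record with empty reference span cannot be binned")
  rows <- rep(seq_len(nrow(records)), reps)
  idx <- unlist(lapply(seq_len(nrow(records)), function(r) i0[r]:i1[r]))
  out <- strip_payload(records[rows, , drop = FALSE])
  out <- cbind(bin = paste0(records$chrom[rows], ":", idx), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Group bin-assigned records and coordinate-sort within each bin
#'
#' Grouping and the within-bin sort by `(pos, qname, flag)` — a total
#' order — make the output independent of input arrival order and of
#' parallelism degree.
#'
#' @param assigned data.frame from [assign_bins()] (a `bin` column plus
#'   record columns), in any row order.
#' @return named list of record data.frames, names sorted in bin order
#'   (chromosome, then index).
#' @export
partition_records <- function(assigned) {
  if (nrow(assigned) == 0L) return(stats::setNames(list(), character(0)))
  bins <- order_bin_names(unique(assigned$bin))
  out <- lapply(bins, function(b) {
    recs <- assigned[assigned$bin == b, setdiff(names(assigned), "bin"),
                     drop = FALSE]
    recs <- recs[c_order(recs$pos, recs$qname, recs$flag), , drop = FALSE]
    rownames(recs) <- NULL
    recs
  })
  stats::setNames(out, bins)
}
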