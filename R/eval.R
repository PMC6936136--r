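# Six-level transcript accuracy evaluation of a query annotation
# against a reference annotation: base, exon, intron, intron chain,
# transcript and locus. Sensitivity = 100 * matched reference features /
# reference features; precision = 100 * correct query features / query
# features. Undefined ratios (empty denominators) are NA, never 0.

eval_levels <- c("base", "exon", "intron", "intron_chain", "transcript", "locus")

# distinct exon interval keys of an annotation (strand-agnostic)
distinct_exons <- function(ts) {
  if (nrow(ts) == 0L) return(character(0))
  unique(unlist(lapply(seq_len(nrow(ts)), function(i) {
    ex <- ts$exons[[i]]
    paste0(ts$chrom[i], ":", ex[, 1L], "-", ex[, 2L])
  })))
}

distinct_introns <- function(ts) {
  if (nrow(ts) == 0L) return(character(0))
  unique(unlist(lapply(seq_len(nrow(ts)), function(i) {
    intr <- exon_introns(ts$exons[[i]])
    if (nrow(intr) == 0L) return(character(0))
    paste0(ts$chrom[i], ":", intr[, 1L], "-", intr[, 2L])
  })))
}

# exonic base positions as IRanges per chromosome (reduced union)
exonic_ranges <- function(ts) {
  if (nrow(ts) == 0L) return(list())
  per_chrom <- split(seq_len(nrow(ts)), ts$chrom)
  lapply(per_chrom, function(rows) {
    s <- unlist(lapply(ts$exons[rows], function(e) e[, 1L]))
    e <- unlist(lapply(ts$exons[rows], function(e) e[, 2L]))
    IRanges::reduce(IRanges::IRanges(s, e))
  })
}

base_counts <- function(q_ranges, r_ranges) {
  chroms <- union(names(q_ranges), names(r_ranges))
  matched <- 0L; q_total <- 0L; r_total <- 0L
  for (cn in chroms) {
    qr <- q_ranges[[cn]]; rr <- r_ranges[[cn]]
    if (!is.null(qr)) q_total <- q_total + sum(IRanges::width(qr))
    if (!is.null(rr)) r_total <- r_total + sum(IRanges::width(rr))
    if (!is.null(qr) && !is.null(rr))
      matched <- matched + sum(IRanges::width(IRanges::intersect(qr, rr)))
  }
  c(matched = matched, q_total = q_total, r_total = r_total)
}

# single-exon reciprocal overlap rule: overlap >= threshold of the
# LONGER transcript (the stricter reading of the 80% rule)
single_exon_match <- function(ex_a, ex_b, threshold = 0.8) {
  ov <- max(0L, min(ex_a[1L, 2L], ex_b[1L, 2L]) -
              max(ex_a[1L, 1L], ex_b[1L, 1L]) + 1L)
  longer <- max(ex_a[1L, 2L] - ex_a[1L, 1L], ex_b[1L, 2L] - ex_b[1L, 1L]) + 1L
  ov / longer >= threshold
}

# per-record transcript matching against the other annotation
transcript_matches <- function(ts, other) {
  if (nrow(ts) == 0L) return(logical(0))
  other_chain <- chain_key(other)
  vapply(seq_len(nrow(ts)), function(i) {
    ch <- chain_key(ts[i, , drop = FALSE])
    if (!is.na(ch)) {
      any(!is.na(other_chain) & other_chain == ch &
            strand_compatible(other$strand, ts$strand[i]))
    } else {
      ex_i <- ts$exons[[i]]
      cand <- which(other$chrom == ts$chrom[i] & tx_nexon(other) == 1L &
                      strand_compatible(other$strand, ts$strand[i]))
      any(vapply(cand, function(j)
        single_exon_match(ex_i, other$exons[[j]]), logical(1)))
    }
  }, logical(1))
}

# single-linkage loci by exonic overlap: component ids per transcript
cluster_loci <- function(ts) {
  n <- nrow(ts)
  if (n == 0L) return(integer(0))
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) comp[max(ri, rj)] <<- min(ri, rj) }
  # overlapping exons chain transcripts together; group via reduced blocks
  for (cn in unique(ts$chrom)) {
    rows <- which(ts$chrom == cn)
    s <- unlist(lapply(ts$exons[rows], function(e) e[, 1L]))
    e <- unlist(lapply(ts$exons[rows], function(e) e[, 2L]))
    owner <- rep(rows, vapply(ts$exons[rows], nrow, integer(1)))
    ir <- IRanges::IRanges(s, e)
    # min.gapwidth = 0: merge only genuinely overlapping exons
    blocks <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, blocks)
    bl <- S4Vectors::subjectHits(hit)
    ow <- owner[S4Vectors::queryHits(hit)]
    for (b in unique(bl)) {
      members <- unique(ow[bl == b])
      if (length(members) > 1L)
        for (m in members[-1L]) unite(members[1L], m)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

ratio_pct <- function(num, den) if (den > 0L) 100 * num / den else NA_real_

#' Compare a query annotation to a reference at six feature levels
#'
#' Matching rules: base level counts exonic base positions
#' (strand-agnostic union over transcripts); exon and intron levels
#' count distinct exact intervals; intron-chain level counts distinct
#' full ordered chains of multi-exon transcripts, matched exactly; a
#' transcript matches when its intron chain is identical to a reference
#' transcript's (multi-exon) or when a single-exon reference transcript
#' overlaps it by at least 80% of the longer of the two (single-exon),
#' with unknown strand (`.`) compatible with either strand; loci are
#' single-linkage clusters of transcripts by exonic overlap, a reference
#' locus matched when it contains a matched reference transcript and a
#' query locus correct when it contains a matched query transcript.
#' At transcript level the query total counts transcript records, and
#' only one record per distinct matched structure counts as correct, so
#' redundant duplicate structures lower precision.
#'
#' @param query,reference `transcript_set`s on the same genome
#'   coordinate system.
#' @return object of class `eval_report`: data.frame with one row per
#'   level and columns `level`, `ref_matched`, `ref_total`,
#'   `query_matched`, `query_total`, `sensitivity`, `precision`.
#' @export
compare_annotations <- function(query, reference) {
  validate_transcripts(query)
  validate_transcripts(reference)
  rows <- list()
  add <- function(level, rm, rt, qm, qt) {
    rows[[length(rows) + 1L]] <<- data.frame(
      level = level, ref_matched = rm, ref_total = rt,
      query_matched = qm, query_total = qt,
      sensitivity = ratio_pct(rm, rt), precision = ratio_pct(qm, qt),
      stringsAsFactors = FALSE)
  }

  bc <- base_counts(exonic_ranges(query), exonic_ranges(reference))
  add("base", bc[["matched"]], bc[["r_total"]], bc[["matched"]], bc[["q_total"]])

  qe <- distinct_exons(query); re <- distinct_exons(reference)
  m <- length(intersect(qe, re))
  add("exon", m, length(re), m, length(qe))

  qi <- distinct_introns(query); ri <- distinct_introns(reference)
  m <- length(intersect(qi, ri))
  add("intron", m, length(ri), m, length(qi))

  qc <- unique(stats::na.omit(chain_key(query)))
  rc <- unique(stats::na.omit(chain_key(reference)))
  m <- length(intersect(qc, rc))
  add("intron_chain", m, length(rc), m, length(qc))

  r_matched <- transcript_matches(reference, query)
  q_matched <- transcript_matches(query, reference)
  # duplicates of an already-counted structure are redundant, not correct
  q_first <- !duplicated(structure_key(query))
  add("transcript", sum(r_matched), nrow(reference),
      sum(q_matched & q_first), nrow(query))

  r_loci <- cluster_loci(reference)
  q_loci <- cluster_loci(query)
  rl_matched <- length(unique(r_loci[r_matched]))
  ql_matched <- length(unique(q_loci[q_matched]))
  add("locus", rl_matched, length(unique(r_loci)),
      ql_matched, length(unique(q_loci)))

  out <- do.call(rbind, rows)
  class(out) <- c("eval_report", "data.frame")
  out
}

#' Format an evaluation report as a text table
#'
#' Six rows with sensitivity and precision columns, one decimal place;
#' undefined cells print as `NA`.
#'
#' @param report an `eval_report`.
#' @return character vector of table lines.
#' @export
report_to_text <- function(report) {
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.1f", x))
  c(sprintf("%-14s %11s %11s", "level", "sensitivity", "precision"),
    sprintf("%-14s %11s %11s", report$level, fmt(report$sensitivity),
            fmt(report$precision)))
}

#' Parse a table produced by [report_to_text()]
#'
#' @param lines character vector of table lines.
#' @return data.frame with `level`, `sensitivity`, `precision` (numeric,
#'   NA where the table shows NA).
#' @export
parse_report_text <- function(lines) {
  body <- lines[-1L]
  parts <- strsplit(trimws(body), "\\s+")
  data.frame(
    level = vapply(parts, `[`, character(1), 1L),
    sensitivity = suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L))),
    precision = suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 3L))),
    stringsAsFactors = FALSE)
}

#' @export
print.eval_report <- function(x, ...) {
  writeLines(report_to_text(x))
  invisible(x)
}
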