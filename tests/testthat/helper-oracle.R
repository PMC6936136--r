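# Independent naive oracles. These deliberately avoid the package's
# implementation machinery (no IRanges, no keys): plain loops and
# integer position sets, so agreement with the fast paths is meaningful.

oracle_exon_list <- function(ts) {
  out <- character(0)
  for (i in seq_len(nrow(ts))) {
    ex <- ts$exons[[i]]
    for (e in seq_len(nrow(ex)))
      out <- c(out, paste0(ts$chrom[i], ":", ex[e, 1], "-", ex[e, 2]))
  }
  out
}

oracle_intron_list <- function(ts) {
  out <- character(0)
  for (i in seq_len(nrow(ts))) {
    ex <- ts$exons[[i]]
    if (nrow(ex) < 2) next
    for (e in seq_len(nrow(ex) - 1))
      out <- c(out, paste0(ts$chrom[i], ":", ex[e, 2] + 1, "-", ex[e + 1, 1] - 1))
  }
  out
}

oracle_chain <- function(ts, i) {
  ex <- ts$exons[[i]]
  if (nrow(ex) < 2) return(NA_character_)
  paste0(ts$chrom[i], "|",
         paste(ex[-nrow(ex), 2] + 1, ex[-1, 1] - 1, sep = ":", collapse = ";"))
}

oracle_positions <- function(ts) {
  # exonic base positions encoded "chrom.pos"
  out <- character(0)
  for (i in seq_len(nrow(ts))) {
    ex <- ts$exons[[i]]
    for (e in seq_len(nrow(ex)))
      out <- c(out, paste0(ts$chrom[i], ".", ex[e, 1]:ex[e, 2]))
  }
  unique(out)
}

oracle_strand_ok <- function(a, b) a == b || a == "." || b == "."

oracle_tx_match <- function(ts, i, other) {
  ch <- oracle_chain(ts, i)
  if (!is.na(ch)) {
    for (j in seq_len(nrow(other))) {
      if (identical(oracle_chain(other, j), ch) &&
          oracle_strand_ok(ts$strand[i], other$strand[j])) return(TRUE)
    }
    return(FALSE)
  }
  ex <- ts$exons[[i]]
  for (j in seq_len(nrow(other))) {
    oe <- other$exons[[j]]
    if (nrow(oe) != 1 || other$chrom[j] != ts$chrom[i] ||
        !oracle_strand_ok(ts$strand[i], other$strand[j])) next
    ov <- min(ex[1, 2], oe[1, 2]) - max(ex[1, 1], oe[1, 1]) + 1
    longer <- max(ex[1, 2] - ex[1, 1], oe[1, 2] - oe[1, 1]) + 1
    if (ov > 0 && ov / longer >= 0.8) return(TRUE)
  }
  FALSE
}

# single-linkage clustering by exonic overlap via O(n^2) closure
oracle_loci <- function(ts) {
  n <- nrow(ts)
  if (n == 0) return(integer(0))
  touches <- function(i, j) {
    if (ts$chrom[i] != ts$chrom[j]) return(FALSE)
    a <- ts$exons[[i]]; b <- ts$exons[[j]]
    for (x in seq_len(nrow(a))) for (y in seq_len(nrow(b)))
      if (a[x, 1] <= b[y, 2] && b[y, 1] <= a[x, 2]) return(TRUE)
    FALSE
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] && touches(i, j)) {
        m <- min(comp[i], comp[j]); comp[comp == comp[i] | comp == comp[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

oracle_structure <- function(ts, i) {
  ex <- ts$exons[[i]]
  paste0(ts$chrom[i], "(", ts$strand[i], "):",
         paste(ex[, 1], ex[, 2], sep = "-", collapse = ","))
}

oracle_compare <- function(query, reference) {
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  row <- function(level, rm, rt, qm, qt)
    data.frame(level = level, ref_matched = rm, ref_total = rt,
               query_matched = qm, query_total = qt,
               sensitivity = pct(rm, rt), precision = pct(qm, qt),
               stringsAsFactors = FALSE)
  qp <- oracle_positions(query); rp <- oracle_positions(reference)
  m <- length(intersect(qp, rp))
  out <- row("base", m, length(rp), m, length(qp))
  qe <- unique(oracle_exon_list(query)); re <- unique(oracle_exon_list(reference))
  m <- length(intersect(qe, re))
  out <- rbind(out, row("exon", m, length(re), m, length(qe)))
  qi <- unique(oracle_intron_list(query)); ri <- unique(oracle_intron_list(reference))
  m <- length(intersect(qi, ri))
  out <- rbind(out, row("intron", m, length(ri), m, length(qi)))
  qc <- unique(stats::na.omit(vapply(seq_len(nrow(query)), function(i)
    oracle_chain(query, i), character(1))))
  rc <- unique(stats::na.omit(vapply(seq_len(nrow(reference)), function(i)
    oracle_chain(reference, i), character(1))))
  m <- length(intersect(qc, rc))
  out <- rbind(out, row("intron_chain", m, length(rc), m, length(qc)))
  r_m <- vapply(seq_len(nrow(reference)), function(i)
    oracle_tx_match(reference, i, query), logical(1))
  q_m <- vapply(seq_len(nrow(query)), function(i)
    oracle_tx_match(query, i, reference), logical(1))
  seen <- character(0)
  q_first <- logical(nrow(query))
  for (i in seq_len(nrow(query))) {
    s <- oracle_structure(query, i)
    q_first[i] <- !(s %in% seen)
    seen <- c(seen, s)
  }
  out <- rbind(out, row("transcript", sum(r_m), nrow(reference),
                        sum(q_m & q_first), nrow(query)))
  rl <- oracle_loci(reference); ql <- oracle_loci(query)
  out <- rbind(out, row("locus", length(unique(rl[r_m])), length(unique(rl)),
                        length(unique(ql[q_m])), length(unique(ql))))
  out
}

# brute-force bin assignment: test every bin of the scheme for
# interval intersection
oracle_bins_for_span <- function(s, e, chrom, scheme) {
  tab <- bin_table(scheme, chrom)
  hits <- tab$bin[tab$start < e & s < tab$end]
  hits
}
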