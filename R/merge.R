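# Bin-overlap redundancy removal and merging of assembled transcripts
# with a reference annotation.

#' Remove bin-overlap redundancy among assembled transcripts
#'
#' Transcripts that are structurally identical — same chromosome,
#' strand, intron chain and exon coordinates — were assembled
#' independently by adjacent overlapping bins; exactly one copy
#' survives, the one from the lowest-ordered origin bin (ties keep the
#' first occurrence). Idempotent, and never removes the last copy of a
#' structure.
#'
#' @param ts a `transcript_set` whose rows carry `origin_bin` tags.
#' @return the deduplicated `transcript_set`.
#' @export
remove_bin_redundancy <- function(ts) {
  if (nrow(ts) < 2L) return(ts)
  key <- structure_key(ts)
  bins <- ifelse(is.na(ts$origin_bin), "", ts$origin_bin)
  parts <- strsplit(bins, ":", fixed = TRUE)
  bchrom <- vapply(parts, function(p) if (length(p)) p[1] else "", character(1))
  bidx <- vapply(parts, function(p)
    if (length(p) > 1L) suppressWarnings(as.integer(p[2])) else NA_integer_,
    integer(1))
  bidx[is.na(bidx)] <- .Machine$integer.max
  ord <- c_order(key, bchrom, bidx, seq_len(nrow(ts)))
  keep <- ord[!duplicated(key[ord])]
  out <- ts[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exonic-overlap width of two exon matrices (shared chromosome assumed)
exonic_overlap_width <- function(ex_a, ex_b) {
  ir_a <- IRanges::IRanges(ex_a[, 1L], ex_a[, 2L])
  ir_b <- IRanges::IRanges(ex_b[, 1L], ex_b[, 2L])
  sum(IRanges::width(IRanges::intersect(ir_a, ir_b)))
}

strand_compatible <- function(a, b) a == b | a == "." | b == "."

#' Merge assembled transcripts with a reference annotation
#'
#' The merged annotation contains every reference transcript unchanged.
#' An assembled multi-exon transcript is absorbed when a reference
#' transcript matches its (chromosome, strand, intron chain); an
#' assembled single-exon transcript is absorbed when a same-strand (or
#' unknown-strand) reference single-exon transcript overlaps it by at
#' least 80% of the longer of the two. Anything else is added as novel
#' with a fresh id, attached to an overlapping strand-compatible
#' reference gene when one exists, otherwise to a new gene. Output is
#' sorted by (chromosome, start, transcript id), so merging is
#' insensitive to the assembled list's input order.
#'
#' @param assembled a `transcript_set` (typically deduplicated with
#'   [remove_bin_redundancy()]).
#' @param reference the reference `transcript_set`.
#' @param single_exon_overlap reciprocal-overlap threshold for
#'   single-exon absorption, as a fraction of the longer transcript
#'   (default 0.8, the evaluator's single-exon rule).
#' @return the merged `transcript_set` (`source` of added transcripts is
#'   `"assembled"`, of kept reference rows `"reference"`).
#' @export
merge_with_reference <- function(assembled, reference,
                                 single_exon_overlap = 0.8) {
  validate_transcripts(assembled)
  validate_transcripts(reference)
  ref <- reference
  ref$source <- "reference"

  if (nrow(assembled) == 0L) {
    out <- sort_annotation(ref)
    return(out)
  }
  ref_chain <- chain_key(ref)
  ref_multi <- !is.na(ref_chain)
  asm_chain <- chain_key(assembled)

  novel <- logical(nrow(assembled))
  for (i in seq_len(nrow(assembled))) {
    if (!is.na(asm_chain[i])) {
      hit <- which(ref_multi & ref_chain == asm_chain[i] &
                     strand_compatible(ref$strand, assembled$strand[i]))
      novel[i] <- length(hit) == 0L
    } else {
      ex_a <- assembled$exons[[i]]
      len_a <- ex_a[1L, 2L] - ex_a[1L, 1L] + 1L
      cand <- which(!ref_multi & ref$chrom == assembled$chrom[i] &
                      tx_nexon(ref) == 1L &
                      strand_compatible(ref$strand, assembled$strand[i]))
      absorbed <- FALSE
      for (j in cand) {
        ex_r <- ref$exons[[j]]
        len_r <- ex_r[1L, 2L] - ex_r[1L, 1L] + 1L
        ov <- max(0L, min(ex_a[1L, 2L], ex_r[1L, 2L]) -
                    max(ex_a[1L, 1L], ex_r[1L, 1L]) + 1L)
        if (ov / max(len_a, len_r) >= single_exon_overlap) { absorbed <- TRUE; break }
      }
      novel[i] <- !absorbed
    }
  }

  added <- assembled[novel, , drop = FALSE]
  if (nrow(added)) {
    # normalize incoming order so the merge result is order-invariant
    added <- added[c_order(added$chrom, tx_start(added), tx_end(added),
                           structure_key(added)), , drop = FALSE]
    # drop structural duplicates among the novel set itself
    added <- added[!duplicated(structure_key(added)), , drop = FALSE]
    new_gene <- 0L
    for (i in seq_len(nrow(added))) {
      ex_a <- added$exons[[i]]
      host <- NA_character_
      for (j in which(ref$chrom == added$chrom[i] &
                        strand_compatible(ref$strand, added$strand[i]))) {
        if (exonic_overlap_width(ex_a, ref$exons[[j]]) > 0L) {
          host <- ref$gene_id[j]
          break
        }
      }
      if (is.na(host)) {
        new_gene <- new_gene + 1L
        host <- sprintf("NOVELG.%s.%d", added$chrom[i], new_gene)
      }
      added$gene_id[i] <- host
    }
    added$transcript_id <- sprintf("NOVEL.%d", seq_len(nrow(added)))
    added$source <- "assembled"
  }
  sort_annotation(bind_transcripts(ref, added))
}

sort_annotation <- function(ts) {
  if (nrow(ts) < 2L) return(ts)
  out <- ts[c_order(ts$chrom, tx_start(ts), ts$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
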