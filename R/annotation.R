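# Strand-aware exon-chain transcript container and GTF serialization.
# Coordinates are 1-based inclusive throughout, matching GTF.

#' Construct a transcript set
#'
#' The package's annotation container: one row per transcript, with the
#' exon chain held as a list-column of two-column integer matrices
#' (columns `start`, `end`; 1-based inclusive; ascending and
#' non-overlapping, with at least a 1 bp gap — the intron — between
#' consecutive exons).
#'
#' @param transcript_id,gene_id,chrom character vectors.
#' @param strand character vector over `+`, `-`, `.` (unknown).
#' @param exons list of integer matrices with columns start, end.
#' @param source character vector tagging provenance (`reference`,
#'   `assembled`, `merged`, ...).
#' @param origin_bin bin name (`"chrom:index"`) the transcript was
#'   assembled in, or `NA`.
#' @return object of class `transcript_set` (a data.frame).
#' @export
transcript_set <- function(transcript_id = character(0),
                           gene_id = character(0),
                           chrom = character(0),
                           strand = character(0),
                           exons = list(),
                           source = "assembled",
                           origin_bin = NA_character_) {
  n <- length(transcript_id)
  exons <- lapply(exons, normalize_exons)
  out <- data.frame(transcript_id = as.character(transcript_id),
                    gene_id = as.character(gene_id),
                    chrom = as.character(chrom),
                    strand = as.character(strand),
                    source = rep_len(as.character(source), n),
                    origin_bin = rep_len(as.character(origin_bin), n),
                    stringsAsFactors = FALSE)
  out$exons <- exons
  check(all(out$strand %in% c("+", "-", ".")),
        "strand must be one of '+', '-', '.'")
  class(out) <- c("transcript_set", "data.frame")
  validate_transcripts(out)
  out
}

normalize_exons <- function(ex) {
  ex <- matrix(as.integer(ex), ncol = 2L,
               dimnames = list(NULL, c("start", "end")))
  ex[order(ex[, 1L]), , drop = FALSE]
}

validate_transcripts <- function(ts) {
  for (i in seq_len(nrow(ts))) {
    ex <- ts$exons[[i]]
    ok <- nrow(ex) >= 1L && all(ex[, 2L] >= ex[, 1L]) &&
      (nrow(ex) < 2L || all(ex[-1L, 1L] > ex[-nrow(ex), 2L] + 1L))
    check(ok, "transcript %s: exons must be ascending, non-overlapping, separated by >= 1 bp",
          ts$transcript_id[i])
  }
  invisible(ts)
}

empty_transcript_set <- function() transcript_set()

#' Bind transcript sets
#'
#' @param ... `transcript_set` objects.
#' @return combined `transcript_set`.
#' @export
bind_transcripts <- function(...) {
  parts <- Filter(function(x) nrow(x) > 0L, list(...))
  if (!length(parts)) return(empty_transcript_set())
  out <- do.call(rbind.data.frame, c(parts, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("transcript_set", "data.frame")
  out
}

#' @export
`[.transcript_set` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && "exons" %in% names(out)) {
    class(out) <- c("transcript_set", "data.frame")
    rownames(out) <- NULL
  }
  out
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("transcript_set: %d transcripts, %d genes, %d chromosome(s)\n",
              nrow(x), length(unique(x$gene_id)), length(unique(x$chrom))))
  if (nrow(x)) {
    show <- utils::head(x, 6L)
    cat(sprintf("  %s %s %s:%d-%d [%s] %d exon(s)\n", show$transcript_id,
                show$strand, show$chrom,
                vapply(show$exons, function(e) e[1, 1], integer(1)),
                vapply(show$exons, function(e) e[nrow(e), 2], integer(1)),
                show$source, vapply(show$exons, nrow, integer(1))))
    if (nrow(x) > 6L) cat(sprintf("  ... and %d more\n", nrow(x) - 6L))
  }
  invisible(x)
}

# Intron matrix (1-based inclusive) of one exon matrix; 0 rows if single exon.
exon_introns <- function(ex) {
  n <- nrow(ex)
  if (n < 2L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = ex[-n, 2L] + 1L, end = ex[-1L, 1L] - 1L)
}

# "chrom:s-e,s-e" key of the ordered intron chain ("" for single-exon).
chain_key <- function(ts) {
  vapply(seq_len(nrow(ts)), function(i) {
    intr <- exon_introns(ts$exons[[i]])
    if (nrow(intr) == 0L) return(NA_character_)
    paste0(ts$chrom[i], ":", paste(intr[, 1L], intr[, 2L], sep = "-", collapse = ","))
  }, character(1))
}

# Full exon-structure key including strand (identity used for dedup).
structure_key <- function(ts) {
  vapply(seq_len(nrow(ts)), function(i) {
    ex <- ts$exons[[i]]
    paste0(ts$chrom[i], "(", ts$strand[i], "):",
           paste(ex[, 1L], ex[, 2L], sep = "-", collapse = ","))
  }, character(1))
}

#' Transcript accessors
#'
#' Genomic start, end and exon count per transcript.
#'
#' @param ts a `transcript_set`.
#' @return integer vector, one element per transcript.
#' @export
tx_start <- function(ts) vapply(ts$exons, function(e) e[1L, 1L], integer(1))

#' @rdname tx_start
#' @export
tx_end <- function(ts) vapply(ts$exons, function(e) e[nrow(e), 2L], integer(1))

#' @rdname tx_start
#' @export
tx_nexon <- function(ts) vapply(ts$exons, nrow, integer(1))

#' Write a transcript set as GTF
#'
#' Emits one `transcript` feature followed by its `exon` features per
#' transcript, 1-based inclusive coordinates, attributes `gene_id`,
#' `transcript_id` and (when set) `origin_bin`; the provenance tag is
#' carried in the GTF source column. An empty set produces a
#' comment-only file.
#'
#' @param ts a `transcript_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(ts, path) {
  validate_transcripts(ts)
  lines <- "##gff-version 2"
  if (nrow(ts)) {
    per_tx <- lapply(seq_len(nrow(ts)), function(i) {
      ex <- ts$exons[[i]]
      attr_bin <- if (!is.na(ts$origin_bin[i]))
        sprintf(" origin_bin \"%s\";", ts$origin_bin[i]) else ""
      attrs <- sprintf("gene_id \"%s\"; transcript_id \"%s\";%s",
                       ts$gene_id[i], ts$transcript_id[i], attr_bin)
      src <- ts$source[i]
      c(sprintf("%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                ts$chrom[i], src, ex[1L, 1L], ex[nrow(ex), 2L], ts$strand[i], attrs),
        sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                ts$chrom[i], src, ex[, 1L], ex[, 2L], ts$strand[i], attrs))
    })
    lines <- c(lines, unlist(per_tx))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GTF annotation into a transcript set
#'
#' Parses with `rtracklayer::import` and reconstructs transcripts from
#' `exon` features grouped by `transcript_id`. Transcript order follows
#' first appearance in the file.
#'
#' @param path path to a GTF file.
#' @return a `transcript_set`.
#' @export
read_annotation_gtf <- function(path) {
  check(file.exists(path), "GTF file not found: %s", path)
  raw <- readLines(path)
  if (!any(nzchar(raw) & !startsWith(raw, "#"))) return(empty_transcript_set())
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  check(length(ex) > 0L, "GTF %s contains no exon features", path)
  tid <- ex$transcript_id
  ord <- match(unique(tid), tid)
  md <- S4Vectors::mcols(ex)
  origin <- if ("origin_bin" %in% names(md)) as.character(md$origin_bin[ord])
            else rep(NA_character_, length(ord))
  starts <- split(GenomicRanges::start(ex), tid)
  ends <- split(GenomicRanges::end(ex), tid)
  uids <- unique(tid)
  exons <- lapply(uids, function(id) cbind(start = starts[[id]], end = ends[[id]]))
  transcript_set(
    transcript_id = uids,
    gene_id = as.character(md$gene_id[ord]),
    chrom = as.character(GenomicRanges::seqnames(ex))[ord],
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(ex))[ord]),
    exons = exons,
    source = as.character(md$source[ord]),
    origin_bin = origin
  )
}
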