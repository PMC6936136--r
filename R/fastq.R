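#' Read a FASTQ file into a record table
#'
#' Reads plain or gzipped FASTQ (gzip is detected from the stream content,
#' not the file extension). Each record is four lines: `@id`, sequence,
#' `+`, quality.
#'
#' @param path path to a FASTQ file, optionally gzip-compressed.
#' @return data.frame with character columns `id` (without the leading
#'   `@`), `seq` and `qual`.
#' @export
read_fastq <- function(path) {
  check(file.exists(path), "FASTQ file not found: %s", path)
  # gzfile() transparently reads both gzip and plain text by magic bytes
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  }
  check(length(lines) %% 4L == 0L,
        "malformed FASTQ %s: %d lines is not a multiple of 4 (truncated record near line %d)",
        path, length(lines), 4L * (length(lines) %/% 4L) + 1L)
  idx <- seq(1L, length(lines), by = 4L)
  bad <- idx[substr(lines[idx], 1L, 1L) != "@"]
  check(length(bad) == 0L,
        "malformed FASTQ %s: record header at line %d does not start with '@'",
        path, if (length(bad)) bad[1] else 0L)
  seqs <- lines[idx + 1L]
  quals <- lines[idx + 3L]
  badlen <- which(nchar(seqs) != nchar(quals))
  check(length(badlen) == 0L,
        "malformed FASTQ %s: sequence/quality length mismatch at line %d",
        path, if (length(badlen)) idx[badlen[1]] + 1L else 0L)
  data.frame(id = substring(lines[idx], 2L), seq = seqs, qual = quals,
             stringsAsFactors = FALSE)
}

#' Write a FASTQ record table
#'
#' @param records data.frame as returned by [read_fastq()].
#' @param path output path; a `.gz` suffix selects gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (nrow(records)) {
    writeLines(paste0("@", records$id, "\n", records$seq, "\n+\n", records$qual),
               con, sep = "\n")
  }
  invisible(path)
}

#' Normalize a read identifier
#'
#' Strips the mate designator so that the two mates of a pair share one
#' identifier. Both the classic `/1` / `/2` suffix dialect and the
#' Casava-style ` 1:...` / ` 2:...` comment dialect are recognized.
#'
#' @param id character vector of raw FASTQ identifiers.
#' @return character vector of normalized identifiers.
#' @export
normalize_read_id <- function(id) {
  id <- sub(" [12]:.*$", "", id)
  sub("/[12]$", "", id)
}

#' Describe one sample's paired FASTQ files
#'
#' @param sample_name sample identifier used in chunk and output names.
#' @param mate1_path,mate2_path paths to the two mate FASTQ files.
#' @return object of class `sample_manifest` (a one-row data.frame).
#' @export
sample_manifest <- function(sample_name, mate1_path, mate2_path) {
  out <- data.frame(sample_name = sample_name, mate1_path = mate1_path,
                    mate2_path = mate2_path, stringsAsFactors = FALSE)
  class(out) <- c("sample_manifest", "data.frame")
  out
}

#' Read a tab-separated manifest of samples
#'
#' The file must have a header line with columns `sample_name`,
#' `mate1_path`, `mate2_path`.
#'
#' @param path path to the TSV manifest.
#' @return a `sample_manifest` data.frame, one row per sample.
#' @export
read_sample_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check(all(c("sample_name", "mate1_path", "mate2_path") %in% names(df)),
        "manifest %s must have columns sample_name, mate1_path, mate2_path", path)
  class(df) <- c("sample_manifest", "data.frame")
  df
}

#' Split one sample's paired FASTQ files into interleaved read chunks
#'
#' Pairs are formed positionally from the two mate files (record i of
#' mate1 with record i of mate2) and grouped into chunks of `chunk_size`
#' pairs; only the last chunk may be smaller. Chunking is a pure function
#' of the input records and `chunk_size`, so any parallel consumer sees
#' the same chunks. An empty sample yields zero chunks.
#'
#' @param manifest a one-row `sample_manifest` (or data.frame with the
#'   same columns) describing the sample.
#' @param chunk_size positive integer number of read pairs per chunk.
#' @return list of `read_chunk` objects, each a list with elements
#'   `sample_name`, `chunk_index` (0-based) and `pairs` (data.frame with
#'   columns `read_id`, `seq1`, `qual1`, `seq2`, `qual2`).
#' @export
split_sample <- function(manifest, chunk_size = 65536L) {
  check(is.numeric(chunk_size) && length(chunk_size) == 1L && chunk_size >= 1,
        "chunk_size must be a positive integer")
  m1 <- read_fastq(manifest$mate1_path[1])
  m2 <- read_fastq(manifest$mate2_path[1])
  sample_name <- manifest$sample_name[1]
  check(nrow(m1) == nrow(m2),
        "sample %s: mate files disagree on record count (%d vs %d)",
        sample_name, nrow(m1), nrow(m2))
  n <- nrow(m1)
  if (n == 0L) return(list())
  chunk_size <- as.integer(min(chunk_size, n))
  id1 <- normalize_read_id(m1$id)
  id2 <- normalize_read_id(m2$id)
  bad <- which(id1 != id2)
  check(length(bad) == 0L,
        "sample %s: mate read ids disagree at record %d ('%s' vs '%s')",
        sample_name, if (length(bad)) bad[1] else 0L,
        if (length(bad)) m1$id[bad[1]] else "", if (length(bad)) m2$id[bad[1]] else "")
  pairs <- data.frame(read_id = id1, seq1 = m1$seq, qual1 = m1$qual,
                      seq2 = m2$seq, qual2 = m2$qual, stringsAsFactors = FALSE)
  starts <- seq(1L, n, by = chunk_size)
  lapply(seq_along(starts), function(i) {
    rows <- starts[i]:min(starts[i] + chunk_size - 1L, n)
    chunk <- list(sample_name = sample_name, chunk_index = i - 1L,
                  pairs = pairs[rows, , drop = FALSE])
    rownames(chunk$pairs) <- NULL
    class(chunk) <- "read_chunk"
    chunk
  })
}

#' Recover the two mate streams from a list of read chunks
#'
#' Inverse of [split_sample()]: chunks are concatenated in
#' `chunk_index` order and de-interleaved back into mate1 and mate2
#' record tables, reproducing the original record order.
#'
#' @param chunks list of `read_chunk` objects with contiguous indices
#'   starting at 0.
#' @param mate1_path,mate2_path optional output FASTQ paths; when given
#'   the streams are also written with [write_fastq()].
#' @return list with data.frame elements `mate1` and `mate2`.
#' @export
deinterleave <- function(chunks, mate1_path = NULL, mate2_path = NULL) {
  if (length(chunks)) {
    idx <- vapply(chunks, `[[`, integer(1), "chunk_index")
    chunks <- chunks[order(idx)]
    idx <- sort(idx)
    check(identical(idx, seq_along(idx) - 1L),
          "chunk indices not contiguous from 0: missing %s",
          paste(setdiff(seq_len(max(idx) + 1L) - 1L, idx), collapse = ", "))
    pairs <- do.call(rbind, lapply(chunks, `[[`, "pairs"))
  } else {
    pairs <- data.frame(read_id = character(0), seq1 = character(0),
                        qual1 = character(0), seq2 = character(0),
                        qual2 = character(0), stringsAsFactors = FALSE)
  }
  out <- list(
    mate1 = data.frame(id = pairs$read_id, seq = pairs$seq1, qual = pairs$qual1,
                       stringsAsFactors = FALSE),
    mate2 = data.frame(id = pairs$read_id, seq = pairs$seq2, qual = pairs$qual2,
                       stringsAsFactors = FALSE)
  )
  if (!is.null(mate1_path)) write_fastq(out$mate1, mate1_path)
  if (!is.null(mate2_path)) write_fastq(out$mate2, mate2_path)
  out
}

#' Serialize a read chunk as interleaved FASTQ
#'
#' Writes mate1 record then mate2 record for each pair, to
#' `<sample>.chunk<idx>.fastq` under `dir`.
#'
#' @param chunk a `read_chunk`.
#' @param dir output directory.
#' @return the file path, invisibly.
#' @export
write_chunk_fastq <- function(chunk, dir) {
  path <- file.path(dir, sprintf("%s.chunk%d.fastq", chunk$sample_name,
                                 chunk$chunk_index))
  p <- chunk$pairs
  con <- file(path, "wt")
  on.exit(close(con))
  if (nrow(p)) {
    writeLines(paste0("@", p$read_id, "/1\n", p$seq1, "\n+\n", p$qual1, "\n",
                      "@", p$read_id, "/2\n", p$seq2, "\n+\n", p$qual2),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read an interleaved chunk FASTQ written by [write_chunk_fastq()]
#'
#' @param path path of form `<sample>.chunk<idx>.fastq`.
#' @return a `read_chunk` object.
#' @export
read_chunk_fastq <- function(path) {
  recs <- read_fastq(path)
  check(nrow(recs) %% 2L == 0L, "interleaved chunk %s has odd record count", path)
  base <- basename(path)
  m <- regmatches(base, regexec("^(.*)\\.chunk(\\d+)\\.fastq$", base))[[1]]
  check(length(m) == 3L, "chunk file name %s not of form <sample>.chunk<idx>.fastq", base)
  o <- if (nrow(recs)) seq(1L, nrow(recs), by = 2L) else integer(0)
  chunk <- list(
    sample_name = m[2], chunk_index = as.integer(m[3]),
    pairs = data.frame(read_id = normalize_read_id(recs$id[o]),
                       seq1 = recs$seq[o], qual1 = recs$qual[o],
                       seq2 = recs$seq[o + 1L], qual2 = recs$qual[o + 1L],
                       stringsAsFactors = FALSE)
  )
  class(chunk) <- "read_chunk"
  chunk
}
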