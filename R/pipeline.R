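# End-to-end drivers for the two processing modes. Parallelism is a
# pool of independent tasks over chunks/bins whose results are merged
# in key order, so the output is a pure function of the input and the
# configuration — invariant under worker count and completion order.

#' Pipeline configuration
#'
#' @param chunk_size read pairs per chunk (default 65536).
#' @param workers parallel workers for chunk alignment and per-bin
#'   assembly (forked via [parallel::mclapply]; 1 = serial).
#' @param k seed length of the built-in aligner.
#' @param bin_size,bin_overlap binning geometry in bp (defaults 1 Mb /
#'   100 kb; see [bin_scheme()]).
#' @param min_cov,min_junction_support,max_paths_per_component assembly
#'   parameters (see [assembly_params()]).
#' @param max_bin_records hard cap on records per bin; an oversized bin
#'   fails with guidance rather than exhausting worker memory.
#' @param guided use the reference annotation during per-bin assembly.
#' @param compare run the evaluation stage against the reference.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(chunk_size = 65536L, workers = 1L, k = 25L,
                            bin_size = 1e6, bin_overlap = 1e5,
                            min_cov = 1.0, min_junction_support = 1L,
                            max_paths_per_component = 64L,
                            max_bin_records = 5e6, guided = TRUE,
                            compare = FALSE) {
  structure(list(chunk_size = as.integer(chunk_size),
                 workers = as.integer(workers), k = as.integer(k),
                 bin_size = bin_size, bin_overlap = bin_overlap,
                 min_cov = min_cov,
                 min_junction_support = as.integer(min_junction_support),
                 max_paths_per_component = as.integer(max_paths_per_component),
                 max_bin_records = max_bin_records,
                 guided = isTRUE(guided), compare = isTRUE(compare)),
            class = "pipeline_config")
}

pipeline_pool <- function(tasks, fun, workers) {
  if (workers > 1L && .Platform$OS.type == "unix") {
    res <- parallel::mclapply(tasks, fun, mc.cores = workers,
                              mc.preschedule = TRUE)
    for (r in res) {
      if (inherits(r, "try-error"))
        stop(attr(r, "condition") %||% conditionMessage(simpleError(as.character(r))))
    }
    res
  } else {
    lapply(tasks, fun)
  }
}

log_stage <- function(log_con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  if (!is.null(log_con)) writeLines(msg, log_con)
  invisible(msg)
}

state_path <- function(output_dir) file.path(output_dir, "pipeline_state.tsv")

mark_stage_done <- function(output_dir, stage) {
  write(sprintf("%s\tdone", stage), state_path(output_dir), append = TRUE)
}

#' Run the alignment-only mode
#'
#' Two stages per sample: every read chunk is aligned and written to a
#' temporary location, then the per-sample chunk alignments are
#' concatenated in chunk order into one alignment file (header from the
#' first chunk, `@PG`/`@CO` dropped; chunk files deleted as consumed).
#' The record set of each per-sample file is identical to a sequential
#' unchunked run of the same deterministic aligner, and the output
#' bytes are invariant under `workers` and task completion order.
#'
#' @param manifest a `sample_manifest` data.frame or the path of a TSV
#'   manifest.
#' @param genome genome (named character vector, DNAStringSet, FASTA
#'   path) or a prebuilt `aligner_index`.
#' @param config a [pipeline_config()].
#' @param output_dir directory receiving `<sample>.sam` files, the
#'   stage log and the resumable state file.
#' @param adapter an `aligner_adapter` (default built-in).
#' @return named character vector of per-sample alignment paths.
#' @export
run_alignment_mode <- function(manifest, genome, config = pipeline_config(),
                               output_dir, adapter = builtin_aligner()) {
  if (is.character(manifest)) manifest <- read_sample_manifest(manifest)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(state_path(output_dir))
  log_con <- file(file.path(output_dir, "alignment_mode.log"), "wt")
  on.exit(close(log_con))
  index <- if (inherits(genome, "aligner_index")) genome else
    build_index(genome, k = config$k)
  temp_dir <- file.path(output_dir, "tmp_chunks")
  dir.create(temp_dir, showWarnings = FALSE)

  if (nrow(manifest) == 0L) {
    log_stage(log_con, "0 samples; nothing to do")
    return(stats::setNames(character(0), character(0)))
  }
  chunks <- list()
  for (s in seq_len(nrow(manifest))) {
    sc <- split_sample(manifest[s, , drop = FALSE], config$chunk_size)
    log_stage(log_con, "split sample=%s pairs=%d chunks=%d",
              manifest$sample_name[s],
              sum(vapply(sc, function(x) nrow(x$pairs), integer(1))), length(sc))
    chunks <- c(chunks, sc)
  }
  mark_stage_done(output_dir, "split")

  aligned <- pipeline_pool(chunks, function(ch)
    align_chunk(ch, adapter, index, temp_dir = temp_dir), config$workers)
  for (a in aligned)
    log_stage(log_con, "aligned sample=%s chunk=%d records=%d",
              a$sample_name, a$chunk_index, nrow(a$records))
  mark_stage_done(output_dir, "align")

  out <- stats::setNames(character(0), character(0))
  for (sn in manifest$sample_name) {
    mine <- aligned[vapply(aligned, function(a) a$sample_name == sn, logical(1))]
    idx <- vapply(mine, `[[`, integer(1), "chunk_index")
    paths <- vapply(mine, `[[`, character(1), "path")[order(idx)]
    dest <- file.path(output_dir, paste0(sn, ".sam"))
    concatenate_sample(sn, paths, dest)
    log_stage(log_con, "concatenated sample=%s chunks=%d -> %s",
              sn, length(paths), dest)
    out[sn] <- dest
  }
  unlink(temp_dir, recursive = TRUE)
  mark_stage_done(output_dir, "concatenate")
  out
}

#' Run the transcript assembly mode
#'
#' Stages, in order: chunk, align, bin (strip payloads, emit each
#' mapped record to every overlapping bin, group and coordinate-sort),
#' assemble per bin (optionally guided by the chromosome-filtered
#' reference), collect in bin order, remove bin-overlap redundancy,
#' merge with the reference (skipped when no reference is given), and
#' optionally compare the merged annotation against the reference. The
#' final GTF bytes are invariant under `workers` and completion order.
#'
#' @inheritParams run_alignment_mode
#' @param reference_annotation a `transcript_set`, a GTF path, or
#'   `NULL` to skip guidance and merging.
#' @return list with `annotation` (the final `transcript_set`),
#'   `gtf_path`, `assembled` (deduplicated pre-merge assembly), and
#'   `report` (an `eval_report`, or `NULL` when comparison is off).
#' @export
run_assembly_mode <- function(manifest, genome, reference_annotation = NULL,
                              config = pipeline_config(), output_dir,
                              adapter = builtin_aligner()) {
  if (is.character(manifest)) manifest <- read_sample_manifest(manifest)
  if (is.character(reference_annotation))
    reference_annotation <- read_annotation_gtf(reference_annotation)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(state_path(output_dir))
  log_con <- file(file.path(output_dir, "assembly_mode.log"), "wt")
  on.exit(close(log_con))
  index <- if (inherits(genome, "aligner_index")) genome else
    build_index(genome, k = config$k)
  scheme <- bin_scheme(index$chrom_lengths, config$bin_size, config$bin_overlap)
  params <- assembly_params(config$min_cov, config$min_junction_support,
                            config$max_paths_per_component)

  chunks <- list()
  for (s in seq_len(nrow(manifest))) {
    chunks <- c(chunks, split_sample(manifest[s, , drop = FALSE],
                                     config$chunk_size))
  }
  log_stage(log_con, "split: %d chunks over %d samples", length(chunks),
            nrow(manifest))
  mark_stage_done(output_dir, "split")

  aligned <- pipeline_pool(chunks, function(ch)
    align_chunk(ch, adapter, index, temp_dir = NULL), config$workers)
  records <- do.call(rbind, c(lapply(aligned, `[[`, "records"),
                              list(empty_records())))
  log_stage(log_con, "align: %d records (%d mapped)", nrow(records),
            sum(!is.na(records$chrom)))
  mark_stage_done(output_dir, "align")

  assigned <- assign_bins(records, scheme)
  groups <- partition_records(assigned)
  log_stage(log_con, "bin: %d bin incidences over %d non-empty bins",
            nrow(assigned), length(groups))
  oversized <- names(groups)[vapply(groups, nrow, integer(1)) > config$max_bin_records]
  check(length(oversized) == 0L, paste0(
    "bin(s) %s exceed max_bin_records (%d); remediations: ",
    "(1) divide samples into smaller batches and merge the assemblies, ",
    "(2) raise the per-worker memory budget / max_bin_records, ",
    "(3) run alignment-only mode and assemble the merged alignments directly"),
    paste(oversized, collapse = ", "), config$max_bin_records)
  mark_stage_done(output_dir, "bin")

  bins <- bin_table(scheme)
  per_bin <- pipeline_pool(names(groups), function(b) {
    pa <- if (config$guided && !is.null(reference_annotation))
      filter_annotation_for_bin(reference_annotation, b) else NULL
    span <- unlist(bins[bins$bin == b, c("start", "end")], use.names = FALSE)
    assemble_bin(groups[[b]], index$genome, params, partial_annotation = pa,
                 bin = b, bin_span = span)
  }, config$workers)
  names(per_bin) <- names(groups)
  assembled <- collect_transcripts(per_bin)
  log_stage(log_con, "assemble: %d transcripts over %d bins", nrow(assembled),
            length(per_bin))
  mark_stage_done(output_dir, "assemble")

  deduped <- remove_bin_redundancy(assembled)
  log_stage(log_con, "dedup: %d -> %d transcripts", nrow(assembled),
            nrow(deduped))
  mark_stage_done(output_dir, "dedup")

  if (!is.null(reference_annotation)) {
    final <- merge_with_reference(deduped, reference_annotation)
    log_stage(log_con, "merge: %d reference + %d assembled -> %d transcripts",
              nrow(reference_annotation), nrow(deduped), nrow(final))
  } else {
    final <- sort_annotation(deduped)
    log_stage(log_con, "merge skipped (no reference); emitting %d transcripts",
              nrow(final))
  }
  mark_stage_done(output_dir, "merge")

  gtf_path <- file.path(output_dir, "updated_annotation.gtf")
  write_annotation_gtf(final, gtf_path)

  report <- NULL
  if (config$compare && !is.null(reference_annotation)) {
    report <- compare_annotations(final, reference_annotation)
    writeLines(report_to_text(report),
               file.path(output_dir, "comparison_stats.txt"))
    mark_stage_done(output_dir, "compare")
  }
  list(annotation = final, gtf_path = gtf_path, assembled = deduped,
       report = report)
}
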