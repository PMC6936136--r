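# Shared fixture builders. Everything is generated in code at test time;
# no data files.

# small, fast simulation world used by most pipeline tests
tiny_cfg <- function(...) {
  args <- list(n_chromosomes = 1L, chrom_length = 2e5, n_genes = 3L,
               isoforms_per_gene = 2L, reads_per_transcript = 60L, seed = 11L)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# write a pair of FASTQ files and return a sample_manifest row
write_pair_files <- function(mate1, mate2, dir, sample = "s1", gz = FALSE) {
  ext <- if (gz) ".fastq.gz" else ".fastq"
  p1 <- file.path(dir, paste0(sample, "_1", ext))
  p2 <- file.path(dir, paste0(sample, "_2", ext))
  write_fastq(mate1, p1)
  write_fastq(mate2, p2)
  sample_manifest(sample, p1, p2)
}

fastq_records <- function(ids, seqs, quals = strrep("I", nchar(seqs))) {
  data.frame(id = ids, seq = seqs, qual = quals, stringsAsFactors = FALSE)
}

# n random read pairs over a random alphabet (round-trip fixtures)
random_pairs_fastq <- function(n, len = 12L, seed = 1L) {
  set.seed(seed)
  mk <- function() vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
  qual <- vapply(seq_len(n), function(i)
    intToUtf8(sample(33:73, len, replace = TRUE)), character(1))
  ids <- sprintf("read%03d", seq_len(n))
  list(mate1 = fastq_records(paste0(ids, "/1"), mk(), qual),
       mate2 = fastq_records(paste0(ids, "/2"), mk(), qual))
}

# one-row alignment record
rec <- function(qname, flag, chrom, pos, cigar, seq = "*", qual = "*") {
  data.frame(qname = qname, flag = as.integer(flag), chrom = chrom,
             pos = as.integer(pos), cigar = cigar, seq = seq, qual = qual,
             stringsAsFactors = FALSE)
}

# simple transcript_set builder: exon list given as c(s1,e1, s2,e2, ...)
tx <- function(id, exons, chrom = "chr1", strand = "+", gene = paste0(id, ".g"),
               source = "assembled", origin_bin = NA_character_) {
  transcript_set(id, gene, chrom, strand,
                 list(matrix(exons, ncol = 2L, byrow = TRUE)),
                 source = source, origin_bin = origin_bin)
}

# random small annotation for evaluator fuzzing: a few transcripts on
# 1-2 chromosomes with mixed single-/multi-exon structures
random_annotation <- function(seed, n_min = 1L, n_max = 6L) {
  set.seed(seed)
  n <- sample(n_min:n_max, 1L)
  parts <- lapply(seq_len(n), function(i) {
    chrom <- sample(c("chr1", "chr2"), 1L)
    strand <- sample(c("+", "-", "."), 1L)
    n_ex <- sample(1:4, 1L)
    pos <- sample(1:2500, 1L)
    starts <- integer(n_ex); ends <- integer(n_ex)
    for (e in seq_len(n_ex)) {
      starts[e] <- pos
      ends[e] <- pos + sample(20:150, 1L)
      pos <- ends[e] + sample(10:100, 1L) + 1L
    }
    tx(sprintf("s%d.t%d", seed, i), as.vector(t(cbind(starts, ends))),
       chrom = chrom, strand = strand, gene = sprintf("s%d.g%d", seed, i))
  })
  do.call(bind_transcripts, parts)
}

# a (query, reference) pair sharing some structures: reference random,
# query = some copied reference transcripts (ids renamed, occasionally
# duplicated) plus fresh random ones
random_annotation_pair <- function(seed) {
  ref <- random_annotation(seed * 2L + 1L)
  set.seed(seed * 2L + 2L)
  copies <- which(stats::runif(nrow(ref)) < 0.5)
  q <- ref[copies, , drop = FALSE]
  if (nrow(q)) {
    q$transcript_id <- paste0("q.", q$transcript_id)
    dup <- which(stats::runif(nrow(q)) < 0.3)
    if (length(dup)) {
      d <- q[dup, , drop = FALSE]
      d$transcript_id <- paste0(d$transcript_id, ".dup")
      q <- bind_transcripts(q, d)
    }
  }
  fresh <- random_annotation(seed * 2L + 500000L, n_min = 0L, n_max = 3L)
  if (nrow(fresh)) fresh$transcript_id <- paste0("q.", fresh$transcript_id)
  list(query = bind_transcripts(q, fresh), reference = ref)
}

# build an aligner index once per session for the shared tiny world
shared_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- tiny_cfg()
      truth <- simulate_genome_and_annotation(cfg)
      reads <- simulate_reads(truth, cfg)
      index <- build_index(truth$genome, k = 25L)
      cache <<- list(cfg = cfg, truth = truth, reads = reads, index = index)
    }
    cache
  }
})

pairs_of_sample <- function(world, sample = "sample1") {
  s <- world$reads$samples[[sample]]
  tt <- world$reads$truth_table
  ids <- tt$read_id[tt$sample == sample]
  data.frame(read_id = ids, seq1 = s$mate1$seq, qual1 = s$mate1$qual,
             seq2 = s$mate2$seq, qual2 = s$mate2$qual,
             stringsAsFactors = FALSE)
}
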