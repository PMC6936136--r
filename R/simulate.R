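# Synthetic genome / annotation / paired-end read generator with exact
# ground truth. Emulates a zero-error 100-bp paired-end simulation with
# a fixed number of read pairs per transcript, at desk scale.

#' Simulation configuration
#'
#' Defaults state the package's reference simulation world: a 2-Mb
#' genome of 2 chromosomes carrying 20 non-overlapping genes with 2
#' disjoint isoforms each, sequenced as zero-error 100-bp paired-end
#' reads at 1000 pairs per transcript.
#'
#' @param n_chromosomes,chrom_length genome shape (bp per chromosome).
#' @param n_genes number of genes, placed non-overlapping with
#'   >= `gene_gap` bp between them.
#' @param isoforms_per_gene isoforms per gene; in disjoint mode they
#'   share no exons or junctions.
#' @param exons_per_transcript,exon_length,intron_length inclusive
#'   `c(min, max)` ranges; minimum exon length must be >= `read_length`
#'   so each read touches at most one junction, and introns must be >= 4
#'   bp to leave room for splice motifs.
#' @param read_length mate length in bp (default 100).
#' @param reads_per_transcript pairs drawn per transcript (default 1000).
#' @param fragment_mean,fragment_sd fragment-length model (bp).
#' @param error_rate per-base substitution probability (default 0).
#' @param n_samples transcripts are partitioned round-robin across this
#'   many samples to emulate single-cell heterogeneity.
#' @param disjoint_isoforms lay isoforms of a gene out over disjoint
#'   genomic intervals (the assembler's exact-recovery regime).
#' @param gene_gap minimum gap between genes (default 1000 bp).
#' @param seed integer seed; all outputs are a pure function of the
#'   configuration including the seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2L, chrom_length = 1e6,
                       n_genes = 20L, isoforms_per_gene = 2L,
                       exons_per_transcript = c(2L, 6L),
                       exon_length = c(150L, 400L),
                       intron_length = c(100L, 1000L),
                       read_length = 100L, reads_per_transcript = 1000L,
                       fragment_mean = 250, fragment_sd = 25,
                       error_rate = 0, n_samples = 1L,
                       disjoint_isoforms = TRUE, gene_gap = 1000L,
                       seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              isoforms_per_gene = as.integer(isoforms_per_gene),
              exons_per_transcript = as.integer(exons_per_transcript),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              read_length = as.integer(read_length),
              reads_per_transcript = as.integer(reads_per_transcript),
              fragment_mean = fragment_mean, fragment_sd = fragment_sd,
              error_rate = error_rate, n_samples = as.integer(n_samples),
              disjoint_isoforms = isTRUE(disjoint_isoforms),
              gene_gap = as.integer(gene_gap), seed = as.integer(seed))
  check(cfg$exon_length[1] >= cfg$read_length,
        "minimum exon length (%d) must be >= read_length (%d)",
        cfg$exon_length[1], cfg$read_length)
  check(cfg$intron_length[1] >= 4L, "introns must be >= 4 bp for splice motifs")
  check(cfg$error_rate >= 0 && cfg$error_rate < 1, "error_rate must be in [0,1)")
  check(all(cfg$exons_per_transcript >= 1L), "exons_per_transcript must be >= 1")
  class(cfg) <- "sim_config"
  cfg
}

rint <- function(n, range) if (range[1] == range[2]) rep(range[1], n) else
  sample(range[1]:range[2], n, replace = TRUE)

#' Simulate a genome and a matching multi-isoform annotation
#'
#' Genes are placed non-overlapping (>= `gene_gap` bp apart) on random
#' A/C/G/T sequence; after placement every intron's boundary
#' dinucleotides are overwritten so that, on the gene's strand, each
#' intron begins `GT` and ends `AG` (genomic `CT..AC` for `-` genes) —
#' this is what makes motif-based strand inference work downstream. In
#' disjoint-isoform mode the isoforms of a gene occupy disjoint genomic
#' sub-intervals, so they share no exons or junctions.
#'
#' @param config a [sim_config()].
#' @return object of class `ground_truth`: list with `genome` (named
#'   character vector), `annotation` (`transcript_set`) and `config`.
#' @export
simulate_genome_and_annotation <- function(config) {
  set.seed(config$seed)
  genome <- vapply(seq_len(config$n_chromosomes), function(i)
    paste(sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE),
          collapse = ""), character(1))
  names(genome) <- paste0("chr", seq_len(config$n_chromosomes))

  iso_gap <- 200L
  tx_id <- character(0); gene_id <- character(0); chrom <- character(0)
  strand <- character(0); exons <- list()
  cursor <- stats::setNames(rep(0L, config$n_chromosomes), names(genome))
  patches <- list()  # (chrom, pos, dinucleotide) to stamp splice motifs

  for (g in seq_len(config$n_genes)) {
    cn <- names(genome)[(g - 1L) %% config$n_chromosomes + 1L]
    gstrand <- sample(c("+", "-"), 1L)
    gid <- sprintf("gene%d", g)
    pos <- cursor[[cn]] + config$gene_gap
    for (iso in seq_len(config$isoforms_per_gene)) {
      n_ex <- rint(1L, config$exons_per_transcript)
      ex_len <- rint(n_ex, config$exon_length)
      in_len <- if (n_ex > 1L) rint(n_ex - 1L, config$intron_length) else integer(0)
      starts <- integer(n_ex); ends <- integer(n_ex)
      p <- pos + 1L
      for (e in seq_len(n_ex)) {
        starts[e] <- p; ends[e] <- p + ex_len[e] - 1L
        if (e < n_ex) p <- ends[e] + in_len[e] + 1L
      }
      check(ends[n_ex] <= config$chrom_length,
            "gene layout exceeds chromosome length %d; need >= %d bp (reduce n_genes or sizes)",
            config$chrom_length, ends[n_ex] + config$gene_gap)
      for (e in seq_len(n_ex - 1L)) {
        d <- ends[e] + 1L; a <- starts[e + 1L] - 1L  # intron [d, a]
        if (gstrand == "+") {
          patches[[length(patches) + 1L]] <- list(cn, d, "GT")
          patches[[length(patches) + 1L]] <- list(cn, a - 1L, "AG")
        } else {
          patches[[length(patches) + 1L]] <- list(cn, d, "CT")
          patches[[length(patches) + 1L]] <- list(cn, a - 1L, "AC")
        }
      }
      tx_id <- c(tx_id, sprintf("%s.t%d", gid, iso))
      gene_id <- c(gene_id, gid)
      chrom <- c(chrom, cn)
      strand <- c(strand, gstrand)
      exons <- c(exons, list(cbind(start = starts, end = ends)))
      pos <- if (config$disjoint_isoforms) ends[n_ex] + iso_gap else pos
    }
    cursor[[cn]] <- max(vapply(exons[gene_id == gid], function(e)
      e[nrow(e), 2L], integer(1)))
  }

  for (p in patches) {
    substr(genome[[p[[1]]]], p[[2]], p[[2]] + 1L) <- p[[3]]
  }

  truth <- list(genome = genome,
                annotation = transcript_set(tx_id, gene_id, chrom, strand,
                                            exons, source = "reference"),
                config = config)
  class(truth) <- "ground_truth"
  truth
}

# spliced (mRNA) sequence of a transcript on its own strand
spliced_sequence <- function(truth, i) {
  ts <- truth$annotation
  ex <- ts$exons[[i]]
  s <- paste(substring(truth$genome[[ts$chrom[i]]], ex[, 1L], ex[, 2L]),
             collapse = "")
  if (ts$strand[i] == "-") revcomp(s) else s
}

inject_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  hit <- which(stats::runif(n) < rate)
  if (!length(hit)) return(seq)
  ch <- strsplit(seq, "")[[1]]
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Simulate paired-end reads from a ground truth
#'
#' For each transcript, `reads_per_transcript` fragments are drawn with
#' uniformly distributed start positions along the spliced sequence;
#' mate1 is the first `read_length` bases of the fragment, mate2 the
#' reverse complement of the last `read_length` bases. Substitution
#' errors are injected at `error_rate` per base. Transcripts shorter
#' than the minimum fragment (the read length) are skipped with a
#' warning. Transcripts are partitioned round-robin across
#' `n_samples` samples.
#'
#' @param truth a `ground_truth` from [simulate_genome_and_annotation()].
#' @param config the same [sim_config()].
#' @return list with `samples` (named list; per sample a list with
#'   `mate1` and `mate2` FASTQ record data.frames) and `truth_table`
#'   (data.frame: `read_id`, `sample`, `transcript_id`, `offset`
#'   0-based fragment start on the spliced sequence, `frag_len`).
#' @export
simulate_reads <- function(truth, config) {
  set.seed(config$seed + 1L)
  ts <- truth$annotation
  rl <- config$read_length
  samples <- stats::setNames(
    lapply(seq_len(config$n_samples), function(i)
      list(mate1 = list(), mate2 = list())),
    sprintf("sample%d", seq_len(config$n_samples)))
  tt <- list()
  for (i in seq_len(nrow(ts))) {
    sseq <- spliced_sequence(truth, i)
    L <- nchar(sseq)
    if (L < rl) {
      warning(sprintf("transcript %s (%d bp) shorter than a fragment; skipped",
                      ts$transcript_id[i], L), call. = FALSE)
      next
    }
    smp <- sprintf("sample%d", (i - 1L) %% config$n_samples + 1L)
    n <- config$reads_per_transcript
    flen <- pmin(L, pmax(rl, round(stats::rnorm(n, config$fragment_mean,
                                                config$fragment_sd))))
    off <- vapply(L - flen, function(m) sample.int(m + 1L, 1L) - 1L, integer(1))
    frag <- substring(sseq, off + 1L, off + flen)
    m1 <- substring(frag, 1L, rl)
    m2 <- revcomp(substring(frag, flen - rl + 1L, flen))
    if (config$error_rate > 0) {
      m1 <- vapply(m1, inject_errors, character(1), rate = config$error_rate,
                   USE.NAMES = FALSE)
      m2 <- vapply(m2, inject_errors, character(1), rate = config$error_rate,
                   USE.NAMES = FALSE)
    }
    ids <- sprintf("%s_r%04d", ts$transcript_id[i], seq_len(n))
    qual <- strrep("I", rl)
    samples[[smp]]$mate1[[length(samples[[smp]]$mate1) + 1L]] <-
      data.frame(id = paste0(ids, "/1"), seq = m1, qual = qual,
                 stringsAsFactors = FALSE)
    samples[[smp]]$mate2[[length(samples[[smp]]$mate2) + 1L]] <-
      data.frame(id = paste0(ids, "/2"), seq = m2, qual = qual,
                 stringsAsFactors = FALSE)
    tt[[length(tt) + 1L]] <- data.frame(
      read_id = ids, sample = smp, transcript_id = ts$transcript_id[i],
      offset = off, frag_len = flen, stringsAsFactors = FALSE)
  }
  samples <- lapply(samples, function(s)
    list(mate1 = if (length(s$mate1)) do.call(rbind, s$mate1) else
           data.frame(id = character(0), seq = character(0), qual = character(0)),
         mate2 = if (length(s$mate2)) do.call(rbind, s$mate2) else
           data.frame(id = character(0), seq = character(0), qual = character(0))))
  list(samples = samples,
       truth_table = if (length(tt)) do.call(rbind, tt) else
         data.frame(read_id = character(0), sample = character(0),
                    transcript_id = character(0), offset = integer(0),
                    frag_len = integer(0)))
}

#' Expected genomic alignments of simulated mates
#'
#' Maps each truth-table fragment back through the annotation to the
#' 1-based genomic position and CIGAR each mate must align with at zero
#' error. Mate1 sits at the fragment's 5' end on the transcript, mate2
#' at the 3' end (reverse-complemented); on `-`-strand transcripts the
#' genomic roles swap.
#'
#' @param truth a `ground_truth`.
#' @param truth_table the table from [simulate_reads()].
#' @param read_length mate length used in the simulation.
#' @return data.frame: `read_id`, `mate` (1/2), `chrom`, `pos`, `cigar`,
#'   `rev` (logical: aligned to the genomic minus strand).
#' @export
truth_alignments <- function(truth, truth_table, read_length) {
  ts <- truth$annotation
  out <- vector("list", 2L * nrow(truth_table))
  for (r in seq_len(nrow(truth_table))) {
    i <- match(truth_table$transcript_id[r], ts$transcript_id)
    ex <- ts$exons[[i]]
    L <- sum(ex[, 2L] - ex[, 1L] + 1L)
    minus <- ts$strand[i] == "-"
    for (mate in 1:2) {
      # transcript-coordinate interval of this mate (0-based half-open)
      t0 <- if (mate == 1L) truth_table$offset[r] else
        truth_table$offset[r] + truth_table$frag_len[r] - read_length
      # on '-' transcripts, transcript coordinate x maps to genomic L-1-x
      g0 <- if (minus) L - (t0 + read_length) else t0
      aln <- spliced_interval_to_genomic(ex, g0, read_length)
      rev_flag <- xor(mate == 2L, minus)
      out[[2L * (r - 1L) + mate]] <- data.frame(
        read_id = truth_table$read_id[r], mate = mate,
        chrom = ts$chrom[i], pos = aln$pos, cigar = aln$cigar,
        rev = rev_flag, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# genomic position + CIGAR of a length-`len` window starting at 0-based
# offset g0 of the exon-concatenated (genomic order) sequence
spliced_interval_to_genomic <- function(ex, g0, len) {
  widths <- ex[, 2L] - ex[, 1L] + 1L
  cum <- cumsum(c(0L, widths))
  first_ex <- findInterval(g0, cum, rightmost.closed = FALSE)
  pos <- ex[first_ex, 1L] + (g0 - cum[first_ex])
  remaining <- len
  parts <- character(0)
  e <- first_ex
  cur <- pos
  while (remaining > 0L) {
    avail <- ex[e, 2L] - cur + 1L
    take <- min(avail, remaining)
    parts <- c(parts, paste0(take, "M"))
    remaining <- remaining - take
    if (remaining > 0L) {
      intron <- ex[e + 1L, 1L] - ex[e, 2L] - 1L
      parts <- c(parts, paste0(intron, "N"))
      e <- e + 1L
      cur <- ex[e, 1L]
    }
  }
  list(pos = pos, cigar = paste(parts, collapse = ""))
}

#' Simulate a full dataset and write it to disk
#'
#' Writes the genome FASTA, the annotation GTF, gzipped paired FASTQ
#' files per sample, the truth table TSV, and a `manifest.tsv` usable by
#' [run_alignment_mode()] / [run_assembly_mode()].
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing).
#' @return list with `truth`, `reads`, and the written `paths`.
#' @export
simulate_dataset <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulate_genome_and_annotation(config)
  reads <- simulate_reads(truth, config)
  genome_path <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(truth$genome), genome_path)
  gtf_path <- file.path(out_dir, "annotation.gtf")
  write_annotation_gtf(truth$annotation, gtf_path)
  manifest <- data.frame(sample_name = names(reads$samples),
                         mate1_path = NA_character_, mate2_path = NA_character_,
                         stringsAsFactors = FALSE)
  for (i in seq_along(reads$samples)) {
    sn <- names(reads$samples)[i]
    manifest$mate1_path[i] <- file.path(out_dir, paste0(sn, "_1.fastq.gz"))
    manifest$mate2_path[i] <- file.path(out_dir, paste0(sn, "_2.fastq.gz"))
    write_fastq(reads$samples[[i]]$mate1, manifest$mate1_path[i])
    write_fastq(reads$samples[[i]]$mate2, manifest$mate2_path[i])
  }
  tt_path <- file.path(out_dir, "truth_table.tsv")
  utils::write.table(reads$truth_table, tt_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  manifest_path <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  class(manifest) <- c("sample_manifest", "data.frame")
  list(truth = truth, reads = reads,
       manifest = manifest,
       paths = list(genome = genome_path, annotation = gtf_path,
                    truth_table = tt_path, manifest = manifest_path))
}
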