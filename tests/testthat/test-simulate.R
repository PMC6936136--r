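test_that("simulation is fully seeded: same config, identical bytes", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  cfg <- tiny_cfg(n_genes = 2L, reads_per_transcript = 10L, seed = 7L)
  d1 <- simulate_dataset(cfg, dir1)
  d2 <- simulate_dataset(cfg, dir2)
  expect_identical(readLines(d1$paths$genome), readLines(d2$paths$genome))
  expect_identical(readLines(d1$paths$annotation), readLines(d2$paths$annotation))
  for (i in seq_len(nrow(d1$manifest))) {
    expect_identical(read_fastq(d1$manifest$mate1_path[i]),
                     read_fastq(d2$manifest$mate1_path[i]))
  }
  expect_identical(d1$reads$truth_table, d2$reads$truth_table)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(exon_length = c(50L, 80L), read_length = 100L),
               "read_length")
  expect_error(sim_config(intron_length = c(2L, 9L)), "4 bp")
  expect_error(sim_config(error_rate = 1.2), "error_rate")
  # infeasible layout names the required length
  cfg <- tiny_cfg(chrom_length = 5000L, n_genes = 4L)
  expect_error(simulate_genome_and_annotation(cfg), "chromosome length")
})

test_that("generated structure: gene gaps, GT..AG motifs, disjoint isoforms", {
  cfg <- tiny_cfg(seed = 19L)
  truth <- simulate_genome_and_annotation(cfg)
  ann <- truth$annotation

  # every intron starts GT and ends AG on the gene's strand
  for (i in seq_len(nrow(ann))) {
    intr <- spliceflow:::exon_introns(ann$exons[[i]])
    g <- truth$genome[[ann$chrom[i]]]
    for (j in seq_len(nrow(intr))) {
      d <- substring(g, intr[j, 1], intr[j, 1] + 1)
      a <- substring(g, intr[j, 2] - 1, intr[j, 2])
      if (ann$strand[i] == "+") {
        expect_equal(d, "GT"); expect_equal(a, "AG")
      } else {
        expect_equal(d, "CT"); expect_equal(a, "AC")
      }
    }
  }

  # genes non-overlapping with >= 1 kb gaps; isoforms disjoint
  for (cn in unique(ann$chrom)) {
    rows <- which(ann$chrom == cn)
    spans <- cbind(tx_start(ann[rows, ]), tx_end(ann[rows, ]))
    o <- order(spans[, 1])
    spans <- spans[o, , drop = FALSE]
    gid <- ann$gene_id[rows][o]
    for (i in seq_len(nrow(spans) - 1)) {
      gap <- spans[i + 1, 1] - spans[i, 2] - 1
      expect_gte(gap, if (gid[i + 1] == gid[i]) 1 else 1000)
    }
  }
})

test_that("read counts, zero-error substring property and provenance", {
  cfg <- tiny_cfg(n_genes = 2L, reads_per_transcript = 25L, seed = 5L)
  truth <- simulate_genome_and_annotation(cfg)
  reads <- simulate_reads(truth, cfg)
  n_tx <- nrow(truth$annotation)
  expect_equal(nrow(reads$truth_table), 25L * n_tx)
  expect_equal(nrow(reads$samples$sample1$mate1), 25L * n_tx)

  # every mate is an exact (reverse-complemented for mate2) substring of
  # its spliced transcript, at the recorded offset
  tt <- reads$truth_table
  m1 <- reads$samples$sample1$mate1
  m2 <- reads$samples$sample1$mate2
  for (i in seq_len(nrow(tt))) {
    tx_i <- match(tt$transcript_id[i], truth$annotation$transcript_id)
    sseq <- spliceflow:::spliced_sequence(truth, tx_i)
    frag <- substring(sseq, tt$offset[i] + 1, tt$offset[i] + tt$frag_len[i])
    expect_identical(m1$seq[i], substring(frag, 1, cfg$read_length))
    expect_identical(m2$seq[i],
                     revcomp(substring(frag, tt$frag_len[i] - cfg$read_length + 1,
                                           tt$frag_len[i])))
  }
})

test_that("multi-sample mode partitions transcripts round-robin", {
  cfg <- tiny_cfg(n_genes = 2L, reads_per_transcript = 5L, n_samples = 3L)
  truth <- simulate_genome_and_annotation(cfg)
  reads <- simulate_reads(truth, cfg)
  expect_length(reads$samples, 3L)
  by_sample <- split(reads$truth_table$transcript_id, reads$truth_table$sample)
  expect_equal(sort(unique(unlist(by_sample))),
               sort(truth$annotation$transcript_id))
  # no transcript's reads are split across samples
  overlap <- intersect(unique(by_sample$sample1), unique(by_sample$sample2))
  expect_length(overlap, 0L)
})

test_that("transcripts shorter than a fragment are skipped with a warning", {
  cfg <- tiny_cfg(n_genes = 1L, isoforms_per_gene = 1L,
                  exons_per_transcript = c(1L, 1L),
                  exon_length = c(100L, 100L), reads_per_transcript = 5L,
                  fragment_mean = 101, fragment_sd = 0)
  truth <- simulate_genome_and_annotation(cfg)
  # shrink the lone exon below read length behind the config's back
  truth$annotation$exons[[1]] <- cbind(start = truth$annotation$exons[[1]][1, 1],
                                       end = truth$annotation$exons[[1]][1, 1] + 49L)
  expect_warning(reads <- simulate_reads(truth, cfg), "skipped")
  expect_equal(nrow(reads$truth_table), 0L)
})

test_that("substitution errors appear at roughly the configured rate", {
  cfg <- tiny_cfg(n_genes = 1L, isoforms_per_gene = 1L,
                  reads_per_transcript = 200L, error_rate = 0.05, seed = 3L)
  truth <- simulate_genome_and_annotation(cfg)
  reads <- simulate_reads(truth, cfg)
  tt <- reads$truth_table
  m1 <- reads$samples$sample1$mate1
  sseq <- spliceflow:::spliced_sequence(truth, 1L)
  mism <- 0L; total <- 0L
  for (i in seq_len(nrow(tt))) {
    want <- substring(sseq, tt$offset[i] + 1, tt$offset[i] + cfg$read_length)
    a <- utf8ToInt(want); b <- utf8ToInt(m1$seq[i])
    mism <- mism + sum(a != b); total <- total + length(a)
  }
  expect_gt(mism / total, 0.03)
  expect_lt(mism / total, 0.07)
})

test_that("junctions recovered from aligned reads equal the annotated introns", {
  world <- shared_world()
  pairs <- pairs_of_sample(world)
  recs <- spliceflow:::align_pairs(pairs, world$index)
  ann <- world$truth$annotation
  for (cn in unique(ann$chrom)) {
    mapped <- recs[!is.na(recs$chrom) & recs$chrom == cn, ]
    ev <- extract_evidence(mapped[order(mapped$pos, mapped$qname, mapped$flag), ],
                           world$truth$genome)
    got <- paste(ev$junctions$start, ev$junctions$end, sep = "-")
    want <- unique(unlist(lapply(which(ann$chrom == cn), function(i) {
      intr <- spliceflow:::exon_introns(ann$exons[[i]])
      paste(intr[, 1], intr[, 2], sep = "-")
    })))
    expect_setequal(got, want)
  }
})
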