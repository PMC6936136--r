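# A hand-built micro-world for exact assembly assertions: one chromosome,
# two-exon gene with a GT..AG intron at known coordinates.
micro_genome <- function(seed = 21) {
  set.seed(seed)
  g <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
  # exon1 = [101,160], intron = [161,260] (GT..AG), exon2 = [261,320]
  substr(g, 161, 162) <- "GT"
  substr(g, 259, 260) <- "AG"
  c(chr1 = g)
}

micro_reads <- function(n_span = 3L, n_ex1 = 2L, n_ex2 = 2L) {
  recs <- list()
  for (i in seq_len(n_ex1)) recs[[length(recs) + 1L]] <-
    rec(sprintf("e1_%d", i), 0, "chr1", 101, "60M")
  for (i in seq_len(n_span)) recs[[length(recs) + 1L]] <-
    rec(sprintf("sp_%d", i), 0, "chr1", 131, "30M100N30M")
  for (i in seq_len(n_ex2)) recs[[length(recs) + 1L]] <-
    rec(sprintf("e2_%d", i), 0, "chr1", 261, "60M")
  out <- do.call(rbind, recs)
  out[order(out$pos, out$qname, out$flag), ]
}

test_that("filter_annotation_for_bin keeps exactly the bin's chromosome", {
  ann <- bind_transcripts(
    tx("t1", c(1, 50), chrom = "chr1"), tx("t2", c(100, 150), chrom = "chr1"),
    tx("t3", c(1, 50), chrom = "chr2"), tx("t4", c(60, 80), chrom = "chr2"),
    tx("t5", c(90, 120), chrom = "chr2"))
  expect_equal(filter_annotation_for_bin(ann, "chr1:0")$transcript_id,
               c("t1", "t2"))
  expect_equal(nrow(filter_annotation_for_bin(ann, "chrX:3")), 0L)
  one <- ann[1:2, ]
  expect_equal(filter_annotation_for_bin(one, "chr1:5"), one)
})

test_that("extract_evidence counts M coverage and N junctions with motif strand", {
  g <- micro_genome()
  r3 <- do.call(rbind, lapply(1:3, function(i) rec(paste0("r", i), 0, "chr1", 101, "50M")))
  ev <- extract_evidence(r3, g)
  expect_equal(as.integer(ev$coverage)[101:150], rep(3L, 50))
  expect_equal(sum(as.integer(ev$coverage)), 150L)
  expect_equal(nrow(ev$junctions), 0L)

  evj <- extract_evidence(rec("j", 0, "chr1", 151, "10M100N10M"), g)
  expect_equal(evj$junctions,
               data.frame(start = 161L, end = 260L, support = 1L, strand = "+",
                          stringsAsFactors = FALSE))

  # '-'-motif intron (CT..AC) is recognized, unknown motifs are '.'
  g2 <- g
  substr(g2["chr1"], 161, 162) <- "CT"
  substr(g2["chr1"], 259, 260) <- "AC"
  expect_equal(extract_evidence(rec("j", 0, "chr1", 151, "10M100N10M"),
                                g2)$junctions$strand, "-")
  substr(g2["chr1"], 161, 162) <- "AA"
  expect_equal(extract_evidence(rec("j", 0, "chr1", 151, "10M100N10M"),
                                g2)$junctions$strand, ".")

  ev0 <- extract_evidence(rec("x", 0, "chr1", 1, "1M")[0, ], g)
  expect_equal(nrow(ev0$junctions), 0L)
  expect_equal(length(ev0$coverage), 0L)

  expect_error(extract_evidence(rec("far", 0, "chr1", 590, "60M"), g),
               "past the end")
  expect_error(extract_evidence(rbind(rec("a", 0, "chr1", 1, "10M"),
                                      rec("b", 0, "chr2", 1, "10M")),
                                c(chr1 = "ACGT", chr2 = "ACGT")),
               "single chromosome")
})

test_that("assemble_bin recovers a spliced isoform exactly from clean evidence", {
  g <- micro_genome()
  asm <- assemble_bin(micro_reads(), g, bin = "chr1:0")
  expect_equal(nrow(asm), 1L)
  expect_equal(asm$exons[[1]], cbind(start = c(101L, 261L), end = c(160L, 320L)))
  expect_equal(asm$strand, "+")
  expect_equal(asm$origin_bin, "chr1:0")
  expect_equal(tx_nexon(asm), 2L)

  # coverage below min_cov -> nothing assembled
  none <- assemble_bin(micro_reads(), g, assembly_params(min_cov = 99),
                       bin = "chr1:0")
  expect_equal(nrow(none), 0L)

  # junction below support threshold breaks the chain into two singletons
  split <- assemble_bin(micro_reads(n_span = 1),  g,
                        assembly_params(min_junction_support = 2), bin = "chr1:0")
  expect_equal(tx_nexon(split), c(1L, 1L))

  expect_error(assemble_bin(rbind(rec("a", 0, "chr1", 101, "10M"),
                                  rec("b", 0, "chr2", 5, "10M")),
                            c(chr1 = micro_genome()[[1]], chr2 = "ACGTACGT"),
                            bin = "chr1:0"),
               "single chromosome")
})

test_that("assembly is a pure function of its inputs (identical GTF bytes)", {
  g <- micro_genome()
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.gtf"); p2 <- file.path(dir, "b.gtf")
  write_annotation_gtf(assemble_bin(micro_reads(), g, bin = "chr1:0"), p1)
  write_annotation_gtf(assemble_bin(micro_reads(), g, bin = "chr1:0"), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("guided mode emits supported reference transcripts first and suppresses duplicate de novo chains", {
  g <- micro_genome()
  ref <- bind_transcripts(
    tx("ref.t1", c(95, 160, 261, 330), strand = "+", source = "reference"),
    tx("ref.t2", c(400, 430, 481, 520), strand = "+", source = "reference"))
  asm <- assemble_bin(micro_reads(), g, partial_annotation = ref, bin = "chr1:0")
  # ref.t1's intron [161,260] is supported -> emitted verbatim;
  # ref.t2's intron has no read support -> not emitted;
  # the de novo path duplicating ref.t1's chain is suppressed
  expect_equal(asm$transcript_id, "ref.t1")
  expect_equal(asm$source, "reference")
  expect_equal(asm$exons[[1]], cbind(start = c(95L, 261L), end = c(160L, 330L)))

  # guided output is a superset: with an unrelated reference, de novo
  # assembly still appears
  asm2 <- assemble_bin(micro_reads(), g,
                       partial_annotation = ref[2, , drop = FALSE],
                       bin = "chr1:0")
  expect_equal(spliceflow:::chain_key(asm2), "chr1:161-260")
})

test_that("single-exon transcripts only for isolated junction-free fragments", {
  g <- micro_genome()
  recs <- rbind(micro_reads(),
                rec("lone1", 0, "chr1", 401, "50M"),
                rec("lone2", 0, "chr1", 401, "50M"))
  recs <- recs[order(recs$pos, recs$qname, recs$flag), ]
  asm <- assemble_bin(recs, g, bin = "chr1:0")
  expect_equal(tx_nexon(asm), c(2L, 1L))
  expect_equal(asm$exons[[2]], cbind(start = 401L, end = 450L))
  expect_equal(asm$strand[2], ".")
  # distinct connected components get distinct genes
  expect_equal(length(unique(asm$gene_id)), 2L)
})

test_that("path enumeration cap truncates with a warning, never reorders", {
  # ladder of alternative junctions: 2^4 = 16 paths through 5 exon islands
  set.seed(5)
  g <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                      collapse = ""))
  recs <- list()
  # two parallel fragments per rung, each feeding the next rung
  # exons at [s, s+19]; rungs at 101, 201, 301, ...
  for (rung in 0:4) {
    s <- 101L + rung * 100L
    recs[[length(recs) + 1L]] <- rec(sprintf("cov%d", rung), 0, "chr1", s, "20M")
    if (rung < 4) {
      recs[[length(recs) + 1L]] <-
        rec(sprintf("sh%d", rung), 0, "chr1", s + 10L, "10M70N10M")
      recs[[length(recs) + 1L]] <-
        rec(sprintf("lo%d", rung), 0, "chr1", s + 15L, "5M75N10M")
    }
  }
  recs <- do.call(rbind, recs)
  recs <- recs[order(recs$pos, recs$qname, recs$flag), ]
  full <- assemble_bin(recs, g, assembly_params(max_paths_per_component = 64),
                       bin = "chr1:0")
  expect_warning(
    capped <- assemble_bin(recs, g, assembly_params(max_paths_per_component = 3),
                           bin = "chr1:0"),
    "capped")
  expect_equal(nrow(capped), 3L)
  # truncation keeps the deterministic leading paths
  expect_equal(spliceflow:::structure_key(capped),
               spliceflow:::structure_key(full)[1:3])
})

test_that("collect_transcripts orders by bin regardless of completion order", {
  a <- tx("a.t1", c(1, 50), origin_bin = "chr1:0")
  b <- tx("b.t1", c(900, 980), origin_bin = "chr1:1")
  c2 <- tx("c.t1", c(5, 60), chrom = "chr2", origin_bin = "chr2:0")
  got <- collect_transcripts(list("chr1:1" = b, "chr2:0" = c2, "chr1:0" = a))
  expect_equal(got$transcript_id, c("a.t1", "b.t1", "c.t1"))
  expect_equal(nrow(collect_transcripts(list())), 0L)
  expect_equal(nrow(collect_transcripts(list("chr1:0" = a[0, ]))), 0L)
  # duplicates from overlapping bins are both retained here
  dup <- tx("a.t1", c(1, 50), origin_bin = "chr1:1")
  both <- collect_transcripts(list("chr1:1" = dup, "chr1:0" = a))
  expect_equal(nrow(both), 2L)
})
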