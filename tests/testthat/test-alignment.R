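test_that("build_index records every genomic k-mer with sorted positions", {
  idx <- build_index(c(chrA = "ACGTACGT"), k = 4)
  hits <- index_lookup(idx, "ACGT")
  expect_equal(hits$offset, c(0L, 4L))
  expect_equal(hits$strand, c("+", "+"))

  idx8 <- build_index(c(chrA = "ACGTACGT"), k = 8)
  expect_equal(nrow(index_lookup(idx8, "ACGTACGT")), 1L)

  expect_error(build_index(c(a = "ACGTACGT", a = "ACGTACGT"), k = 4),
               "duplicate chromosome")
  expect_error(build_index(c(a = "ACGT"), k = 8), "exceeds")
})

test_that("toy_align places exonic, junction-spanning and unalignable mates", {
  world <- shared_world()
  truth <- world$truth
  idx <- world$index
  ann <- truth$annotation

  # zero-error read copied verbatim from an exon interior -> <len>M there
  ex <- ann$exons[[1]]
  read1 <- substring(truth$genome[[ann$chrom[1]]], ex[1, 1], ex[1, 1] + 99)
  pair <- data.frame(read_id = "p1", seq1 = read1, qual1 = strrep("I", 100),
                     seq2 = revcomp(read1), qual2 = strrep("I", 100))
  recs <- toy_align(pair, idx)
  expect_equal(nrow(recs), 2L)
  expect_equal(recs$pos, rep(unname(ex[1, 1]), 2))
  expect_equal(recs$cigar, c("100M", "100M"))
  expect_equal(bitwAnd(recs$flag, 16L) > 0, c(FALSE, TRUE))
  expect_equal(bitwAnd(recs$flag, c(64L, 128L)) > 0, c(TRUE, TRUE))

  # read spanning one junction with 40 bases on the left exon
  g <- truth$genome[[ann$chrom[1]]]
  left <- substring(g, ex[1, 2] - 39, ex[1, 2])
  right <- substring(g, ex[2, 1], ex[2, 1] + 59)
  intron <- ex[2, 1] - ex[1, 2] - 1L
  pairj <- data.frame(read_id = "pj", seq1 = paste0(left, right),
                      qual1 = strrep("I", 100),
                      seq2 = revcomp(paste0(left, right)), qual2 = strrep("I", 100))
  recj <- toy_align(pairj, idx)
  expect_equal(recj$cigar[1], sprintf("40M%dN60M", intron))
  expect_equal(recj$pos[1], unname(ex[1, 2]) - 39L)

  # all-N read -> unmapped record, not an error
  pn <- data.frame(read_id = "pn", seq1 = strrep("N", 100), qual1 = strrep("I", 100),
                   seq2 = read1, qual2 = strrep("I", 100))
  recn <- toy_align(pn, idx)
  expect_true(is.na(recn$chrom[1]))
  expect_equal(bitwAnd(recn$flag[1], 4L), 4L)
  expect_equal(recn$cigar[1], "*")
  expect_false(is.na(recn$chrom[2]))
})

test_that("align_chunk yields 2 records per pair, deterministically serialized", {
  world <- shared_world()
  dir <- withr::local_tempdir()
  pairs <- pairs_of_sample(world)[1:4, ]
  chunk <- structure(list(sample_name = "sA", chunk_index = 0L, pairs = pairs),
                     class = "read_chunk")
  a <- align_chunk(chunk, builtin_aligner(), world$index, temp_dir = dir)
  expect_equal(nrow(a$records), 8L)
  expect_equal(a$records$qname, rep(pairs$read_id, each = 2L))

  first <- readLines(a$path)
  a2 <- align_chunk(chunk, builtin_aligner(), world$index, temp_dir = dir)
  expect_identical(readLines(a2$path), first)

  empty <- structure(list(sample_name = "sA", chunk_index = 1L,
                          pairs = pairs[0, ]), class = "read_chunk")
  e <- align_chunk(empty, builtin_aligner(), world$index)
  expect_equal(nrow(e$records), 0L)

  failing <- aligner_adapter("boom", function(p, i) stop("nope"), TRUE)
  expect_error(align_chunk(chunk, failing, world$index),
               "sample sA chunk 0")
})

test_that("concatenate_sample conserves records, normalizes headers, cleans up", {
  world <- shared_world()
  dir <- withr::local_tempdir()
  pairs <- pairs_of_sample(world)
  sizes <- c(4L, 4L, 2L)
  offs <- c(0L, cumsum(sizes))
  paths <- character(3)
  for (i in 1:3) {
    chunk <- structure(list(sample_name = "sB", chunk_index = i - 1L,
                            pairs = pairs[(offs[i] + 1):offs[i + 1], ]),
                       class = "read_chunk")
    paths[i] <- align_chunk(chunk, builtin_aligner(), world$index, dir)$path
  }
  out <- file.path(dir, "sB.sam")
  concatenate_sample("sB", paths, out)
  sam <- read_sam(out)
  expect_equal(nrow(sam$records), 20L)
  expect_false(any(startsWith(sam$header, "@PG")))
  expect_false(any(file.exists(paths)))  # temporary chunks deleted

  # single chunk: output record-identical to that chunk
  chunk <- structure(list(sample_name = "sC", chunk_index = 0L,
                          pairs = pairs[1:3, ]), class = "read_chunk")
  a <- align_chunk(chunk, builtin_aligner(), world$index, dir)
  out1 <- file.path(dir, "sC.sam")
  concatenate_sample("sC", a$path, out1, delete_chunks = FALSE)
  expect_equal(read_sam(out1)$records, read_sam(a$path)$records)

  # missing middle chunk reported by index
  expect_error(concatenate_sample("sB", c(out1, file.path(dir, "gone.sam"), out1),
                                  file.path(dir, "x.sam")),
               "index 1")
})

test_that("verify_equivalence is reflexive and pinpoints a perturbed record", {
  world <- shared_world()
  dir <- withr::local_tempdir()
  pairs <- pairs_of_sample(world)[1:6, ]
  recs <- toy_align(pairs[1, ], world$index)
  for (i in 2:6) recs <- rbind(recs, toy_align(pairs[i, ], world$index))
  f1 <- file.path(dir, "a.sam")
  write_sam(recs, world$index, f1, program = "run A")
  expect_true(verify_equivalence(f1, f1)$equivalent)

  # @PG differences alone do not break equivalence
  f2 <- file.path(dir, "b.sam")
  write_sam(recs, world$index, f2, program = "a very different command line")
  expect_true(verify_equivalence(f1, f2)$equivalent)

  # +1 position perturbation is caught and reported
  recs2 <- recs
  i <- which(!is.na(recs2$pos))[1]
  recs2$pos[i] <- recs2$pos[i] + 1L
  f3 <- file.path(dir, "c.sam")
  write_sam(recs2, world$index, f3)
  res <- verify_equivalence(f1, f3)
  expect_false(res$equivalent)
  expect_match(res$first_divergence$b, recs2$qname[i])
  expect_error(verify_equivalence(f1, file.path(dir, "missing.sam")), "not found")
})

test_that("chunked-then-concatenated equals the single-pass sequential run", {
  world <- shared_world()
  dir <- withr::local_tempdir()
  pairs <- pairs_of_sample(world)
  n <- nrow(pairs)

  seqf <- file.path(dir, "seq.sam")
  write_sam(spliceflow:::align_pairs(pairs, world$index), world$index, seqf,
            program = "sequential single pass")

  for (cs in c(7L, 64L)) {
    starts <- seq(1L, n, by = cs)
    paths <- vapply(seq_along(starts), function(i) {
      rows <- starts[i]:min(starts[i] + cs - 1L, n)
      ch <- structure(list(sample_name = "sD", chunk_index = i - 1L,
                           pairs = pairs[rows, ]), class = "read_chunk")
      align_chunk(ch, builtin_aligner(), world$index, dir)$path
    }, character(1))
    out <- file.path(dir, sprintf("chunked_%d.sam", cs))
    concatenate_sample("sD", paths, out)
    expect_true(verify_equivalence(out, seqf)$equivalent)
  }
})

test_that("record conservation: mapped + unmapped = 2 x pairs", {
  world <- shared_world()
  pairs <- pairs_of_sample(world)
  recs <- spliceflow:::align_pairs(pairs, world$index)
  expect_equal(nrow(recs), 2L * nrow(pairs))
  expect_equal(sum(is.na(recs$chrom)) + sum(!is.na(recs$chrom)), 2L * nrow(pairs))
})

test_that("zero-error mates with long junction overhangs match truth exactly", {
  world <- shared_world()
  tt <- world$reads$truth_table
  ta <- truth_alignments(world$truth, tt, world$cfg$read_length)
  pairs <- pairs_of_sample(world)
  recs <- spliceflow:::align_pairs(pairs, world$index)
  k <- world$index$k
  for (m in 1:2) {
    tam <- ta[ta$mate == m, ]
    # reads whose every aligned segment is >= k fit the two-seed model
    seg_ok <- vapply(tam$cigar, function(cg) {
      ops <- spliceflow:::parse_cigar(cg)
      all(ops$len[ops$op == "M"] >= k)
    }, logical(1))
    got <- recs[bitwAnd(recs$flag, if (m == 1) 64L else 128L) > 0, ]
    got <- got[match(tam$read_id, got$qname), ]
    sel <- which(seg_ok)
    expect_gt(length(sel), 100L)
    expect_equal(got$pos[sel], tam$pos[sel])
    expect_equal(got$cigar[sel], tam$cigar[sel])
    expect_equal(bitwAnd(got$flag[sel], 16L) > 0, tam$rev[sel])
  }
})

test_that("external aligner adapters are inert hooks", {
  expect_error(star_adapter("/idx")$fun(NULL, NULL), "STAR")
  expect_error(hisat2_adapter("/idx")$fun(NULL, NULL), "hisat2")
  expect_false(hisat2_adapter("/idx")$deterministic)
})
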