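# Simulators and the evaluation metrics.

test_that("genome simulation is deterministic and honors GC content", {
  g1 <- simulate_genome(5000, seed = 7)
  g2 <- simulate_genome(5000, seed = 7)
  expect_identical(g1, g2)
  g3 <- simulate_genome(5000, seed = 8)
  expect_false(identical(g1, g3))
  gat <- simulate_genome(3000, gc = 0, seed = 9)
  expect_false(grepl("[GC]", gat[[1]]))
  g <- simulate_genome(1e6, gc = 0.5, seed = 10)
  gc <- sum(strsplit(g[[1]], "")[[1]] %in% c("G", "C")) / 1e6
  expect_lt(abs(gc - 0.5), 0.01)
  expect_equal(nchar(simulate_genome(10000, seed = 1, n_contigs = 4)),
               setNames(rep(2500L, 4), paste0("chr", 1:4)))
})

test_that("error-free paired reads are exact genome substrings in FR layout", {
  g <- simulate_genome(50000, seed = 11)
  sim <- simulate_pe_reads(g, 30, 100, 0, 500, 50, seed = 12)
  gs <- g[[1]]
  for (i in 1:30) {
    t1 <- sim$truth[i, ]; t2 <- sim$truth[30 + i, ]
    expect_equal(sim$reads1$seq[i], substr(gs, t1$pos + 1, t1$pos + 100))
    expect_equal(revcomp(sim$reads2$seq[i]),
                 substr(gs, t2$pos + 1, t2$pos + 100))
    expect_equal(t1$strand, "+"); expect_equal(t2$strand, "-")
    expect_gte(t2$pos, t1$pos)
  }
})

test_that("injected substitution rate matches the requested rate", {
  g <- simulate_genome(200000, seed = 13)
  sim <- simulate_pe_reads(g, 500, 100, 0.02, 500, 50, seed = 14)
  gs <- g[[1]]
  mism <- 0L
  for (i in 1:500) {
    t1 <- sim$truth[i, ]
    truth_seq <- substr(gs, t1$pos + 1, t1$pos + 100)
    mism <- mism + sum(strsplit(sim$reads1$seq[i], "")[[1]] !=
                         strsplit(truth_seq, "")[[1]])
  }
  rate <- mism / 50000  # 500 reads x 100 bases
  expect_gte(rate, 0.018); expect_lte(rate, 0.022)
})

test_that("insert sizes follow the requested normal distribution", {
  g <- simulate_genome(300000, seed = 15)
  sim <- simulate_pe_reads(g, 5000, 100, 0, 500, 50, seed = 16)
  ins <- (sim$truth$pos[5001:10000] + 100) - sim$truth$pos[1:5000]
  expect_lt(abs(mean(ins) - 500), 3)   # se of the mean ~ 0.7
  expect_lt(abs(sd(ins) - 50), 3)
  expect_error(simulate_pe_reads(g, 10, 100, 0, 150, 10),
               "twice the read length")
  expect_error(simulate_pe_reads(c(x = rand_seq(300)), 10, 100, 0, 500, 50),
               "too short")
})

test_that("color mate-pairs decode to the source bases with FF truth", {
  g <- simulate_genome(40000, seed = 17)
  sim <- simulate_color_pairs(g, 20, 50, 0, 200, 20, seed = 18)
  gs <- g[[1]]
  expect_true(all(nchar(sim$reads1$colors) == 50))  # primer + L colors
  expect_true(all(sim$truth$strand == "+"))
  for (i in 1:20) {
    t1 <- sim$truth[i, ]; t2 <- sim$truth[20 + i, ]
    expect_equal(decode_colors(sim$reads1$primer[i], sim$reads1$colors[i]),
                 substr(gs, t1$pos + 1, t1$pos + 50))
    expect_equal(decode_colors(sim$reads2$primer[i], sim$reads2$colors[i]),
                 substr(gs, t2$pos + 1, t2$pos + 50))
  }
})

test_that("evaluation reproduces hand-counted metrics on a 4-read fixture", {
  truth <- data.frame(read_id = c("a", "b", "c", "d"),
                      contig = "chr1", pos = c(100, 200, 300, 400),
                      strand = "+", stringsAsFactors = FALSE)
  # a: correct (distance 5); b: correct at boundary 10; c: wrong (distance 11
  # on a second hit, first hit wrong contig position far away); d: unaligned
  aln <- data.frame(
    qname = c("a", "b", "c", "c"),
    end = 0L, rank = c(1L, 1L, 1L, 2L),
    contig = "chr1",
    pos = c(105, 210, 5000, 311),
    strand = "+",
    mapq = c(60L, 40L, 20L, 20L),
    stringsAsFactors = FALSE)
  ev <- evaluate_alignments(aln, truth)
  expect_equal(ev$sensitivity, 75)     # 3 of 4 aligned
  expect_equal(ev$recall_all, 50)      # a and b correct; c misses by 11
  expect_equal(ev$recall_first, 50)
  # reported 105 vs truth 100 is correct; 111 vs 100 is not
  one <- function(p) evaluate_alignments(
    data.frame(qname = "a", end = 0L, rank = 1L, contig = "chr1", pos = p,
               strand = "+", mapq = 60L), truth[1, ])$recall_all
  expect_equal(one(105), 100)
  expect_equal(one(111), 0)
  # opposite strand hits are incorrect
  wrong <- data.frame(qname = "a", end = 0L, rank = 1L, contig = "chr1",
                      pos = 100, strand = "-", mapq = 60L)
  expect_equal(evaluate_alignments(wrong, truth[1, ])$recall_all, 0)
})

test_that("evaluation metrics respect their ordering invariant on real runs", {
  ref <- make_test_ref(100000, seed = 19)
  sim <- simulate_pe_reads(ref$genome, 200, 100, 0.06, 500, 50, seed = 20)
  a <- align_reads(ref$index, rbind(sim$reads1, sim$reads2))
  ev <- evaluate_alignments(a, sim$truth)
  expect_lte(ev$recall_first, ev$recall_all)
  expect_lte(ev$recall_all, ev$sensitivity)
  expect_true(all(diff(ev$roc$tpr) <= 1e-9))  # TPR non-increasing in q
  # error-free runs: every aligned read is correct
  sim0 <- simulate_pe_reads(ref$genome, 100, 100, 0, 500, 50, seed = 21)
  a0 <- align_reads(ref$index, sim0$reads1)
  ev0 <- evaluate_alignments(a0, sim0$truth)
  expect_equal(ev0$recall_all, ev0$sensitivity)
})

test_that("MAPQ filtering and truth mismatches are handled", {
  truth <- data.frame(read_id = "a", contig = "chr1", pos = 100, strand = "+")
  aln <- data.frame(qname = "a", end = 0L, rank = 1L, contig = "chr1",
                    pos = 100, strand = "+", mapq = 5L)
  expect_equal(evaluate_alignments(aln, truth, min_mapq = 10)$sensitivity, 0)
  bad <- data.frame(qname = "zz", end = 0L, rank = 1L, contig = "chr1",
                    pos = 1, strand = "+", mapq = 60L)
  expect_error(evaluate_alignments(bad, truth), "absent from the truth")
})

test_that("SAM files round-trip through the evaluator", {
  ref <- make_test_ref(60000, seed = 22)
  sim <- simulate_pe_reads(ref$genome, 50, 100, 0.02, 400, 40, seed = 23)
  a <- align_reads(ref$index, sim$reads1)
  f <- tempfile(fileext = ".sam")
  write_sam(a, sim$reads1, ref$index, f)
  truth1 <- sim$truth[grepl("/1$", sim$truth$read_id), ]
  # SAM qnames keep the /1 suffix for single-end input
  ev_direct <- evaluate_alignments(a, sim$truth)
  ev_sam <- evaluate_alignments(f, sim$truth)
  expect_equal(ev_sam$recall_all, ev_direct$recall_all)
  expect_equal(ev_sam$sensitivity, ev_direct$sensitivity)
  unlink(f)
})
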