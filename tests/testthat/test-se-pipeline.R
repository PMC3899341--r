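# Single-end pipeline: seed scoring/ranking, extension, semi-global rescue,
# k-mer re-seeding, reporting.

test_that("seed scoring and ranking orders by independently recomputed scores", {
  ref <- make_test_ref(20000, seed = 41)
  set.seed(42)
  read <- as.character(cpp_mutate_seqs(substr(ref$seq, 5001, 5100), 0.04, "ACGT"))
  seeds <- rbind(find_mem_seeds(ref$index, read, 12),
                 find_kmer_seeds(ref$index, read, 13))
  ranked <- score_and_rank_seeds(ref$index, read, seeds)
  expect_true(nrow(ranked) >= 1)
  # deduplication: one row per (region, strand)
  expect_false(any(duplicated(ranked[c("strand", "region_start")])))
  # order equals an independent re-scoring
  rescored <- vapply(seq_len(nrow(ranked)), function(i) {
    s <- ranked[i, ]
    region <- substr(ref$seq, s$region_start + 1, s$region_end)
    ori <- if (s$strand == 1) revcomp(read) else read
    smith_waterman(ori, region)$score
  }, 0)
  expect_equal(ranked$score_q, rescored)
  expect_true(all(diff(ranked$score_q) <= 0))
})

test_that("an error-free read gets the perfect top seed score", {
  ref <- make_test_ref(20000, seed = 43)
  read <- substr(ref$seq, 3001, 3100)
  seeds <- find_mem_seeds(ref$index, read, 15)
  ranked <- score_and_rank_seeds(ref$index, read, seeds)
  expect_equal(ranked$score_q[1], 100)  # match score * read length
})

test_that("error-free reads align uniquely at the simulated position", {
  ref <- make_test_ref(50000, seed = 44)
  sim <- simulate_pe_reads(ref$genome, 50, 100, 0, 400, 30, seed = 45)
  a <- align_reads(ref$index, sim$reads1)
  expect_equal(length(unique(a$read)), 50L)
  prim <- a[a$rank == 1, ]
  truth1 <- sim$truth[seq_len(50), ]
  expect_true(all(prim$pos == truth1$pos & prim$strand == truth1$strand))
  expect_true(all(prim$mapq == 60))  # unique placements, no runner-up
})

test_that("reads of random unrelated sequence stay unaligned", {
  ref <- make_test_ref(30000, seed = 46)
  set.seed(47)
  junk <- vapply(1:20, function(i) rand_seq(100), "")
  a <- align_reads(ref$index, junk)
  expect_equal(nrow(a), 0L)
})

test_that("a long contiguous mismatch block is rescued semi-globally", {
  ref <- make_test_ref(30000, seed = 48)
  p <- 12000
  true_read <- substr(ref$seq, p + 1, p + 100)
  read <- paste0(substr(true_read, 1, 75),
                 chartr("ACGT", "TGCA", substr(true_read, 76, 100)))
  a <- align_single(ref$index, read)
  expect_gte(nrow(a), 1L)
  expect_equal(a$mode[1], "semiglobal")
  expect_equal(a$pos[1], p)
  expect_equal(a$aligned_frac[1], 1)
  # identity 75% sits between the global (65) and local (90) thresholds
  expect_gte(a$identity[1], 65)
  expect_lt(a$identity[1], 90)
})

test_that("semi-global rescue strictly increases recall on deletion reads", {
  ref <- make_test_ref(60000, seed = 49)
  set.seed(50)
  # 12-bp deletion 24 bases from the read end: the local optimum clips the
  # 24-base suffix (coverage 0.76 < 0.8) while the gapped semi-global
  # alignment spans the deletion
  starts <- sample(0:(60000 - 120), 100)
  reads <- vapply(starts, function(p)
    paste0(substr(ref$seq, p + 1, p + 76), substr(ref$seq, p + 89, p + 112)),
    "")
  truth <- data.frame(read_id = paste0("read", seq_along(reads)),
                      contig = "chr1", pos = starts, strand = "+")
  on_df <- align_reads(ref$index, reads)
  off_df <- align_reads(ref$index, reads,
                        align_config(semiglobal_rescue = FALSE))
  rec <- function(df) evaluate_alignments(df, truth)$recall_all
  expect_gt(rec(on_df), rec(off_df))
  expect_true(all(on_df$mode[on_df$rank == 1] == "semiglobal"))
})

test_that("k-mer re-seeding recovers reads whose MEMs are destroyed", {
  ref <- make_test_ref(50000, seed = 51)
  p <- 20000
  true_read <- substr(ref$seq, p + 1, p + 100)
  # errors spaced 14-15 apart kill every MEM of length >= 15 but leave the
  # second 13-mer window (offsets 13-25) error-free
  r <- strsplit(true_read, "")[[1]]
  for (i in c(13, 28, 42, 56, 70, 84, 98))
    r[i] <- setdiff(c("A", "C", "G", "T"), r[i])[1]
  read <- paste(r, collapse = "")
  mems <- find_mem_seeds(ref$index, read, 15)
  expect_equal(nrow(mems), 0L)
  a <- align_single(ref$index, read, align_config(min_mem_len = 15))
  expect_gte(nrow(a), 1L)
  expect_equal(a$pos[1], p)
  anok <- align_single(ref$index, read,
                       align_config(min_mem_len = 15, kmer_reseed = FALSE))
  expect_equal(nrow(anok), 0L)
})

test_that("every reported alignment passes qualification for its mode", {
  ref <- make_test_ref(50000, seed = 52)
  sim <- simulate_pe_reads(ref$genome, 150, 100, 0.06, 400, 40, seed = 53)
  a <- align_reads(ref$index, sim$reads1)
  cfg <- align_config()
  loc <- a$mode == "local"
  expect_true(all(a$identity[loc] >= cfg$min_id_local - 1e-9))
  expect_true(all(a$identity[!loc] >= cfg$min_id_global - 1e-9))
  expect_true(all(a$aligned_frac >= cfg$min_align_frac - 1e-9))
  expect_true(all(a$rank <= cfg$max_reported))
})

test_that("sensitivity is monotone non-increasing in the error rate", {
  ref <- make_test_ref(100000, seed = 54)
  sens <- vapply(c(0, 0.02, 0.06), function(e) {
    sim <- simulate_pe_reads(ref$genome, 150, 100, e, 400, 40, seed = 55)
    a <- align_reads(ref$index, sim$reads1)
    length(unique(a$read)) / 150
  }, 0)
  expect_true(all(diff(sens) <= 0))
})

test_that("alignment ordering is score-desc, then edit, then coordinate", {
  ref <- make_test_ref(30000, seed = 56)
  # duplicate a segment so a read has two placements
  g2 <- c(chr1 = paste0(ref$seq, substr(ref$seq, 1001, 1200)))
  idx <- build_index(g2)
  read <- substr(ref$seq, 1051, 1150)
  a <- align_single(idx, read)
  expect_gte(nrow(a), 2L)
  expect_true(all(diff(a$score) <= 0))
  expect_equal(a$mapq[1], 0)  # two co-optimal placements -> ambiguous
  ties <- a$score == a$score[1]
  expect_equal(a$pos[which(ties)[1]], min(a$pos[ties]))
})
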