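# Paired-end pipeline: insert estimation, weighted seed pairing, alignment
# pair ranking, and read mate rescuing.

test_that("pair weight follows its normalized form", {
  expect_equal(pair_weight(100, 100, 1, 100, 100), 1)
  expect_equal(pair_weight(60, 40, 1, 100, 100), 0.5)
  # homogeneity: scaling scores and match score together leaves w unchanged
  expect_equal(pair_weight(60, 40, 1, 100, 100),
               pair_weight(180, 120, 3, 100, 100))
  # monotone in each q
  expect_gt(pair_weight(61, 40, 1, 100, 100), pair_weight(60, 40, 1, 100, 100))
})

test_that("insert estimation recovers the simulated distribution", {
  ref <- make_test_ref(200000, seed = 61)
  sim <- simulate_pe_reads(ref$genome, 2000, 100, 0.02, 500, 50, seed = 62)
  est <- estimate_insert_size(ref$index, sim$reads1, sim$reads2)
  expect_gte(est[["mean"]], 490); expect_lte(est[["mean"]], 510)
  expect_gte(est[["sd"]], 40); expect_lte(est[["sd"]], 60)
})

test_that("identical inserts estimate to (insert, 0) and junk reads error", {
  ref <- make_test_ref(100000, seed = 63)
  set.seed(64)
  starts <- sample(0:(100000 - 301), 150)
  r1 <- substring(ref$seq, starts + 1, starts + 100)
  r2 <- revcomp(substring(ref$seq, starts + 201, starts + 300))
  est <- estimate_insert_size(ref$index, r1, r2)
  expect_equal(est[["mean"]], 300)
  expect_equal(est[["sd"]], 0)
  junk1 <- vapply(1:150, function(i) rand_seq(100), "")
  junk2 <- vapply(1:150, function(i) rand_seq(100), "")
  expect_error(estimate_insert_size(ref$index, junk1, junk2),
               "insert_mean/insert_sd")
})

test_that("seed pairing equals the exhaustive enumeration oracle", {
  ref <- make_test_ref(150000, seed = 65)
  set.seed(66)
  cfg <- align_config()
  for (rep in 1:20) {
    p <- sample(1000:140000, 1)
    r1 <- as.character(cpp_mutate_seqs(substr(ref$seq, p + 1, p + 100), 0.02, "ACGT"))
    r2c <- substr(ref$seq, p + 401, p + 500)
    r2 <- as.character(cpp_mutate_seqs(revcomp(r2c), 0.02, "ACGT"))
    rk1 <- score_and_rank_seeds(ref$index, r1,
                                find_mem_seeds(ref$index, r1, 13))
    rk2 <- score_and_rank_seeds(ref$index, r2,
                                find_mem_seeds(ref$index, r2, 13))
    sp <- pair_seeds(rk1, rk2, c(500, 50), cfg)
    # heap order: non-increasing weight
    if (nrow(sp) > 1) expect_true(all(diff(sp$w) <= 1e-12))
    # brute-force oracle over all high-quality seed combinations
    thr <- 30; lo <- 500 - 4 * 50; hi <- 500 + 4 * 50
    h1 <- rk1[rk1$score_q >= thr, ]; h2 <- rk2[rk2$score_q >= thr, ]
    n_oracle <- 0
    if (nrow(h1) && nrow(h2))
      for (i in seq_len(nrow(h1))) for (j in seq_len(nrow(h2))) {
        s1 <- h1[i, ]; s2 <- h2[j, ]
        if (s1$strand == s2$strand) next
        p1 <- s1$genome_pos - s1$read_offset
        p2 <- s2$genome_pos - s2$read_offset
        ins <- if (s1$strand == 0) p2 + 100 - p1 else p1 + 100 - p2
        ordok <- if (s1$strand == 0) p2 >= p1 else p1 >= p2
        if (ordok && ins >= lo && ins <= hi) n_oracle <- n_oracle + 1
      }
    expect_equal(nrow(sp), n_oracle, info = rep)
  }
})

test_that("seeds implying an out-of-window insert are excluded", {
  ref <- make_test_ref(50000, seed = 67)
  p <- 10000
  r1 <- substr(ref$seq, p + 1, p + 100)
  r2 <- revcomp(substr(ref$seq, p + 801, p + 900))  # implied insert 900
  rk1 <- score_and_rank_seeds(ref$index, r1, find_mem_seeds(ref$index, r1, 15))
  rk2 <- score_and_rank_seeds(ref$index, r2, find_mem_seeds(ref$index, r2, 15))
  expect_equal(nrow(pair_seeds(rk1, rk2, c(500, 50))), 0L)
  sp <- pair_seeds(rk1, rk2, c(900, 50))
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$w[1], 1)
})

test_that("error-free pairs produce one proper pair at the true positions", {
  ref <- make_test_ref(200000, seed = 68)
  sim <- simulate_pe_reads(ref$genome, 40, 100, 0, 500, 50, seed = 69)
  pa <- align_pairs(ref$index, sim$reads1, sim$reads2,
                    insert_mean = 500, insert_sd = 50)
  prim <- pa[pa$rank == 1, ]
  expect_equal(nrow(prim), 80L)
  expect_true(all(prim$proper))
  ev <- evaluate_alignments(pa, sim$truth)
  expect_equal(ev$recall_all, 100)
  # insert window and orientation hold for every reported pair
  e1 <- prim[prim$end == 1, ]; e2 <- prim[prim$end == 2, ]
  expect_true(all(e1$strand != e2$strand))
  lft <- ifelse(e1$strand == "+", e1$pos, e2$pos)
  rgt <- ifelse(e1$strand == "+", e2$pos, e1$pos) + 100
  expect_true(all(rgt - lft >= 300 & rgt - lft <= 700))
})

test_that("a noisy end is carried by its clean mate beyond SE reach", {
  ref <- make_test_ref(300000, seed = 70)
  n <- 300
  sim <- with_seed(71, {
    s1 <- simulate_pe_reads(ref$genome, n, 100, 0, 500, 50)
    # corrupt end 2 heavily (10% error) after truth is recorded
    s1$reads2$seq <- as.character(cpp_mutate_seqs(s1$reads2$seq, 0.10, "ACGT"))
    s1
  })
  se2 <- align_reads(ref$index, sim$reads2)
  se2_frac <- length(unique(se2$read)) / n
  pa <- align_pairs(ref$index, sim$reads1, sim$reads2,
                    insert_mean = 500, insert_sd = 50)
  paired_frac <- sum(pa$end == 2 & pa$rank == 1 & pa$proper) / n
  expect_gt(paired_frac, se2_frac)
})

test_that("disabling mate rescue strictly reduces the paired fraction", {
  ref <- make_test_ref(200000, seed = 72)
  sim <- simulate_pe_reads(ref$genome, 2000, 100, 0.06, 500, 50, seed = 73)
  # large-genome seeding regime: some ends have no seed at all and can only
  # be placed through their mate
  cfg_on <- align_config(min_mem_len = 15)
  cfg_off <- align_config(min_mem_len = 15, mate_rescue = FALSE)
  pa_on <- align_pairs(ref$index, sim$reads1, sim$reads2, cfg_on,
                       insert_mean = 500, insert_sd = 50)
  pa_off <- align_pairs(ref$index, sim$reads1, sim$reads2, cfg_off,
                        insert_mean = 500, insert_sd = 50)
  paired <- function(pa) sum(pa$proper & pa$rank == 1 & pa$end == 1)
  expect_gt(paired(pa_on), paired(pa_off))
})

test_that("PE sensitivity is at least SE sensitivity on the same reads", {
  ref <- make_test_ref(200000, seed = 74)
  sim <- simulate_pe_reads(ref$genome, 300, 100, 0.06, 500, 50, seed = 75)
  se <- align_reads(ref$index, rbind(sim$reads1, sim$reads2))
  se_sens <- length(unique(se$qname)) / 600
  pa <- align_pairs(ref$index, sim$reads1, sim$reads2,
                    insert_mean = 500, insert_sd = 50)
  pe_sens <- length(unique(paste(pa$read, pa$end))) / 600
  expect_gte(pe_sens, se_sens)
})

test_that("rescue_mate aligns the mate inside the implied window", {
  ref <- make_test_ref(100000, seed = 76)
  p <- 10000
  anchor_read <- substr(ref$seq, p + 1, p + 100)
  a <- align_single(ref$index, anchor_read)
  mate_true <- revcomp(substr(ref$seq, p + 401, p + 500))
  mate <- as.character(with_seed(77, cpp_mutate_seqs(mate_true, 0.05, "ACGT")))
  res <- rescue_mate(ref$index, a[1, ], mate, c(500, 50))
  expect_false(is.null(res))
  expect_equal(res$strand, "-")
  expect_lte(abs(res$pos - (p + 400)), 10)
  # anchor below the MAPQ gate is not used
  weak <- a[1, ]; weak$mapq <- 10L
  expect_null(rescue_mate(ref$index, weak, mate, c(500, 50)))
  # a random mate fails the identity threshold
  expect_null(rescue_mate(ref$index, a[1, ],
                          with_seed(78, rand_seq(100)), c(500, 50)))
})
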