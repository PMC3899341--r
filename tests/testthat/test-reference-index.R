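# FM-index construction, backward search, locate, and seed extraction.

test_that("BWT construction matches the rotation-sort oracle", {
  expect_equal(cpp_index_bwt(build_index(c(x = "ACGT"), 1)$ptr),
               bwt_oracle("ACGT"))
  set.seed(11)
  for (n in c(1, 2, 7, 40, 200)) {
    g <- rand_seq(n)
    idx <- build_index(c(x = g), 1)
    expect_equal(cpp_index_bwt(idx$ptr), bwt_oracle(g), info = g)
  }
  # multi-contig text gets a separator; the BWT still inverts through locate
  idx <- build_index(c(a = "ACGTT", b = "GGAAC"), 1)
  expect_equal(idx$lengths, c(5L, 5L))
})

test_that("backward_search counts equal naive substring counts", {
  set.seed(12)
  for (rep in 1:60) {
    g <- rand_seq(sample(30:400, 1))
    idx <- build_index(c(x = g), sample(c(1, 4, 8), 1))
    for (k in 1:6) {
      pl <- sample(1:12, 1)
      pat <- if (runif(1) < 0.7 && pl <= nchar(g)) {
        s <- sample(nchar(g) - pl + 1, 1); substr(g, s, s + pl - 1)
      } else rand_seq(pl)
      expect_identical(backward_search(idx, pat)$n,
                       count_occurrences(g, pat),
                       info = paste(g, pat))
    }
  }
})

test_that("whole-genome pattern and absent pattern behave as expected", {
  g <- "ACGGTTACGA"
  idx <- build_index(c(x = g))
  expect_identical(backward_search(idx, g)$n, 1L)
  expect_identical(backward_search(idx, "ACGTACGTACGT")$n, 0L)
  expect_identical(backward_search(idx, "ACN")$n, 0L)  # N never matches
})

test_that("locate is exact for every row at sample rate 1 and recovers sampled rates", {
  set.seed(13)
  g <- rand_seq(300)
  for (rate in c(1, 8)) {
    idx <- build_index(c(x = g), rate)
    for (k in 1:20) {
      pl <- sample(3:10, 1); s <- sample(300 - pl, 1)
      pat <- substr(g, s, s + pl - 1)
      iv <- backward_search(idx, pat)
      pos <- sort(locate_interval(idx, iv, 1000))
      naive <- which(vapply(seq_len(300 - pl + 1), function(i)
        substr(g, i, i + pl - 1) == pat, TRUE)) - 1L
      expect_identical(pos, naive)
    }
  }
})

test_that("homopolymer interval locates all positions", {
  idx <- build_index(c(x = "AAAA"), 1)
  iv <- backward_search(idx, "A")
  expect_setequal(locate_interval(idx, iv, 100), 0:3)
})

test_that("index input validation errors are informative", {
  expect_error(build_index(character(0)), "no sequences")
  expect_error(build_index(c(bad = "ACXT")), "bad")
  expect_error(build_index(c(a = "")), "empty contig")
})

test_that("MEM seeds equal the brute-force enumeration on random cases", {
  set.seed(14)
  for (rep in 1:100) {
    g <- rand_seq(sample(200:2000, 1))
    read <- if (runif(1) < 0.5) {
      # embed a (mutated) genome substring so long MEMs exist
      L <- sample(20:80, 1); s <- sample(nchar(g) - L, 1)
      r <- substr(g, s, s + L - 1)
      as.character(cpp_mutate_seqs(r, 0.05, "ACGT"))
    } else rand_seq(sample(15:60, 1))
    minlen <- sample(5:12, 1)
    idx <- build_index(c(x = g))
    got <- find_mem_seeds(idx, read, min_mem_len = minlen, max_occ = 1e6)
    expect_identical(seed_key(got), seed_key(mem_oracle(g, read, minlen)),
                     info = paste(rep, minlen))
  }
})

test_that("a read equal to a unique genome substring yields one spanning forward MEM", {
  ref <- make_test_ref(3000, seed = 21)
  read <- substr(ref$seq, 501, 560)
  mems <- find_mem_seeds(ref$index, read, min_mem_len = 15)
  fwd <- mems[mems$strand == 0, ]
  expect_identical(nrow(fwd), 1L)
  expect_identical(fwd$read_offset, 0L)
  expect_identical(fwd$genome_pos, 500)
  expect_identical(fwd$length, 60L)
})

test_that("reads of N yield no seeds and short reads are handled", {
  ref <- make_test_ref(2000, seed = 22)
  expect_identical(nrow(find_mem_seeds(ref$index, strrep("N", 30), 10)), 0L)
  expect_identical(nrow(find_mem_seeds(ref$index, "ACG", min_mem_len = 10)), 0L)
})

test_that("MEMs are strand-symmetric under read reverse complement", {
  ref <- make_test_ref(3000, seed = 23)
  set.seed(24)
  for (k in 1:10) {
    read <- as.character(cpp_mutate_seqs(
      substr(ref$seq, 100 * k + 1, 100 * k + 60), 0.03, "ACGT"))
    a <- find_mem_seeds(ref$index, read, 10)
    b <- find_mem_seeds(ref$index, revcomp(read), 10)
    # seeds of revcomp(read) are the same matches with strands swapped
    a$strand <- 1L - a$strand
    expect_identical(seed_key(a), seed_key(b))
  }
})

test_that("k-mer seeding tiles non-overlapping windows and respects N", {
  idx <- build_index(c(x = "ACGTACGT"))
  ks <- find_kmer_seeds(idx, "ACGTACGT", k = 4, max_occ = 100)
  fwd <- ks[ks$strand == 0, ]
  expect_setequal(fwd$read_offset, c(0L, 4L))
  expect_setequal(fwd$genome_pos[fwd$read_offset == 0], c(0, 4))
  expect_setequal(fwd$genome_pos[fwd$read_offset == 4], c(0, 4))
  expect_true(all(ks$kind == "KMER" & ks$length == 4L))
  # at most floor(L / k) windows per strand
  ref <- make_test_ref(5000, seed = 25)
  read <- substr(ref$seq, 1001, 1100)
  ks <- find_kmer_seeds(ref$index, read, k = 13)
  expect_lte(length(unique(ks$read_offset[ks$strand == 0])), 7L)
  # window containing N contributes nothing
  readN <- paste0(substr(read, 1, 13), strrep("N", 13), substr(read, 27, 100))
  ksN <- find_kmer_seeds(ref$index, readN, k = 13)
  expect_false(13L %in% ksN$read_offset[ksN$strand == 0])
})

test_that("seed substrings match the genome (strand-adjusted)", {
  ref <- make_test_ref(4000, seed = 26)
  read <- as.character(cpp_mutate_seqs(substr(ref$seq, 2001, 2080), 0.04, "ACGT"))
  mems <- find_mem_seeds(ref$index, read, 8)
  ori <- c(read, revcomp(read))
  for (i in seq_len(nrow(mems))) {
    s <- mems[i, ]
    expect_identical(
      substr(ori[s$strand + 1], s$read_offset + 1, s$read_offset + s$length),
      substr(ref$seq, s$genome_pos + 1, s$genome_pos + s$length))
  }
})

test_that("no seed straddles a contig boundary", {
  g <- c(a = "ACGTACGTAC", b = "GTACGTACGT")
  idx <- build_index(g)
  # the concatenation 'a'+'b' would contain ACGTACGTACGTAC...; a seed across
  # the junction must not appear
  mems <- find_mem_seeds(idx, "ACGTACGTACGTAC", 6, max_occ = 1e4)
  for (i in seq_len(nrow(mems))) {
    s <- mems[i, ]
    ci <- findInterval(s$genome_pos, idx$starts)
    expect_lte(s$genome_pos + s$length, idx$starts[ci] + idx$lengths[ci])
  }
})

test_that("saving and loading an index reproduces it", {
  ref <- make_test_ref(1500, seed = 27)
  f <- tempfile(fileext = ".idx")
  save_index(ref$index, f)
  idx2 <- load_index(f)
  expect_identical(idx2$names, ref$index$names)
  expect_identical(cpp_index_bwt(idx2$ptr), cpp_index_bwt(ref$index$ptr))
  unlink(f)
})
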