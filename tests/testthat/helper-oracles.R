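# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own data structures: rotation sort for the BWT, regex
# scans for substring counts, diagonal run-length scans for MEMs, and plain
# full-matrix R loops for the affine DP scores.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# BWT via sorting all rotations of text + sentinel
bwt_oracle <- function(text) {
  s <- paste0(text, "$")
  n <- nchar(s)
  rot <- vapply(seq_len(n), function(i)
    paste0(substr(s, i, n), substr(s, 1, i - 1)), "")
  # symbol order of the index alphabet: $ < A < C < G < T < N
  key <- vapply(rot, function(r)
    paste(sprintf("%02d", match(strsplit(r, "")[[1]],
                                c("$", "A", "C", "G", "T", "N"))),
          collapse = ""), "")
  sorted <- rot[order(key)]
  paste(substr(sorted, n, n), collapse = "")
}

count_occurrences <- function(genome, pattern) {
  if (grepl("N", pattern)) return(0L)
  hits <- gregexpr(pattern, genome, fixed = TRUE)[[1]]
  # gregexpr misses overlapping matches; scan manually
  n <- 0L
  for (i in seq_len(nchar(genome) - nchar(pattern) + 1))
    if (substr(genome, i, i + nchar(pattern) - 1) == pattern) n <- n + 1L
  n
}

# all maximal exact matches of length >= minlen between read and genome,
# per strand, via diagonal run-length scans
mem_oracle <- function(genome, read, minlen) {
  gi <- strsplit(genome, "")[[1]]
  out <- list()
  for (strand in 0:1) {
    ori <- if (strand == 1) revcomp(read) else read
    qi <- strsplit(ori, "")[[1]]
    L <- length(qi); G <- length(gi)
    for (d in (-(L - 1)):(G - 1)) {
      i0 <- max(0, -d); j0 <- max(0, d)
      len <- min(L - i0, G - j0)
      if (len < minlen) next
      eq <- qi[i0 + seq_len(len)] == gi[j0 + seq_len(len)] &
        qi[i0 + seq_len(len)] %in% c("A", "C", "G", "T")
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (k in which(r$values & r$lengths >= minlen)) {
        out[[length(out) + 1]] <- data.frame(
          read_offset = i0 + starts[k] - 1,
          genome_pos = j0 + starts[k] - 1,
          length = r$lengths[k], strand = strand)
      }
    }
  }
  if (!length(out))
    return(data.frame(read_offset = integer(), genome_pos = integer(),
                      length = integer(), strand = integer()))
  do.call(rbind, out)
}

seed_key <- function(df)
  sort(paste(df$read_offset, df$genome_pos, df$length, df$strand))

NEGINF <- -1e9

# score-only affine local alignment oracle (full matrix, plain loops)
local_score_oracle <- function(q, r, sc) {
  qi <- strsplit(q, "")[[1]]; ri <- strsplit(r, "")[[1]]
  m <- length(qi); w <- length(ri)
  H <- matrix(0, m + 1, w + 1); E <- matrix(NEGINF, m + 1, w + 1)
  F <- matrix(NEGINF, m + 1, w + 1)
  go <- sc$gap_open + sc$gap_extend; ge <- sc$gap_extend
  best <- 0
  for (i in 2:(m + 1)) for (j in 2:(w + 1)) {
    E[i, j] <- max(H[i, j - 1] + go, E[i, j - 1] + ge)
    F[i, j] <- max(H[i - 1, j] + go, F[i - 1, j] + ge)
    mt <- qi[i - 1] == ri[j - 1] && qi[i - 1] %in% c("A", "C", "G", "T")
    d <- H[i - 1, j - 1] + if (mt) sc$match else sc$mismatch
    H[i, j] <- max(0, d, E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

semiglobal_score_oracle <- function(q, r, sc) {
  qi <- strsplit(q, "")[[1]]; ri <- strsplit(r, "")[[1]]
  m <- length(qi); w <- length(ri)
  H <- matrix(NEGINF, m + 1, w + 1); E <- matrix(NEGINF, m + 1, w + 1)
  F <- matrix(NEGINF, m + 1, w + 1)
  go <- sc$gap_open + sc$gap_extend; ge <- sc$gap_extend
  H[1, ] <- 0
  for (i in 2:(m + 1)) { F[i, 1] <- sc$gap_open + (i - 1) * ge; H[i, 1] <- F[i, 1] }
  for (i in 2:(m + 1)) for (j in 2:(w + 1)) {
    E[i, j] <- max(H[i, j - 1] + go, E[i, j - 1] + ge)
    F[i, j] <- max(H[i - 1, j] + go, F[i - 1, j] + ge)
    mt <- qi[i - 1] == ri[j - 1] && qi[i - 1] %in% c("A", "C", "G", "T")
    d <- H[i - 1, j - 1] + if (mt) sc$match else sc$mismatch
    H[i, j] <- max(d, E[i, j], F[i, j])
  }
  max(H[m + 1, ])
}

# re-derive an alignment's score by walking its CIGAR against the reference
rescore_alignment <- function(read, contig_seq, pos, strand, cigar,
                              sc = scoring_scheme()) {
  ori <- if (identical(strand, "-")) revcomp(read) else read
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDS]", cigar))[[1]]
  lens <- as.integer(sub("[MIDS]", "", ops)); kinds <- sub("[0-9]+", "", ops)
  qi <- 0; ri <- pos; score <- 0
  for (k in seq_along(ops)) {
    if (kinds[k] == "S") qi <- qi + lens[k]
    else if (kinds[k] == "M") {
      for (t in seq_len(lens[k])) {
        a <- substr(ori, qi + t, qi + t)
        b <- substr(contig_seq, ri + t, ri + t)
        score <- score + if (a == b && a %in% c("A", "C", "G", "T"))
          sc$match else sc$mismatch
      }
      qi <- qi + lens[k]; ri <- ri + lens[k]
    } else if (kinds[k] == "I") {
      score <- score + sc$gap_open + lens[k] * sc$gap_extend
      qi <- qi + lens[k]
    } else {
      score <- score + sc$gap_open + lens[k] * sc$gap_extend
      ri <- ri + lens[k]
    }
  }
  score
}

cigar_read_len <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDS]", cigar))[[1]]
  sum(as.integer(sub(".$", "", ops[grepl("[MIS]$", ops)])))
}

# cost of one candidate base string under the translation objective
translation_cost <- function(bases, stripped_colors, guidance, anchor_base,
                             reverse = FALSE) {
  b <- strsplit(bases, "")[[1]]
  gd <- strsplit(guidance, "")[[1]]
  ec <- strsplit(stripped_colors, "")[[1]]
  code <- function(x) match(x, c("A", "C", "G", "T")) - 1L
  cost <- 2 * sum(b != gd & gd != "N")  # base mismatch costs 2, color 1
  if (length(ec)) {
    implied <- bitwXor(code(b[-length(b)]), code(b[-1]))
    obs <- suppressWarnings(as.integer(ec))
    cost <- cost + sum(implied != obs & !is.na(obs))
  }
  if (!is.na(anchor_base) && anchor_base != "N") {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    first <- if (reverse) comp[[b[length(b)]]] else b[1]
    cost <- cost + as.numeric(first != anchor_base)
  }
  cost
}

# a tiny deterministic genome/index pair reused by several files
make_test_ref <- function(len = 20000, seed = 101) {
  g <- simulate_genome(len, seed = seed)
  list(genome = g, index = build_index(g), seq = g[[1]])
}
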