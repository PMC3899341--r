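# Read and genome simulation with recorded ground truth. The base-space
# simulator mirrors wgsim's default behaviour: fragments drawn uniformly,
# insert sizes from N(mean, sd), FR orientation, substitution-only errors at
# a uniform per-base rate. Truth is recorded before errors are injected.

#' Simulate a random genome
#'
#' Draws i.i.d. bases at the requested GC content. Deterministic for a fixed
#' seed.
#'
#' @param length genome length in bases.
#' @param gc GC fraction in [0, 1].
#' @param seed RNG seed (optional; uses the current stream when \code{NULL}).
#' @param n_contigs number of contigs the sequence is split into.
#' @param file optional FASTA path to write (gzip when ending in \code{.gz}).
#' @return Named character vector of contig sequences (invisibly the file
#'   path when \code{file} is given).
#' @examples
#' g <- simulate_genome(1000, seed = 1)
#' nchar(g)
#' @export
simulate_genome <- function(length, gc = 0.5, seed = NULL, n_contigs = 1L,
                            file = NULL) {
  stopifnot(length >= 1, gc >= 0, gc <= 1, n_contigs >= 1)
  with_seed(seed, {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = p)
    bounds <- floor(seq(0, length, length.out = n_contigs + 1))
    seqs <- vapply(seq_len(n_contigs), function(i)
      paste(bases[(bounds[i] + 1):bounds[i + 1]], collapse = ""), "")
    names(seqs) <- paste0("chr", seq_len(n_contigs))
    if (!is.null(file)) {
      write_fasta(seqs, file)
      return(invisible(file))
    }
    seqs
  })
}

sample_fragments <- function(genome, n, read_len, insert_mean, insert_sd) {
  clen <- nchar(genome)
  if (insert_mean < 2 * read_len)
    stop("insert_mean must be at least twice the read length")
  if (all(clen < insert_mean))
    stop("genome too short for the requested insert size")
  usable <- which(clen >= insert_mean)
  ci <- usable[sample.int(length(usable), n, replace = TRUE,
                          prob = clen[usable])]
  ins <- pmax(read_len, pmin(round(rnorm(n, insert_mean, insert_sd)),
                             clen[ci]))
  start <- floor(runif(n) * (clen[ci] - ins + 1))  # 0-based leftmost
  list(contig = names(genome)[ci], ci = ci, insert = ins, start = start)
}

#' Simulate Illumina-like paired-end reads
#'
#' Fragments are placed uniformly on the genome with insert sizes from
#' N(\code{insert_mean}, \code{insert_sd}); end 1 is the forward prefix of
#' the fragment and end 2 the reverse complement of its suffix (FR layout).
#' Substitution errors are injected at a uniform per-base rate after the
#' true positions are recorded.
#'
#' @param genome named character vector of contigs (or a FASTA path).
#' @param n_pairs number of read pairs.
#' @param read_len read length.
#' @param err_rate per-base substitution error rate.
#' @param insert_mean,insert_sd insert-size distribution.
#' @param seed RNG seed.
#' @param prefix read-name prefix.
#' @return List with \code{reads1}, \code{reads2} (data frames with
#'   \code{id}, \code{seq}, \code{qual}) and \code{truth} (one row per read:
#'   \code{read_id}, \code{contig}, \code{pos} 0-based leftmost,
#'   \code{strand}).
#' @examples
#' g <- simulate_genome(20000, seed = 1)
#' sim <- simulate_pe_reads(g, 10, 100, 0.02, 500, 50, seed = 2)
#' head(sim$truth)
#' @export
simulate_pe_reads <- function(genome, n_pairs, read_len = 100,
                              err_rate = 0.02, insert_mean = 500,
                              insert_sd = 50, seed = NULL, prefix = "r") {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta_seqs(genome)
  stopifnot(n_pairs >= 1, read_len >= 1, err_rate >= 0, err_rate < 1)
  with_seed(seed, {
    fr <- sample_fragments(genome, n_pairs, read_len, insert_mean, insert_sd)
    g <- genome[fr$ci]
    r1 <- substring(g, fr$start + 1, fr$start + read_len)
    p2 <- fr$start + fr$insert - read_len
    r2 <- revcomp(substring(g, p2 + 1, p2 + read_len))
    ids <- sprintf("%s%06d", prefix, seq_len(n_pairs))
    truth <- data.frame(
      read_id = c(paste0(ids, "/1"), paste0(ids, "/2")),
      contig = rep(fr$contig, 2),
      pos = c(fr$start, p2),
      strand = rep(c("+", "-"), each = n_pairs),
      stringsAsFactors = FALSE)
    if (err_rate > 0) {
      r1 <- as.character(cpp_mutate_seqs(r1, err_rate, "ACGT"))
      r2 <- as.character(cpp_mutate_seqs(r2, err_rate, "ACGT"))
    }
    qual <- strrep("I", read_len)
    list(reads1 = data.frame(id = paste0(ids, "/1"), seq = r1, qual = qual,
                             stringsAsFactors = FALSE),
         reads2 = data.frame(id = paste0(ids, "/2"), seq = r2, qual = qual,
                             stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Simulate SOLiD-like color-space mate pairs
#'
#' Mate-paired (FF) layout: both ends are read from the forward strand of the
#' fragment, end 1 at its 5' start and end 2 at its 3' end. Each read is
#' emitted CSFASTA-style as a primer base plus \code{read_len} colors (the
#' first color links the primer to the first base). Color-level substitution
#' errors are injected after truth is recorded.
#'
#' @inheritParams simulate_pe_reads
#' @param err_rate per-color substitution error rate.
#' @return List with \code{reads1}, \code{reads2} (data frames with
#'   \code{id}, \code{primer}, \code{colors}, \code{qual}) and \code{truth}
#'   (base-space 0-based leftmost positions; both strands \code{"+"}).
#' @export
simulate_color_pairs <- function(genome, n_pairs, read_len = 50,
                                 err_rate = 0.02, insert_mean = 200,
                                 insert_sd = 20, seed = NULL, prefix = "c") {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta_seqs(genome)
  with_seed(seed, {
    fr <- sample_fragments(genome, n_pairs, read_len, insert_mean, insert_sd)
    g <- genome[fr$ci]
    b1 <- substring(g, fr$start + 1, fr$start + read_len)
    p2 <- fr$start + fr$insert - read_len
    b2 <- substring(g, p2 + 1, p2 + read_len)
    primer <- "T"
    c1 <- as.character(cpp_encode_colors(paste0(primer, b1)))
    c2 <- as.character(cpp_encode_colors(paste0(primer, b2)))
    if (err_rate > 0) {
      c1 <- as.character(cpp_mutate_seqs(c1, err_rate, "0123"))
      c2 <- as.character(cpp_mutate_seqs(c2, err_rate, "0123"))
    }
    ids <- sprintf("%s%06d", prefix, seq_len(n_pairs))
    qual <- strrep("I", read_len)
    truth <- data.frame(
      read_id = c(paste0(ids, "/1"), paste0(ids, "/2")),
      contig = rep(fr$contig, 2),
      pos = c(fr$start, p2),
      strand = "+",
      stringsAsFactors = FALSE)
    list(reads1 = data.frame(id = paste0(ids, "/1"), primer = primer,
                             colors = c1, qual = qual, stringsAsFactors = FALSE),
         reads2 = data.frame(id = paste0(ids, "/2"), primer = primer,
                             colors = c2, qual = qual, stringsAsFactors = FALSE),
         truth = truth)
  })
}
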