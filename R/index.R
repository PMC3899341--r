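#' Build an FM-index over a reference genome
#'
#' Constructs the Burrows-Wheeler transform, rank structure and sampled suffix
#' array used for seed lookup. Contigs are concatenated with separator symbols
#' so that no seed or extension can straddle a contig boundary. \code{N} (and
#' any IUPAC ambiguity code) is excluded from the match alphabet: a pattern
#' containing it never matches.
#'
#' @param fasta path to a (optionally gzip-compressed) FASTA file, or a named
#'   character vector of sequences.
#' @param sa_sample_rate sampling rate of the suffix array (every position
#'   divisible by the rate is stored; others are recovered by LF-walk).
#' @param color set to \code{TRUE} when \code{fasta} holds color-space (digit)
#'   sequences, as produced by \code{\link{encode_colors}}.
#' @return An object of class \code{"hybridaln_index"}.
#' @examples
#' idx <- build_index(c(chr1 = "ACGTACGTACGTACGT"))
#' idx
#' @export
build_index <- function(fasta, sa_sample_rate = 8L, color = FALSE) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta))
    read_fasta_seqs(fasta) else fasta
  if (!is.character(seqs) || length(seqs) == 0L)
    stop("no sequences found: supply a FASTA path or a named character vector")
  if (any(nchar(seqs) == 0L)) stop("empty contig in reference input")
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    names(seqs) <- paste0("contig", seq_along(seqs))
  if (!color) {
    bad <- grepl("[^ACGTRYSWKMBDHVNacgtryswkmbdhvn]", seqs)
    if (any(bad))
      stop("non-IUPAC characters in record(s): ",
           paste(names(seqs)[bad], collapse = ", "))
  } else if (any(grepl("[^0123.]", seqs))) {
    stop("color-space reference must use symbols 0-3 and '.'")
  }
  sa_sample_rate <- as.integer(sa_sample_rate)
  stopifnot(sa_sample_rate >= 1L)
  ptr <- cpp_build_index(unname(seqs), names(seqs), sa_sample_rate, color)
  info <- cpp_index_info(ptr)
  structure(list(ptr = ptr, names = info$names, starts = info$starts,
                 lengths = info$lengths, text_length = info$text_length,
                 sa_sample_rate = info$sa_sample_rate, color = isTRUE(color)),
            class = "hybridaln_index")
}

#' @export
print.hybridaln_index <- function(x, ...) {
  cat("hybridaln FM-index (", if (x$color) "color" else "base", " space)\n",
      sep = "")
  cat("  contigs:", length(x$names), " total length:",
      sum(as.numeric(x$lengths)), "bp\n")
  cat("  suffix-array sample rate:", x$sa_sample_rate, "\n")
  invisible(x)
}

#' Build the color-space companion index of a base-space reference
#'
#' Encodes every contig as its di-base color sequence and indexes the result;
#' color reads are seeded and extended against this index before being
#' translated back to nucleotides.
#'
#' @param fasta the same FASTA path or named character vector used for the
#'   base-space index.
#' @param sa_sample_rate suffix-array sampling rate.
#' @return A color-space \code{"hybridaln_index"}.
#' @export
build_color_index <- function(fasta, sa_sample_rate = 8L) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta))
    read_fasta_seqs(fasta) else fasta
  cols <- setNames(as.character(encode_colors(seqs)), names(seqs))
  build_index(cols, sa_sample_rate = sa_sample_rate, color = TRUE)
}

#' Save / load an index
#'
#' The packed reference text is written to disk; the BWT and rank structures
#' are rebuilt deterministically on load.
#'
#' @param index a \code{"hybridaln_index"}.
#' @param file destination / source path.
#' @return \code{load_index} returns the rebuilt index.
#' @export
save_index <- function(index, file) {
  stopifnot(inherits(index, "hybridaln_index"))
  seqs <- index_sequences(index)
  saveRDS(list(format = "hybridaln-index-v1", sequences = seqs,
               sa_sample_rate = index$sa_sample_rate, color = index$color),
          file)
  invisible(file)
}

#' @rdname save_index
#' @export
load_index <- function(file) {
  obj <- readRDS(file)
  if (!identical(obj$format, "hybridaln-index-v1"))
    stop("not a hybridaln index file: ", file)
  build_index(obj$sequences, sa_sample_rate = obj$sa_sample_rate,
              color = obj$color)
}

# contig sequences back out of the packed text
index_sequences <- function(index) {
  setNames(vapply(seq_along(index$names), function(i)
    cpp_extract_text(index$ptr, index$starts[i], index$lengths[i],
                     index$color), ""), index$names)
}

#' Backward search on the FM-index
#'
#' Finds the suffix-array interval of all exact occurrences of a pattern.
#'
#' @param index a \code{"hybridaln_index"}.
#' @param pattern nucleotide (or color) string; a pattern containing \code{N}
#'   (or \code{.}) yields an empty interval.
#' @return A list with \code{lower}, \code{upper} (0-based, half-open rows) and
#'   \code{n} (number of occurrences).
#' @examples
#' idx <- build_index(c(chr1 = "ACGTACGT"))
#' backward_search(idx, "ACG")$n
#' @export
backward_search <- function(index, pattern) {
  stopifnot(inherits(index, "hybridaln_index"), nchar(pattern) >= 1L)
  iv <- cpp_backward_search(index$ptr, pattern, index$color)
  list(lower = iv[1], upper = iv[2], n = iv[2] - iv[1])
}

#' Locate the genome positions of a suffix-array interval
#'
#' @param index a \code{"hybridaln_index"}.
#' @param interval a list from \code{\link{backward_search}}.
#' @param max_occ cap on positions returned (suffix-array order).
#' @return Integer vector of 0-based global text offsets.
#' @export
locate_interval <- function(index, interval, max_occ = 1000L) {
  cpp_locate_range(index$ptr, interval$lower, interval$upper,
                   as.integer(max_occ))
}

#' Extract MEM seeds for a read
#'
#' Enumerates, for both strands, every maximal exact match of length at least
#' \code{min_mem_len} between the read and the genome (maximal: extendable in
#' neither direction). Matches of patterns occurring more than \code{max_occ}
#' times are reported at most \code{max_occ} times, taking the first positions
#' in suffix-array order. \code{read_offset} is relative to the oriented read
#' (the reverse complement for \code{strand == 1}).
#'
#' @param index a \code{"hybridaln_index"}.
#' @param read read sequence.
#' @param min_mem_len minimal seed length.
#' @param max_occ occurrence cap per seed pattern.
#' @return \code{data.frame} with columns \code{read_offset},
#'   \code{genome_pos} (0-based global), \code{length}, \code{strand} (0
#'   forward, 1 reverse) and \code{kind}.
#' @examples
#' idx <- build_index(c(chr1 = "ACGTACGTTT"))
#' find_mem_seeds(idx, "CGTAC", min_mem_len = 3)
#' @export
find_mem_seeds <- function(index, read, min_mem_len = NULL, max_occ = 1000L) {
  stopifnot(inherits(index, "hybridaln_index"))
  if (is.null(min_mem_len))
    min_mem_len <- default_min_mem_len(sum(as.numeric(index$lengths)))
  cpp_find_seeds(index$ptr, read, as.integer(min_mem_len),
                 as.integer(max_occ), FALSE, index$color)
}

#' Extract non-overlapping exact-match k-mer seeds for a read
#'
#' Tiles each strand of the read into \code{floor(L / k)} non-overlapping
#' k-mers at offsets 0, k, 2k, ... and reports every exact genome occurrence
#' (capped at \code{max_occ} per k-mer). Windows containing \code{N}
#' contribute no seeds.
#'
#' @inheritParams find_mem_seeds
#' @param k k-mer length.
#' @return Seed \code{data.frame} as in \code{\link{find_mem_seeds}} with
#'   \code{kind == "KMER"}.
#' @export
find_kmer_seeds <- function(index, read, k = 13L, max_occ = 1000L) {
  stopifnot(inherits(index, "hybridaln_index"))
  cpp_find_seeds(index$ptr, read, as.integer(k), as.integer(max_occ),
                 TRUE, index$color)
}

#' Mapping region implied by a seed
#'
#' Projects a seed onto the genome as the window expected to contain the full
#' read placement, padded by a margin of \code{ceiling(0.1 * read_len) + 10}
#' bases to tolerate indels, and clamped to the seed's contig.
#'
#' @param seed one row of a seed \code{data.frame} (or a list with
#'   \code{read_offset}, \code{genome_pos}, \code{strand}).
#' @param read_len read length.
#' @param index a \code{"hybridaln_index"} (for contig clamping).
#' @param margin override for the padding margin.
#' @return List with \code{start}, \code{end} (0-based half-open global
#'   offsets) and \code{strand}.
#' @export
region_from_seed <- function(seed, read_len, index = NULL, margin = NULL) {
  if (is.null(margin)) margin <- ceiling(0.1 * read_len) + 10
  start <- seed$genome_pos - seed$read_offset - margin
  end <- seed$genome_pos + (read_len - seed$read_offset) + margin
  if (!is.null(index)) {
    ci <- findInterval(seed$genome_pos, index$starts)
    cs <- index$starts[ci]; ce <- cs + index$lengths[ci]
    start <- max(start, cs); end <- min(end, ce)
  } else {
    start <- max(start, 0)
  }
  list(start = start, end = end, strand = seed$strand)
}
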