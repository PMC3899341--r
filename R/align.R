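# Single-end and paired-end alignment drivers over the C++ engine.

reads_df <- function(x, prefix = "read") {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "seq") %in% names(x)))
    if (is.null(x$qual)) x$qual <- strrep("I", nchar(x$seq))
    return(x[c("id", "seq", "qual")])
  }
  ids <- names(x)
  if (is.null(ids)) ids <- sprintf("%s%d", prefix, seq_along(x))
  data.frame(id = ids, seq = unname(x), qual = strrep("I", nchar(x)),
             stringsAsFactors = FALSE)
}

engine_rows_to_df <- function(rows, index, ids) {
  df <- as.data.frame(rows, stringsAsFactors = FALSE)
  df$qname <- ids[df$read]
  df$contig <- index$names[df$contig]
  df$strand <- ifelse(df$strand == 1L, "-", "+")
  df$mode <- c("local", "semiglobal", "rescued")[df$mode + 1L]
  df$proper <- df$proper == 1L
  df[c("qname", "read", "end", "rank", "contig", "pos", "strand", "mapq",
       "score", "cigar", "nm", "identity", "aligned_frac", "mode", "proper",
       "n_candidates")]
}

#' Align single-end reads
#'
#' Runs the full hybrid-seeding single-end pipeline for each read: MEM
#' seeding, seed scoring and ranking, local extension of the top-ranked
#' seeds, semi-global rescue through a variable-length seed when no local
#' alignment qualifies, one round of exact-match k-mer re-seeding, and
#' finally reporting up to \code{max_reported} qualified alignments (or none,
#' in which case the read is unaligned and absent from the result).
#'
#' @param index a \code{"hybridaln_index"}.
#' @param reads character vector of read sequences (optionally named), or a
#'   \code{data.frame} with columns \code{id}, \code{seq} and optionally
#'   \code{qual} as returned by \code{\link{read_sequences}}.
#' @param cfg an \code{\link{align_config}}.
#' @return A \code{data.frame} with one row per reported alignment: read name
#'   and index, rank (1 = primary), contig, 0-based leftmost position, strand,
#'   MAPQ, score, CIGAR, NM edit distance, percent identity, aligned base
#'   fraction, and alignment mode (\code{local}, \code{semiglobal} or
#'   \code{rescued}).
#' @examples
#' idx <- build_index(c(chr1 = strrep("ACGTT", 40)))
#' align_reads(idx, c(r1 = "ACGTTACGTTACGTTACGTT"),
#'             cfg = align_config(min_mem_len = 10))
#' @export
align_reads <- function(index, reads, cfg = align_config()) {
  stopifnot(inherits(index, "hybridaln_index"))
  rd <- reads_df(reads)
  ecfg <- resolve_config(cfg, index, color = index$color)
  rows <- cpp_align_se_batch(index$ptr, rd$seq, ecfg)
  engine_rows_to_df(rows, index, rd$id)
}

#' @rdname align_reads
#' @param read a single read sequence.
#' @export
align_single <- function(index, read, cfg = align_config()) {
  align_reads(index, setNames(read, "read1"), cfg)
}

#' Score and rank seeds by optimal local alignment score
#'
#' Derives the mapping region of each seed, computes the optimal local
#' alignment score of the read against it (the seed score \eqn{q}), removes
#' seeds collapsing to the same (region, strand), and orders the survivors by
#' descending score (ties: smaller region start, then forward strand first).
#'
#' @param index a \code{"hybridaln_index"}.
#' @param read the read sequence.
#' @param seeds seed \code{data.frame} from \code{\link{find_mem_seeds}} or
#'   \code{\link{find_kmer_seeds}}.
#' @param scoring a \code{\link{scoring_scheme}}.
#' @return The seed \code{data.frame} (deduplicated) with added columns
#'   \code{score_q}, \code{region_start}, \code{region_end}, sorted best
#'   first.
#' @export
score_and_rank_seeds <- function(index, read, seeds,
                                 scoring = scoring_scheme()) {
  L <- nchar(read)
  if (nrow(seeds) == 0L) {
    seeds$score_q <- numeric(0); seeds$region_start <- numeric(0)
    seeds$region_end <- numeric(0)
    return(seeds)
  }
  reg <- lapply(seq_len(nrow(seeds)), function(i)
    region_from_seed(seeds[i, ], L, index))
  seeds$region_start <- vapply(reg, `[[`, 0, "start")
  seeds$region_end <- vapply(reg, `[[`, 0, "end")
  keep <- !duplicated(seeds[c("strand", "region_start")])
  seeds <- seeds[keep, , drop = FALSE]
  ori <- c(read, as.character(revcomp(read, color = index$color)))
  seeds$score_q <- vapply(seq_len(nrow(seeds)), function(i) {
    s <- seeds[i, ]
    region <- cpp_extract_text(index$ptr, s$region_start,
                               as.integer(s$region_end - s$region_start),
                               index$color)
    raw <- cpp_local_align(ori[s$strand + 1L], region, unclass(scoring),
                           index$color)
    as.numeric(raw$score)
  }, 0)
  ord <- order(-seeds$score_q, seeds$region_start, seeds$strand)
  seeds <- seeds[ord, , drop = FALSE]
  rownames(seeds) <- NULL
  attr(seeds, "read_len") <- L
  seeds
}

#' Weight of a seed (or alignment) pair
#'
#' The pairing weight is the summed alignment score of the two ends
#' normalized by the maximum achievable score,
#' \deqn{w = (q_1 + q_2) / (m (L_1 + L_2)),}
#' where \eqn{q_i} is the optimal local (or semi-global) alignment score of
#' end \eqn{i} against its mapping region, \eqn{m} the match score and
#' \eqn{L_i} the read lengths. \eqn{w} lies in [0, 1] for non-negative scores
#' and is monotone increasing in each \eqn{q_i}.
#'
#' @param q1,q2 alignment scores of the two ends.
#' @param m positive match score.
#' @param len1,len2 read lengths.
#' @return The weight \eqn{w}.
#' @examples
#' pair_weight(100, 100, 1, 100, 100)  # 1
#' @export
pair_weight <- function(q1, q2, m, len1, len2) {
  stopifnot(m > 0, len1 > 0, len2 > 0)
  (q1 + q2) / (m * (len1 + len2))
}

#' Enumerate and rank qualified seed pairs
#'
#' Considers every pair of high-quality seeds (score at least
#' \code{min_seed_score}) whose orientations fit the library layout and whose
#' implied insert size falls inside \code{mean +/- insert_nsd * sd}, computes
#' the pairing weight for each, and returns them in max-heap (non-increasing
#' weight) order.
#'
#' @param ranked1,ranked2 scored seed frames from
#'   \code{\link{score_and_rank_seeds}} for end 1 and end 2.
#' @param insert numeric \code{c(mean, sd)} of the insert size.
#' @param cfg an \code{\link{align_config}} (supplies the score threshold,
#'   window width and orientation).
#' @param len1,len2 read lengths; defaults to the attribute recorded by
#'   \code{\link{score_and_rank_seeds}}.
#' @return \code{data.frame} of seed pairs with implied positions, insert and
#'   weight \code{w}, sorted by non-increasing \code{w}.
#' @export
pair_seeds <- function(ranked1, ranked2, insert, cfg = align_config(),
                       len1 = attr(ranked1, "read_len"),
                       len2 = attr(ranked2, "read_len")) {
  m <- cfg$scoring$match
  thr <- if (is.null(cfg$min_seed_score)) 30 * m else cfg$min_seed_score
  lo <- max(0, insert[1] - cfg$insert_nsd * insert[2])
  hi <- insert[1] + cfg$insert_nsd * insert[2]
  h1 <- ranked1[ranked1$score_q >= thr, , drop = FALSE]
  h2 <- ranked2[ranked2$score_q >= thr, , drop = FALSE]
  out <- data.frame()
  if (nrow(h1) && nrow(h2)) {
    g <- expand.grid(i = seq_len(nrow(h1)), j = seq_len(nrow(h2)))
    p1 <- h1$genome_pos[g$i] - h1$read_offset[g$i]
    p2 <- h2$genome_pos[g$j] - h2$read_offset[g$j]
    s1 <- h1$strand[g$i]; s2 <- h2$strand[g$j]
    if (cfg$orientation == "ff") {
      ok <- s1 == s2
      ins <- ifelse(p2 >= p1, p2 + len2 - p1, p1 + len1 - p2)
    } else {
      ok <- s1 != s2
      ins <- ifelse(s1 == 0, p2 + len2 - p1, p1 + len1 - p2)
      ok <- ok & ifelse(s1 == 0, p2 >= p1, p1 >= p2)
    }
    ok <- ok & ins >= lo & ins <= hi
    if (any(ok)) {
      w <- pair_weight(h1$score_q[g$i[ok]], h2$score_q[g$j[ok]], m, len1, len2)
      out <- data.frame(i1 = g$i[ok], i2 = g$j[ok],
                        pos1 = p1[ok], pos2 = p2[ok],
                        insert = ins[ok], w = w)
      out <- out[order(-out$w, out$pos1, out$i1), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  out
}

cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDS]", cg))[[1]]
    sum(as.numeric(sub("[MIDS]", "", ops[grepl("[MD]$", ops)])))
  }, 0, USE.NAMES = FALSE)
}

#' Estimate the insert-size distribution from a read-pair sample
#'
#' Aligns a sample of pairs in single-end mode, keeps pairs in which both ends
#' have a unique qualified alignment in proper orientation on one contig,
#' drops outliers beyond 3 IQRs from the median, and returns the mean and
#' standard deviation of the remaining observed insert sizes.
#'
#' @param index a \code{"hybridaln_index"}.
#' @param reads1,reads2 paired reads (character vectors or read frames).
#' @param cfg an \code{\link{align_config}} (\code{sample_n} controls the
#'   sample size).
#' @return Named numeric \code{c(mean, sd, n)}.
#' @export
estimate_insert_size <- function(index, reads1, reads2, cfg = align_config()) {
  r1 <- reads_df(reads1); r2 <- reads_df(reads2)
  stopifnot(nrow(r1) == nrow(r2))
  n <- min(nrow(r1), cfg$sample_n)
  a1 <- align_reads(index, r1$seq[seq_len(n)], cfg)
  a2 <- align_reads(index, r2$seq[seq_len(n)], cfg)
  uniq <- function(a) {
    tab <- table(a$read)
    a[a$read %in% as.integer(names(tab)[tab == 1L]), , drop = FALSE]
  }
  a1 <- uniq(a1); a2 <- uniq(a2)
  common <- intersect(a1$read, a2$read)
  a1 <- a1[match(common, a1$read), , drop = FALSE]
  a2 <- a2[match(common, a2$read), , drop = FALSE]
  same <- a1$contig == a2$contig
  if (cfg$orientation == "ff") {
    ok <- same & a1$strand == a2$strand
    ins <- ifelse(a2$pos >= a1$pos,
                  a2$pos + cigar_ref_span(a2$cigar) - a1$pos,
                  a1$pos + cigar_ref_span(a1$cigar) - a2$pos)
  } else {
    ok <- same & a1$strand != a2$strand
    fwd1 <- a1$strand == "+"
    ins <- ifelse(fwd1, a2$pos + cigar_ref_span(a2$cigar) - a1$pos,
                  a1$pos + cigar_ref_span(a1$cigar) - a2$pos)
    ok <- ok & ins > 0
  }
  ins <- ins[ok]
  if (length(ins) >= 4) {
    qs <- quantile(ins, c(0.25, 0.75), names = FALSE)
    iqr <- qs[2] - qs[1]
    keep <- abs(ins - median(ins)) <= 3 * max(iqr, 0)
    if (iqr > 0) ins <- ins[keep]
  }
  if (length(ins) < 100)
    stop("too few uniquely aligned proper pairs (", length(ins), ") to ",
         "estimate the insert size; supply --insert-mean/--insert-sd ",
         "(insert_mean/insert_sd) explicitly")
  c(mean = mean(ins), sd = sd(ins), n = length(ins))
}

#' Align read pairs
#'
#' Runs the paired-end pipeline: MEM seeding and ranking per end, weighted
#' seed pairing under the insert-size constraint with iterative k-mer
#' re-seeding of ends without qualified pairs, extension of seed pairs into
#' qualified alignment pairs ranked by weight then edit-distance sum, read
#' mate rescuing from confident anchor alignments when pairing fails, and
#' single-end fallback reporting for reads that remain unpaired.
#'
#' @param index a \code{"hybridaln_index"}.
#' @param reads1,reads2 paired reads (character vectors or read frames).
#' @param cfg an \code{\link{align_config}}.
#' @param insert_mean,insert_sd insert-size distribution; when \code{NULL}
#'   they are estimated with \code{\link{estimate_insert_size}}.
#' @return A \code{data.frame} as in \code{\link{align_reads}} with additional
#'   meaning for \code{end} (1 or 2) and \code{proper} (\code{TRUE} when the
#'   row belongs to a qualified alignment pair); \code{rank} pairs rows of the
#'   two ends. The estimated insert is attached as attribute \code{insert}.
#' @export
align_pairs <- function(index, reads1, reads2, cfg = align_config(),
                        insert_mean = NULL, insert_sd = NULL) {
  stopifnot(inherits(index, "hybridaln_index"))
  r1 <- reads_df(reads1, "read"); r2 <- reads_df(reads2, "read")
  if (nrow(r1) != nrow(r2)) stop("paired read inputs differ in length")
  if (is.null(insert_mean) || is.null(insert_sd)) {
    est <- estimate_insert_size(index, r1, r2, cfg)
    insert_mean <- est[["mean"]]; insert_sd <- est[["sd"]]
  }
  ecfg <- resolve_config(cfg, index, color = index$color)
  rows <- cpp_align_pe_batch(index$ptr, r1$seq, r2$seq, insert_mean,
                             insert_sd, ecfg)
  ids <- sub("/[12]$", "", r1$id)
  out <- engine_rows_to_df(rows, index, ids)
  attr(out, "insert") <- c(mean = insert_mean, sd = insert_sd)
  out
}

#' Rescue an unaligned mate from an anchored alignment
#'
#' Semi-globally aligns the mate inside the genomic window implied by the
#' anchor's position and strand, the library orientation and the insert-size
#' window; the alignment is returned only when it passes the semi-global
#' qualification thresholds and the anchor's MAPQ reaches
#' \code{rescue_min_mapq}.
#'
#' @param index a \code{"hybridaln_index"}.
#' @param anchored a list or single-row \code{data.frame} with \code{contig},
#'   \code{pos} (0-based), \code{strand} (\code{"+"}/\code{"-"}),
#'   \code{cigar} and \code{mapq} describing the anchor alignment.
#' @param mate_read the mate's sequence.
#' @param insert numeric \code{c(mean, sd)}.
#' @param cfg an \code{\link{align_config}}.
#' @return A list describing the rescued alignment, or \code{NULL} when the
#'   rescue is not attempted or fails qualification.
#' @export
rescue_mate <- function(index, anchored, mate_read, insert,
                        cfg = align_config()) {
  ci <- match(anchored$contig, index$names)
  if (is.na(ci)) stop("anchor contig not present in the index")
  gstart <- index$starts[ci] + anchored$pos
  strand <- if (identical(anchored$strand, "-") || identical(anchored$strand, 1L)) 1L else 0L
  span <- as.integer(cigar_ref_span(anchored$cigar))
  ecfg <- resolve_config(cfg, index, color = index$color)
  res <- cpp_rescue_mate(index$ptr, gstart, strand, span,
                         as.integer(anchored$mapq), mate_read,
                         insert[1], insert[2], ecfg)
  if (!isTRUE(res$rescued)) return(NULL)
  res$contig <- index$names[res$contig]
  res$strand <- if (res$strand == 1L) "-" else "+"
  res$rescued <- NULL
  res
}

#' Reverse complement
#'
#' @param x character vector of sequences.
#' @param color in color space complementation is the identity, so the
#'   reverse strand is the plain reversal of the color string.
#' @return Character vector of reverse-complemented sequences.
#' @export
revcomp <- function(x, color = FALSE) {
  if (color) {
    return(vapply(strsplit(x, ""), function(s)
      paste(rev(s), collapse = ""), ""))
  }
  as.character(cpp_revcomp(x))
}
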