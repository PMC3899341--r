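# Evaluation of alignments against simulated truth: sensitivity, recall (all
# reported alignments vs first occurrence only) and the MAPQ-ordered ROC.

#' Evaluate alignments against simulated truth
#'
#' A read counts as aligned when it has at least one reported alignment with
#' MAPQ >= \code{min_mapq}; it counts as correctly aligned when a considered
#' alignment lies on the true contig and strand with leftmost position within
#' \code{distance_tol} bases of the truth. Sensitivity is aligned / total
#' reads, recall is correct / total reads -- computed both over all reported
#' alignments (\code{recall_all}) and over only the first alignment occurrence
#' per read (\code{recall_first}). The ROC sorts reads by descending MAPQ and
#' reports, for each threshold \eqn{q}, TPR = correct reads with MAPQ >= q /
#' total reads and FPR = incorrect reads with MAPQ >= q / aligned reads with
#' MAPQ >= q.
#'
#' @param alignments an alignment \code{data.frame} from
#'   \code{\link{align_reads}} / \code{\link{align_pairs}}, or a path to a SAM
#'   file written by \code{\link{write_sam}}.
#' @param truth truth \code{data.frame} (\code{read_id}, \code{contig},
#'   \code{pos} 0-based, \code{strand}) from the simulators, or a TSV path.
#' @param distance_tol maximal distance to the true position for an alignment
#'   to count as correct.
#' @param min_mapq minimal MAPQ for an alignment to be considered.
#' @return An object of class \code{"hybridaln_eval"}: a list with
#'   \code{sensitivity}, \code{recall_all}, \code{recall_first} (percent),
#'   \code{roc} (data.frame \code{mapq}, \code{tpr}, \code{fpr}), and counts.
#' @examples
#' truth <- data.frame(read_id = "x/1", contig = "chr1", pos = 100,
#'                     strand = "+")
#' aln <- data.frame(qname = "x/1", end = 0L, rank = 1L, contig = "chr1",
#'                   pos = 105, strand = "+", mapq = 60L)
#' evaluate_alignments(aln, truth)$recall_all  # 100: distance 5 <= 10
#' @export
evaluate_alignments <- function(alignments, truth, distance_tol = 10,
                                min_mapq = 0) {
  if (is.character(alignments) && length(alignments) == 1L)
    alignments <- read_sam(alignments)
  if (is.character(truth) && length(truth) == 1L)
    truth <- utils::read.table(truth, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  stopifnot(all(c("read_id", "contig", "pos", "strand") %in% names(truth)))
  aln <- alignments
  key <- if (!is.null(aln$end) && any(aln$end > 0))
    ifelse(aln$end > 0, paste0(aln$qname, "/", aln$end), aln$qname)
  else aln$qname
  unknown <- setdiff(unique(key), truth$read_id)
  if (length(unknown))
    stop("alignments contain reads absent from the truth table, e.g. ",
         unknown[1])
  aln <- aln[aln$mapq >= min_mapq, , drop = FALSE]
  key <- key[alignments$mapq >= min_mapq]
  ti <- match(key, truth$read_id)
  correct <- aln$contig == truth$contig[ti] &
    aln$strand == truth$strand[ti] &
    abs(aln$pos - truth$pos[ti]) <= distance_tol

  total <- nrow(truth)
  first <- !duplicated(key)
  aligned_reads <- unique(key)
  correct_all <- unique(key[correct])
  correct_first <- unique(key[first & correct])

  # per-read MAPQ (of the primary alignment) for the ROC
  pk <- key[first]
  pmapq <- aln$mapq[first]
  pcorrect <- pk %in% correct_all
  thresholds <- sort(unique(pmapq), decreasing = TRUE)
  roc <- do.call(rbind, lapply(thresholds, function(q) {
    sel <- pmapq >= q
    nal <- sum(sel)
    data.frame(mapq = q,
               tpr = 100 * sum(pcorrect & sel) / total,
               fpr = if (nal) 100 * sum(!pcorrect & sel) / nal else 0)
  }))
  structure(list(
    sensitivity = 100 * length(aligned_reads) / total,
    recall_all = 100 * length(correct_all) / total,
    recall_first = 100 * length(correct_first) / total,
    roc = roc,
    n_reads = total,
    n_aligned = length(aligned_reads),
    n_correct = length(correct_all)
  ), class = "hybridaln_eval")
}

#' @export
print.hybridaln_eval <- function(x, ...) {
  cat(sprintf("reads: %d  aligned: %d  correct: %d\n",
              x$n_reads, x$n_aligned, x$n_correct))
  cat(sprintf("sensitivity:  %.2f%%\n", x$sensitivity))
  cat(sprintf("recall (all): %.2f%%\n", x$recall_all))
  cat(sprintf("recall (1st): %.2f%%\n", x$recall_first))
  invisible(x)
}

#' Minimal SAM reader for evaluation
#'
#' Parses the mandatory SAM columns of mapped records into the alignment
#' \code{data.frame} layout used by \code{\link{evaluate_alignments}}.
#' Not a general-purpose SAM parser.
#'
#' @param path SAM file path.
#' @return Alignment \code{data.frame} (0-based \code{pos}).
#' @export
read_sam <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  if (!length(ln))
    return(data.frame(qname = character(), end = integer(), rank = integer(),
                      contig = character(), pos = numeric(),
                      strand = character(), mapq = integer(),
                      stringsAsFactors = FALSE))
  f <- strsplit(ln, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), 0L)
  df <- data.frame(
    qname = vapply(f, `[`, "", 1),
    end = ifelse(bitwAnd(flag, 64L) > 0L, 1L,
                 ifelse(bitwAnd(flag, 128L) > 0L, 2L, 0L)),
    contig = vapply(f, `[`, "", 3),
    pos = vapply(f, function(x) as.numeric(x[4]), 0) - 1,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mapq = vapply(f, function(x) as.integer(x[5]), 0L),
    stringsAsFactors = FALSE)
  df <- df[bitwAnd(flag, 4L) == 0L, , drop = FALSE]
  df$rank <- stats::ave(seq_len(nrow(df)),
                        paste(df$qname, df$end), FUN = seq_along)
  df
}
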