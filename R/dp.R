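# DP kernel surfaces. The heavy batch paths call the C++ kernels directly;
# these wrappers expose single alignments with the derived quality metrics.

aln_from_raw <- function(raw, read_len, mode) {
  albases <- raw$matches + raw$mismatches + raw$insertions
  list(score = raw$score,
       ref_start = raw$ref_start,
       cigar = raw$cigar,
       matches = raw$matches, mismatches = raw$mismatches,
       insertions = raw$insertions, deletions = raw$deletions,
       sclip_left = raw$sclip_left, sclip_right = raw$sclip_right,
       identity = if (albases > 0) 100 * raw$matches / albases else 0,
       aligned_fraction = (read_len - raw$sclip_left - raw$sclip_right) / read_len,
       edit_distance = raw$mismatches + raw$insertions + raw$deletions,
       mode = mode, empty = isTRUE(raw$empty))
}

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' Full-matrix Smith-Waterman of a read against a mapping-region sequence with
#' affine gap costs and CIGAR traceback; unaligned read ends become soft clips.
#' Ties prefer the diagonal over deletions over insertions, and among
#' equal-scoring end cells the smallest reference coordinate wins, so the
#' result is deterministic.
#'
#' @param read read sequence.
#' @param region_seq mapping-region sequence.
#' @param scoring a \code{\link{scoring_scheme}}.
#' @return An alignment list with \code{score}, \code{cigar},
#'   \code{ref_start} (0-based within the region), \code{identity} (percent,
#'   over aligned read bases), \code{aligned_fraction}, \code{edit_distance}
#'   and \code{mode = "local"}. A score of 0 marks an empty alignment.
#' @examples
#' smith_waterman("ACGT", "ACTT", scoring_scheme())$score
#' @export
smith_waterman <- function(read, region_seq, scoring = scoring_scheme()) {
  stopifnot(nchar(read) > 0, nchar(region_seq) > 0)
  raw <- cpp_local_align(read, region_seq, unclass(scoring), FALSE)
  aln_from_raw(raw, nchar(read), "local")
}

#' Optimal semi-global alignment
#'
#' Aligns the whole read end-to-end against a region with free gaps at the
#' region ends (no soft clipping; \code{aligned_fraction} is always 1).
#'
#' @inheritParams smith_waterman
#' @return An alignment list as in \code{\link{smith_waterman}} with
#'   \code{mode = "semiglobal"}.
#' @examples
#' semi_global("ACGT", "TTACGTTT", scoring_scheme())$ref_start
#' @export
semi_global <- function(read, region_seq, scoring = scoring_scheme()) {
  if (nchar(region_seq) < nchar(read))
    stop("semi-global alignment requires a region at least as long as the read")
  raw <- cpp_semiglobal_align(read, region_seq, unclass(scoring), FALSE)
  aln_from_raw(raw, nchar(read), "semiglobal")
}

#' Alignment qualification test
#'
#' An alignment qualifies when its percent identity reaches the mode-specific
#' threshold (default 90 for local, 65 for semi-global) and at least
#' \code{min_align_frac} of the read's bases are aligned.
#'
#' @param a an alignment list (from \code{\link{smith_waterman}},
#'   \code{\link{semi_global}}, or a row of a batch result coerced to list).
#' @param mode \code{"local"} or \code{"semiglobal"}; defaults to
#'   \code{a$mode}.
#' @param cfg an \code{\link{align_config}}.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
qualify <- function(a, mode = a$mode, cfg = align_config()) {
  thr <- if (identical(mode, "semiglobal")) cfg$min_id_global else cfg$min_id_local
  if (isTRUE(a$empty)) return(FALSE)
  a$identity >= thr - 1e-9 && a$aligned_fraction >= cfg$min_align_frac - 1e-9
}
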