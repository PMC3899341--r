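#' Alignment scoring scheme
#'
#' Affine-gap scoring used by all dynamic-programming kernels. The match score
#' is deliberately smaller in magnitude than the mismatch and gap penalties, so
#' that runs of dense errors drag the local score down and trigger the
#' semi-global rescue path instead of producing heavily clipped local hits.
#' A gap of length \eqn{g} costs \code{gap_open + g * gap_extend}.
#'
#' @param match positive match score (the \eqn{m} used in seed-pair weights).
#' @param mismatch negative mismatch penalty.
#' @param gap_open negative gap-opening penalty.
#' @param gap_extend negative per-base gap-extension penalty.
#' @return A list of class \code{"hybridaln_scoring"}.
#' @examples
#' scoring_scheme()
#' @export
scoring_scheme <- function(match = 1L, mismatch = -3L, gap_open = -5L,
                           gap_extend = -2L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  if (match <= 0L) stop("match score must be positive")
  if (mismatch >= 0L || gap_open >= 0L || gap_extend >= 0L)
    stop("mismatch and gap penalties must be negative")
  if (-mismatch < match)
    stop("the mismatch penalty must be at least as large as the match score")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "hybridaln_scoring")
}

#' Aligner configuration
#'
#' Collects every tunable of the alignment pipelines with its default.
#' Thresholds follow the aligner's qualification rules: a local alignment
#' qualifies at >= 90\% identity, a semi-global alignment at >= 65\% identity,
#' and both additionally require that at least 80\% of the read's bases are
#' aligned (not soft-clipped).
#'
#' @param scoring a \code{\link{scoring_scheme}}.
#' @param min_id_local minimal percent identity for a local alignment.
#' @param min_id_global minimal percent identity for a semi-global alignment.
#' @param min_align_frac minimal aligned base proportion per read.
#' @param min_mem_len minimal MEM seed length; \code{NULL} picks
#'   \code{min(17, ceiling(log4(genome length)) + 3)} when the index is known.
#' @param kmer length of the non-overlapping exact-match k-mer seeds.
#' @param max_occ cap on occurrences reported per seed pattern; beyond it the
#'   first \code{max_occ} positions in suffix-array order are kept.
#' @param max_seeds_extend number of top-ranked seeds extended per stage.
#' @param max_reported maximum number of alignments (or alignment pairs)
#'   reported per read.
#' @param min_seed_score minimal local score for a seed to enter paired-end
#'   seed pairing; \code{NULL} uses \code{30 * match} (30 under the default
#'   scheme, rescaled proportionally for other match scores).
#' @param rescue_min_mapq minimal MAPQ of an anchor alignment used for mate
#'   rescue.
#' @param max_top_seeds cap on high-quality seeds (and rescue anchors) per read.
#' @param insert_nsd half-width of the insert-size window in standard
#'   deviations (window = mean +/- \code{insert_nsd} * sd).
#' @param orientation \code{"fr"} for Illumina paired-end layout, \code{"ff"}
#'   for SOLiD-style mate pairs.
#' @param semiglobal_rescue enable the variable-length-seed semi-global rescue.
#' @param mate_rescue enable paired-end read mate rescuing.
#' @param kmer_reseed enable the k-mer re-seeding stage.
#' @param sample_n number of pairs sampled when estimating the insert size.
#' @return A list of class \code{"hybridaln_config"}.
#' @examples
#' cfg <- align_config(max_reported = 5)
#' cfg$max_reported
#' @export
align_config <- function(scoring = scoring_scheme(),
                         min_id_local = 90, min_id_global = 65,
                         min_align_frac = 0.8,
                         min_mem_len = NULL, kmer = 13L, max_occ = 1000L,
                         max_seeds_extend = 20L, max_reported = 10L,
                         min_seed_score = NULL,
                         rescue_min_mapq = 20L, max_top_seeds = 100L,
                         insert_nsd = 4, orientation = c("fr", "ff"),
                         semiglobal_rescue = TRUE, mate_rescue = TRUE,
                         kmer_reseed = TRUE, sample_n = 10000L) {
  orientation <- match.arg(orientation)
  if (!inherits(scoring, "hybridaln_scoring"))
    scoring <- do.call(scoring_scheme, as.list(scoring))
  stopifnot(min_id_local > 0, min_id_local <= 100,
            min_id_global > 0, min_id_global <= 100,
            min_align_frac > 0, min_align_frac <= 1,
            kmer >= 4, max_occ >= 1, max_seeds_extend >= 1, max_reported >= 1,
            insert_nsd > 0)
  structure(list(
    scoring = scoring,
    min_id_local = min_id_local, min_id_global = min_id_global,
    min_align_frac = min_align_frac,
    min_mem_len = if (is.null(min_mem_len)) NULL else as.integer(min_mem_len),
    kmer = as.integer(kmer), max_occ = as.integer(max_occ),
    max_seeds_extend = as.integer(max_seeds_extend),
    max_reported = as.integer(max_reported),
    min_seed_score = if (is.null(min_seed_score)) NULL else min_seed_score,
    rescue_min_mapq = as.integer(rescue_min_mapq),
    max_top_seeds = as.integer(max_top_seeds),
    insert_nsd = insert_nsd, orientation = orientation,
    semiglobal_rescue = isTRUE(semiglobal_rescue),
    mate_rescue = isTRUE(mate_rescue),
    kmer_reseed = isTRUE(kmer_reseed),
    sample_n = as.integer(sample_n)
  ), class = "hybridaln_config")
}

# Default MEM seed length: 17 for large genomes, ceiling(log4(G)) + 3 for
# smaller ones (short enough that a random seed is still near-unique).
default_min_mem_len <- function(genome_length) {
  min(17L, as.integer(ceiling(log(max(genome_length, 4), 4))) + 3L)
}

# Flatten the user config into the list the C++ engine consumes, resolving
# index-dependent defaults.
resolve_config <- function(cfg, index = NULL, color = FALSE) {
  if (is.null(cfg)) cfg <- align_config()
  if (!inherits(cfg, "hybridaln_config"))
    stop("cfg must be created by align_config()")
  mem <- cfg$min_mem_len
  if (is.null(mem)) {
    if (is.null(index)) mem <- 17L
    else mem <- default_min_mem_len(sum(as.numeric(index$lengths)))
  }
  mss <- cfg$min_seed_score
  if (is.null(mss)) mss <- 30 * cfg$scoring$match
  list(match = cfg$scoring$match, mismatch = cfg$scoring$mismatch,
       gap_open = cfg$scoring$gap_open, gap_extend = cfg$scoring$gap_extend,
       min_id_local = cfg$min_id_local, min_id_global = cfg$min_id_global,
       min_align_frac = cfg$min_align_frac,
       min_mem_len = as.integer(mem), kmer = cfg$kmer, max_occ = cfg$max_occ,
       max_seeds_extend = cfg$max_seeds_extend,
       max_reported = cfg$max_reported, min_seed_score = mss,
       rescue_min_mapq = cfg$rescue_min_mapq,
       max_top_seeds = cfg$max_top_seeds, insert_nsd = cfg$insert_nsd,
       color = isTRUE(color), orient_ff = cfg$orientation == "ff",
       semiglobal_rescue = cfg$semiglobal_rescue,
       mate_rescue = cfg$mate_rescue, kmer_reseed = cfg$kmer_reseed)
}

# Evaluate expr under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}
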