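# SOLiD color-space support: di-base encoding, color-space alignment through
# the standard pipelines, and dynamic-programming translation of qualified
# color alignments back to nucleotides.

#' Di-base color encoding
#'
#' Encodes adjacent base pairs as SOLiD colors: 0 = \{AA,CC,GG,TT\},
#' 1 = \{AC,CA,GT,TG\}, 2 = \{AG,GA,CT,TC\}, 3 = \{AT,TA,CG,GC\} (the XOR of
#' the 2-bit base codes). Any pair containing \code{N} becomes \code{"."}.
#' Because the code is complement-invariant,
#' \code{encode_colors(revcomp(s)) == reverse(encode_colors(s))}.
#'
#' @param bases character vector of nucleotide strings (length >= 2 each).
#' @return Character vector of color strings (length \code{nchar(bases) - 1}).
#' @examples
#' encode_colors("ACGT")  # "131"
#' @export
encode_colors <- function(bases) {
  as.character(cpp_encode_colors(bases))
}

#' @rdname encode_colors
#' @param primer primer base(s) anchoring the first color.
#' @param colors color string(s).
#' @return \code{decode_colors}: the base string implied by walking the color
#'   chain from the primer.
#' @export
decode_colors <- function(primer, colors) {
  as.character(cpp_decode_colors(primer, colors))
}

# project read base positions (0-based, oriented frame) onto reference base
# positions using the color alignment's CIGAR; NA where the base has no
# reference counterpart (insertions / clips). Color t is the junction between
# bases t and t+1, so base 0 sits at the first aligned junction's coordinate
# and base t (t >= 1) one to the right of junction t-1.
project_base_positions <- function(cigar, pos, n_bases) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDS]", cigar))[[1]]
  lens <- as.integer(sub("[MIDS]", "", ops))
  kinds <- sub("[0-9]+", "", ops)
  refcol <- rep(NA_real_, n_bases - 1L)   # junction -> ref junction
  cpos <- 0L; rpos <- pos
  for (k in seq_along(ops)) {
    if (kinds[k] %in% c("M")) {
      idx <- cpos + seq_len(lens[k])
      refcol[idx] <- rpos + seq_len(lens[k]) - 1
      cpos <- cpos + lens[k]; rpos <- rpos + lens[k]
    } else if (kinds[k] %in% c("I", "S")) {
      cpos <- cpos + lens[k]
    } else if (kinds[k] == "D") {
      rpos <- rpos + lens[k]
    }
  }
  base_ref <- rep(NA_real_, n_bases)
  base_ref[1L] <- refcol[1L]
  if (n_bases > 1L) base_ref[-1L] <- refcol + 1
  base_ref
}

#' Translate a color alignment to nucleotides
#'
#' Dynamic programming over the four possible bases per read position: moving
#' from one base to the next costs 1 when the implied di-base color disagrees
#' with the observed color (0 when it agrees or the color is missing,
#' \code{"."}), and emitting a base costs 2 when it differs from the aligned
#' reference base (0 when it matches or no reference base is aligned). The
#' base-mismatch cost exceeds the color-mismatch cost because isolated color
#' discrepancies are far more often sequencing errors than true variants, so
#' a single color error is absorbed as one color correction instead of either
#' cascading through all downstream bases or flipping a base against exact
#' reference guidance. The chain is anchored at the primer base through the
#' read's first color.
#'
#' @param color_read a list or single-row frame with \code{primer} and
#'   \code{colors} (the full CSFASTA color string, first color included).
#' @param ref_bases guidance string: the reference base aligned under each
#'   read base position (oriented frame), \code{N} where none.
#' @param color_alignment the parent color-space alignment (a list with at
#'   least \code{strand}); only its orientation is used here.
#' @return The translated nucleotide string (oriented frame: forward-genome
#'   direction).
#' @export
translate_alignment <- function(color_read, ref_bases, color_alignment) {
  colors_full <- as.character(color_read$colors)
  primer <- as.character(color_read$primer)
  L <- nchar(colors_full)            # number of read bases
  stripped <- substring(colors_full, 2L)
  reverse <- identical(color_alignment$strand, "-") ||
    identical(color_alignment$strand, 1L)
  ec <- strsplit(stripped, "")[[1]]
  if (reverse) ec <- rev(ec)
  guid <- strsplit(ref_bases, "")[[1]]
  stopifnot(length(guid) == L)
  # anchor: expected first base from primer + first color, applied at the
  # oriented position holding the read's first base
  b1 <- substr(decode_colors(primer, substr(colors_full, 1L, 1L)), 1L, 1L)
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  emit <- function(t, b) {
    g <- guid[t]
    if (is.na(g) || g == "N") 0 else 2 * as.numeric(bases[b] != g)
  }
  anchor <- function(t, b) {
    if (b1 == "N") return(0)
    if (!reverse && t == 1L) return(as.numeric(bases[b] != b1))
    if (reverse && t == L) return(as.numeric(comp[bases[b]] != b1))
    0
  }
  cost <- vapply(1:4, function(b) emit(1L, b) + anchor(1L, b), 0)
  back <- matrix(0L, nrow = max(L - 1L, 0L), ncol = 4L)
  for (t in seq_len(L - 1L)) {
    newcost <- numeric(4L)
    for (b in 1:4) {
      tc <- vapply(1:4, function(pb) {
        obs <- ec[t]
        tcost <- if (obs == ".") 0 else as.numeric(bitwXor(pb - 1L, b - 1L) != (as.integer(obs)))
        cost[pb] + tcost
      }, 0)
      pb <- which.min(tc)            # ties: lower base index
      back[t, b] <- pb
      newcost[b] <- tc[pb] + emit(t + 1L, b) + anchor(t + 1L, b)
    }
    cost <- newcost
  }
  b <- which.min(cost)
  out <- integer(L); out[L] <- b
  for (t in rev(seq_len(L - 1L))) out[t] <- back[t, out[t + 1L]]
  paste(bases[out], collapse = "")
}

translate_and_realign <- function(rows_df, creads, base_index, cfg) {
  if (nrow(rows_df) == 0L) {
    rows_df$translated <- character(0)
    return(rows_df)
  }
  scoring <- unclass(cfg$scoring)
  keep <- logical(nrow(rows_df))
  for (i in seq_len(nrow(rows_df))) {
    r <- rows_df[i, ]
    cr <- creads[r$read, ]
    L <- nchar(cr$colors)
    ci <- match(r$contig, base_index$names)
    cs <- base_index$starts[ci]; cl <- base_index$lengths[ci]
    bp <- project_base_positions(r$cigar, r$pos, L)
    guid <- vapply(bp, function(p) {
      if (is.na(p) || p < 0 || p >= cl) "N"
      else cpp_extract_text(base_index$ptr, cs + p, 1L, FALSE)
    }, "")
    tr <- translate_alignment(cr, paste(guid, collapse = ""),
                              list(strand = r$strand))
    mg <- ceiling(0.1 * L) + 10
    rs <- max(r$pos - mg, 0); re <- min(r$pos + L + mg, cl)
    region <- cpp_extract_text(base_index$ptr, cs + rs, as.integer(re - rs),
                               FALSE)
    raw <- if (r$mode == "local")
      cpp_local_align(tr, region, scoring, FALSE)
    else cpp_semiglobal_align(tr, region, scoring, FALSE)
    a <- aln_from_raw(raw, L, if (r$mode == "local") "local" else "semiglobal")
    if (!qualify(a, a$mode, cfg)) next
    keep[i] <- TRUE
    rows_df$pos[i] <- rs + a$ref_start
    rows_df$score[i] <- a$score
    rows_df$cigar[i] <- a$cigar
    rows_df$nm[i] <- a$edit_distance
    rows_df$identity[i] <- a$identity
    rows_df$aligned_frac[i] <- a$aligned_fraction
    rows_df$translated[i] <- tr
  }
  out <- rows_df[keep, , drop = FALSE]
  # re-rank within read by base-space score, preserving pair ranks for PE
  if (nrow(out) && all(out$end == 0L)) {
    ord <- order(out$read, -out$score, out$pos)
    out <- out[ord, , drop = FALSE]
    out$rank <- stats::ave(seq_len(nrow(out)), out$read, FUN = seq_along)
  }
  rownames(out) <- NULL
  out
}

#' Align color-space reads
#'
#' Runs the single-end (or paired-end) pipeline in color space against the
#' color index, translates each qualified color alignment to nucleotides
#' under reference guidance, and re-aligns the translated sequence to the
#' base-space genome with the same mode (local stays local, semi-global stays
#' semi-global). Reported alignments are base-space; the translated sequence
#' is returned in column \code{translated}.
#'
#' @param base_index base-space \code{"hybridaln_index"}.
#' @param color_index matching color-space index from
#'   \code{\link{build_color_index}}.
#' @param creads color read frame (\code{id}, \code{primer}, \code{colors}).
#' @param cfg an \code{\link{align_config}}.
#' @return Alignment \code{data.frame} as in \code{\link{align_reads}} plus
#'   \code{translated}.
#' @export
align_color_reads <- function(base_index, color_index, creads,
                              cfg = align_config()) {
  stopifnot(inherits(base_index, "hybridaln_index"),
            inherits(color_index, "hybridaln_index"), color_index$color)
  stripped <- substring(creads$colors, 2L)
  ecfg <- resolve_config(cfg, color_index, color = TRUE)
  rows <- cpp_align_se_batch(color_index$ptr, stripped, ecfg)
  df <- engine_rows_to_df(rows, color_index, creads$id)
  df$translated <- rep(NA_character_, nrow(df))
  translate_and_realign(df, creads, base_index, cfg)
}

#' @rdname align_color_reads
#' @param creads1,creads2 color read frames for the two mate files.
#' @param insert_mean,insert_sd insert-size distribution (estimated from a
#'   color-space single-end sample when \code{NULL}).
#' @export
align_color_pairs <- function(base_index, color_index, creads1, creads2,
                              cfg = align_config(orientation = "ff"),
                              insert_mean = NULL, insert_sd = NULL) {
  stopifnot(inherits(color_index, "hybridaln_index"), color_index$color)
  s1 <- substring(creads1$colors, 2L)
  s2 <- substring(creads2$colors, 2L)
  if (is.null(insert_mean) || is.null(insert_sd)) {
    est <- estimate_insert_size(color_index, s1, s2, cfg)
    # color coordinates equal base coordinates of the left junction base;
    # the color read is one symbol shorter than the base read
    insert_mean <- est[["mean"]] + 1; insert_sd <- est[["sd"]]
  }
  ecfg <- resolve_config(cfg, color_index, color = TRUE)
  rows <- cpp_align_pe_batch(color_index$ptr, s1, s2, insert_mean, insert_sd,
                             ecfg)
  ids <- sub("/[12]$", "", creads1$id)
  df <- engine_rows_to_df(rows, color_index, ids)
  df$translated <- rep(NA_character_, nrow(df))
  out1 <- translate_and_realign(df[df$end == 1L, , drop = FALSE], creads1,
                                base_index, cfg)
  out2 <- translate_and_realign(df[df$end == 2L, , drop = FALSE], creads2,
                                base_index, cfg)
  out <- rbind(out1, out2)
  out <- out[order(out$read, out$rank, out$end), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "insert") <- c(mean = insert_mean, sd = insert_sd)
  out
}
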