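# MAPQ assignment and SAM emission.

#' Mapping quality from the alignment candidate list
#'
#' With two or more co-optimal candidates the placement is ambiguous and MAPQ
#' is 0; a unique alignment without any runner-up gets the cap of 60;
#' otherwise MAPQ scales with the relative score gap,
#' \code{round(60 * (best - second) / best)}, clamped to [0, 60]. All
#' alignments reported for one read share the primary's MAPQ.
#'
#' @param best best alignment (list with \code{$score}) or its score.
#' @param second runner-up alignment or score, or \code{NULL} when absent.
#' @param n_best number of co-optimal candidates.
#' @return Integer MAPQ in [0, 60].
#' @examples
#' compute_mapq(100, 50, 1)  # 30
#' compute_mapq(100, NULL, 1)  # 60
#' compute_mapq(100, 100, 2)  # 0
#' @export
compute_mapq <- function(best, second = NULL, n_best = 1L) {
  s1 <- if (is.list(best)) best$score else best
  has2 <- !is.null(second)
  s2 <- if (!has2) 0L else if (is.list(second)) second$score else second
  cpp_compute_mapq(as.integer(s1), as.integer(s2), as.integer(n_best), has2)
}

sam_escape_rname <- function(x) gsub("[ \t]", "_", x)

#' Write alignments as SAM
#'
#' Emits a valid SAM file: \code{@HD}/\code{@SQ}/\code{@PG} header, 1-based
#' positions, FLAG bits for pairing / strand / first-second-in-pair /
#' secondary, \code{NM} and \code{AS} tags, and unaligned reads as records
#' with flag 0x4. Alignments after the first per read are flagged secondary
#' (0x100). Reverse-strand records carry the reverse-complemented sequence
#' and reversed qualities, as the SAM specification requires.
#'
#' @param alignments alignment \code{data.frame} from \code{\link{align_reads}}
#'   or \code{\link{align_pairs}}.
#' @param reads the reads that were aligned: a read frame (or character
#'   vector) for single-end, or a list of two read frames for paired-end.
#' @param index the \code{"hybridaln_index"} used (for \code{@SQ} lines).
#' @param file output path or connection.
#' @param program_args command line recorded in \code{@PG} (optional).
#' @return Invisibly, the number of records written.
#' @export
write_sam <- function(alignments, reads, index, file,
                      program_args = character()) {
  paired <- is.list(reads) && !is.data.frame(reads) && length(reads) == 2L
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", sam_escape_rname(index$names),
                   index$lengths),
           paste0("@PG\tID:hybridaln\tPN:hybridaln\tVN:",
                  as.character(utils::packageVersion("hybridaln")),
                  if (length(program_args))
                    paste0("\tCL:", paste(program_args, collapse = " "))
                  else ""))
  aln <- alignments
  recs <- if (paired) {
    r1 <- reads_df(reads[[1]]); r2 <- reads_df(reads[[2]])
    sam_records_pe(aln, r1, r2)
  } else {
    sam_records_se(aln, reads_df(reads))
  }
  con <- if (inherits(file, "connection")) file else base::file(file, "w")
  if (!inherits(file, "connection")) on.exit(close(con))
  writeLines(c(hdr, recs), con)
  invisible(length(recs))
}

revqual <- function(q) vapply(strsplit(q, ""), function(s)
  paste(rev(s), collapse = ""), "", USE.NAMES = FALSE)

sam_one_end <- function(a, seqs, quals, flag_base) {
  rev <- a$strand == "-"
  flag <- flag_base + ifelse(rev, 16L, 0L) + ifelse(a$rank > 1L, 256L, 0L)
  seq <- ifelse(rev, revcomp(seqs), seqs)
  qual <- ifelse(rev, revqual(quals), quals)
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d\tAS:i:%d",
          a$qname, flag, sam_escape_rname(a$contig), as.integer(a$pos) + 1L,
          a$mapq, a$cigar, seq, qual, a$nm, a$score)
}

sam_records_se <- function(aln, rd) {
  ids <- sub("/[12]$", "", rd$id)
  out <- character(0)
  if (nrow(aln)) {
    i <- aln$read
    out <- sam_one_end(aln, rd$seq[i], rd$qual[i], 0L)
  }
  un <- setdiff(seq_len(nrow(rd)), unique(aln$read))
  if (length(un))
    out <- c(out, sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s",
                          ids[un], rd$seq[un], rd$qual[un]))
  out
}

sam_records_pe <- function(aln, r1, r2) {
  ids <- sub("/[12]$", "", r1$id)
  n <- nrow(r1)
  out <- character(0)
  if (nrow(aln)) {
    key <- paste(aln$read, aln$rank)
    e1 <- aln[aln$end == 1L, , drop = FALSE]
    e2 <- aln[aln$end == 2L, , drop = FALSE]
    m12 <- match(paste(e1$read, e1$rank), paste(e2$read, e2$rank))
    m21 <- match(paste(e2$read, e2$rank), paste(e1$read, e1$rank))
    mk <- function(a, mates, rd, first) {
      base <- 1L + ifelse(first, 64L, 128L)
      hasmate <- !is.na(mates$row)
      flag <- base +
        ifelse(a$proper & hasmate, 2L, 0L) +
        ifelse(hasmate, ifelse(mates$strand == "-", 32L, 0L), 8L) +
        ifelse(a$strand == "-", 16L, 0L) +
        ifelse(a$rank > 1L, 256L, 0L)
      rnext <- ifelse(hasmate, ifelse(mates$contig == a$contig, "=",
                                      sam_escape_rname(mates$contig)), "*")
      pnext <- ifelse(hasmate, as.integer(mates$pos) + 1L, 0L)
      span_a <- cigar_ref_span(a$cigar)
      span_m <- ifelse(hasmate, cigar_ref_span(mates$cigar), 0)
      tlen <- ifelse(hasmate & mates$contig == a$contig,
                     ifelse(a$pos <= mates$pos,
                            (mates$pos + span_m) - a$pos,
                            -((a$pos + span_a) - mates$pos)),
                     0)
      i <- a$read
      rev <- a$strand == "-"
      seq <- ifelse(rev, revcomp(rd$seq[i]), rd$seq[i])
      qual <- ifelse(rev, revqual(rd$qual[i]), rd$qual[i])
      sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s\tNM:i:%d\tAS:i:%d",
              a$qname, flag, sam_escape_rname(a$contig),
              as.integer(a$pos) + 1L, a$mapq, a$cigar, rnext, pnext,
              as.integer(round(tlen)), seq, qual, a$nm, a$score)
    }
    mate_info <- function(other, m) {
      data.frame(row = m,
                 contig = other$contig[m], pos = other$pos[m],
                 strand = other$strand[m], cigar = other$cigar[m],
                 stringsAsFactors = FALSE)
    }
    if (nrow(e1)) out <- c(out, mk(e1, mate_info(e2, m12), r1, TRUE))
    if (nrow(e2)) out <- c(out, mk(e2, mate_info(e1, m21), r2, FALSE))
  }
  # unmapped records (per end), with mate info from the other end's primary
  prim <- aln[aln$rank == 1L, , drop = FALSE]
  for (endi in 1:2) {
    rd <- if (endi == 1L) r1 else r2
    mapped <- unique(aln$read[aln$end == endi])
    un <- setdiff(seq_len(n), mapped)
    if (!length(un)) next
    op <- prim[prim$end == (3L - endi), , drop = FALSE]
    m <- match(un, op$read)
    hasmate <- !is.na(m)
    flag <- 1L + 4L + ifelse(endi == 1L, 64L, 128L) +
      ifelse(hasmate, ifelse(op$strand[m] == "-", 32L, 0L), 8L)
    rname <- ifelse(hasmate, sam_escape_rname(op$contig[m]), "*")
    pos <- ifelse(hasmate, as.integer(op$pos[m]) + 1L, 0L)
    out <- c(out, sprintf("%s\t%d\t%s\t%d\t0\t*\t%s\t%d\t0\t%s\t%s",
                          ids[un], flag, rname, pos,
                          ifelse(hasmate, "=", "*"), pos,
                          rd$seq[un], rd$qual[un]))
  }
  out
}
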