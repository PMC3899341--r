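# Sequence file IO. FASTA/FASTQ parsing is delegated to Biostrings (which
# auto-detects gzip and handles wrapped FASTA); CSFASTA(+QUAL) has no
# installed reader and is parsed here directly.

read_fasta_seqs <- function(path) {
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stop("failed to parse FASTA '", path,
                                         "': ", conditionMessage(e)))
  if (length(x) == 0L) stop("empty FASTA: ", path)
  setNames(as.character(x), sub("\\s.*", "", names(x)))
}

detect_format <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (!length(first)) stop("empty sequence file: ", path)
  if (startsWith(first, ">")) "fasta"
  else if (startsWith(first, "@")) "fastq"
  else stop("unrecognized sequence format in ", path,
            " (expected FASTA or FASTQ)")
}

#' Read sequences from FASTA or FASTQ
#'
#' Format is auto-detected from the first record marker; gzip compression is
#' auto-detected from the file content. FASTQ records are validated
#' (sequence/quality length agreement, truncation).
#'
#' @param path input file.
#' @return \code{data.frame} with \code{id}, \code{seq} and \code{qual}
#'   (\code{NA} for FASTA input).
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fmt <- detect_format(path)
  if (fmt == "fasta") {
    s <- read_fasta_seqs(path)
    return(data.frame(id = names(s), seq = unname(s), qual = NA_character_,
                      stringsAsFactors = FALSE))
  }
  out <- tryCatch({
    # Biostrings warns about dropping its own metadata columns here
    x <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    data.frame(id = sub("\\s.*", "", names(x)),
               seq = as.character(x),
               qual = as.character(Biostrings::quality(x)),
               stringsAsFactors = FALSE)
  }, error = function(e) stop("failed to parse FASTQ '", path, "': ",
                              conditionMessage(e)))
  bad <- nchar(out$seq) != nchar(out$qual)
  if (any(bad))
    stop("FASTQ record ", which(bad)[1], " ('", out$id[which(bad)[1]],
         "') in '", path, "' has mismatched sequence/quality lengths")
  out
}

#' Read synchronized read pairs from two files
#'
#' @param path1,path2 the two mate files (FASTA/FASTQ, optionally gzipped).
#' @return List with \code{reads1}, \code{reads2} (read frames with
#'   normalized shared ids: trailing \code{/1}, \code{/2} stripped).
#' @export
read_paired <- function(path1, path2) {
  r1 <- read_sequences(path1)
  r2 <- read_sequences(path2)
  if (nrow(r1) != nrow(r2))
    stop("paired files differ in record count (", nrow(r1), " vs ",
         nrow(r2), ") at record ", min(nrow(r1), nrow(r2)) + 1L)
  base1 <- sub("/[12]$", "", r1$id)
  base2 <- sub("/[12]$", "", r2$id)
  if (!all(base1 == base2))
    stop("read ids diverge at record ", which(base1 != base2)[1])
  list(reads1 = r1, reads2 = r2, ids = base1)
}

open_out <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
}

#' Write sequences as FASTA / FASTQ
#'
#' @param seqs named character vector (FASTA) or read frame with \code{id},
#'   \code{seq}, \code{qual} (FASTQ).
#' @param path output path; \code{.gz} suffix enables gzip compression.
#' @param width FASTA line width.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- open_out(path)
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' @rdname write_fasta
#' @param reads read frame with \code{id}, \code{seq}, \code{qual}.
#' @export
write_fastq <- function(reads, path) {
  con <- open_out(path)
  on.exit(close(con))
  qual <- if (is.null(reads$qual)) strrep("I", nchar(reads$seq)) else reads$qual
  writeLines(as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual)),
             con)
  invisible(path)
}

#' Read / write CSFASTA color-space reads
#'
#' CSFASTA records hold a primer base followed by the color string; an
#' optional QUAL file carries space-separated PHRED scores per color.
#'
#' @param path CSFASTA file (optionally gzipped).
#' @param qual_path optional QUAL file.
#' @return \code{data.frame} with \code{id}, \code{primer}, \code{colors} and
#'   \code{qual}.
#' @export
read_csfasta <- function(path, qual_path = NULL) {
  ln <- readLines(gz <- gzfile(path, "rt")); close(gz)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  hd <- startsWith(ln, ">")
  if (!any(hd)) stop("no CSFASTA records in ", path)
  ids <- sub("^>", "", ln[hd])
  seqs <- ln[!hd]
  if (length(ids) != length(seqs))
    stop("malformed CSFASTA (header/sequence count mismatch) in ", path)
  if (any(!grepl("^[ACGTacgt][0123.]+$", seqs)))
    stop("malformed CSFASTA record (expected primer base + colors) in ", path)
  out <- data.frame(id = ids, primer = toupper(substr(seqs, 1L, 1L)),
                    colors = substring(seqs, 2L), stringsAsFactors = FALSE)
  out$qual <- strrep("I", nchar(out$colors))
  if (!is.null(qual_path)) {
    qn <- readLines(gz <- gzfile(qual_path, "rt")); close(gz)
    qn <- qn[!startsWith(qn, "#") & nzchar(qn)]
    qv <- qn[!startsWith(qn, ">")]
    phred <- lapply(strsplit(qv, "[ \t]+"), as.integer)
    out$qual <- vapply(phred, function(p)
      intToUtf8(pmin(pmax(p, 0L), 60L) + 33L), "")
  }
  out
}

#' @rdname read_csfasta
#' @param reads color read frame (\code{id}, \code{primer}, \code{colors}).
#' @export
write_csfasta <- function(reads, path) {
  con <- open_out(path)
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0(">", reads$id),
                             paste0(reads$primer, reads$colors))), con)
  invisible(path)
}

#' Write a truth table as TSV
#'
#' @param truth truth \code{data.frame} from the simulators.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
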