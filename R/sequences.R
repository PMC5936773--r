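#' Sequence records
#'
#' `seq_record()` builds the light-weight container used throughout the
#' package for reads, merged contigs, OTU centroids and protein references.
#' A record is a named list with class `"seq_record"` holding an id, a free
#' description, an alphabet tag, the residue string (upper case) and an
#' optional integer vector of per-residue Phred quality scores.
#'
#' @param id record identifier (first whitespace-delimited token of a FASTA
#'   header).
#' @param residues residue string; case is normalised to upper.
#' @param alphabet `"nucleotide"` or `"amino-acid"`.
#' @param description free-text remainder of the header, may be `""`.
#' @param quality optional integer vector of Phred scores, same length as
#'   `residues`.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, residues, alphabet = c("nucleotide", "amino-acid"),
                       description = "", quality = NULL) {
  alphabet <- match.arg(alphabet)
  residues <- toupper(as.character(residues))
  if (!nzchar(residues)) stop("seq_record: residues must be non-empty")
  check_alphabet(residues, alphabet)
  if (!is.null(quality)) {
    quality <- as.integer(quality)
    if (length(quality) != nchar(residues))
      stop("seq_record: quality length (", length(quality),
           ") != residue length (", nchar(residues), ")")
    if (any(quality < 0L)) stop("seq_record: negative Phred score")
  }
  structure(list(id = as.character(id), description = as.character(description),
                 alphabet = alphabet, residues = residues, quality = quality),
            class = "seq_record")
}

IUPAC_NT <- c("A", "C", "G", "T", "U", "N", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V")
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

check_alphabet <- function(residues, alphabet) {
  chars <- unique(strsplit(residues, "")[[1]])
  ok <- if (alphabet == "nucleotide") c(IUPAC_NT, "-", ".") else
    c(AA20, "X", "*", "-", ".")
  bad <- setdiff(chars, ok)
  if (length(bad))
    stop("invalid ", alphabet, " residue(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' @export
print.seq_record <- function(x, ...) {
  n <- nchar(x$residues)
  head <- if (n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(sprintf("<seq_record %s> %s, %d residues%s\n  %s\n", x$id, x$alphabet, n,
              if (is.null(x$quality)) "" else " (+quality)", head))
  invisible(x)
}

#' Reverse complement of a nucleotide string
#'
#' Handles the full IUPAC nucleotide code (including ambiguity codes).
#'
#' @param x a character scalar of nucleotides.
#' @return the reverse-complemented string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

reverse_record <- function(rec) {
  out <- rec
  out$residues <- revcomp(rec$residues)
  if (!is.null(rec$quality)) out$quality <- rev(rec$quality)
  out
}

#' Read and write FASTA
#'
#' Minimal strict FASTA I/O on `seq_record` lists. Wrapped sequence lines
#' are concatenated, case is normalised to upper, and the first
#' whitespace-delimited header token becomes the record id. Malformed input
#' (sequence data before the first header, a header with an empty body)
#' raises an error naming the offending line. gzip-compressed files are
#' read transparently.
#'
#' @param path file path.
#' @param alphabet alphabet of the records in the file.
#' @return `read_fasta()`: a list of [seq_record()]s (empty list for an
#'   empty file). `write_fasta()`: the path, invisibly.
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "amino-acid")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) <= length(lines)]
  recs <- list()
  id <- NULL; desc <- ""; chunks <- character(); header_line <- 0L
  flush <- function() {
    if (is.null(id)) return(invisible(NULL))
    body <- paste(chunks, collapse = "")
    if (!nzchar(body))
      stop("FASTA parse error at line ", header_line, ": empty sequence body")
    recs[[length(recs) + 1L]] <<- seq_record(id, body, alphabet, desc)
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, ">")) {
      flush()
      h <- sub("^>", "", ln)
      id <- sub("\\s.*$", "", h)
      desc <- if (grepl("\\s", h)) sub("^\\S+\\s+", "", h) else ""
      if (!nzchar(id))
        stop("FASTA parse error at line ", i, ": empty header")
      chunks <- character(); header_line <- i
    } else if (grepl("^\\s*$", ln)) {
      next
    } else {
      if (is.null(id))
        stop("FASTA parse error at line ", i, ": sequence data before header")
      chunks <- c(chunks, gsub("\\s", "", ln))
    }
  }
  flush()
  recs
}

#' @rdname read_fasta
#' @param records list of [seq_record()]s.
#' @param width line-wrap width for sequence lines.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    header <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    writeLines(paste0(">", header), con)
    s <- r$residues
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read and write FASTQ (Phred+33)
#'
#' Strict 4-line-per-record FASTQ. Quality strings are decoded to integer
#' Phred scores; a length mismatch between sequence and quality, or a
#' truncated final record, is an error naming the line.
#'
#' @inheritParams read_fasta
#' @return `read_fastq()`: a list of [seq_record()]s carrying quality.
#' @export
read_fastq <- function(path, alphabet = "nucleotide") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (!length(lines)) return(list())
  if (length(lines) %% 4L != 0L)
    stop("FASTQ parse error: truncated record near line ", length(lines))
  n <- length(lines) %/% 4L
  recs <- vector("list", n)
  for (k in seq_len(n)) {
    i <- (k - 1L) * 4L + 1L
    if (!startsWith(lines[i], "@"))
      stop("FASTQ parse error at line ", i, ": expected '@' header")
    if (!startsWith(lines[i + 2L], "+"))
      stop("FASTQ parse error at line ", i + 2L, ": expected '+' separator")
    seq <- lines[i + 1L]; qual <- lines[i + 3L]
    if (nchar(seq) != nchar(qual))
      stop("FASTQ parse error at line ", i + 3L,
           ": quality length != sequence length")
    h <- sub("^@", "", lines[i])
    id <- sub("\\s.*$", "", h)
    desc <- if (grepl("\\s", h)) sub("^\\S+\\s+", "", h) else ""
    recs[[k]] <- seq_record(id, seq, alphabet, desc,
                            quality = utf8ToInt(qual) - 33L)
  }
  recs
}

#' @rdname read_fastq
#' @param records list of [seq_record()]s with quality.
#' @export
write_fastq <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    if (is.null(r$quality)) stop("write_fastq: record ", r$id, " has no quality")
    header <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    writeLines(c(paste0("@", header), r$residues, "+",
                 intToUtf8(r$quality + 33L)), con)
  }
  invisible(path)
}

residue_vec <- function(rec) strsplit(rec$residues, "")[[1]]
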