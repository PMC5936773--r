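# Translation and frameshift-aware protein-guided alignment.

codon_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- Biostrings::GENETIC_CODE
    cache
  }
})

#' Translate a nucleotide string
#'
#' Standard genetic code, one letter per complete codon (the incomplete
#' tail is dropped); stop codons are rendered `*`; any codon containing a
#' non-ACGT base translates to `X`.
#'
#' @param nt nucleotide string or [seq_record()].
#' @param frame 0, 1 or 2 (bases skipped at the 5' end).
#' @return amino-acid string.
#' @export
translate_nt <- function(nt, frame = 0L) {
  s <- toupper(as_seqchar(nt)$residues)
  s <- chartr("U", "T", s)
  if (nchar(s) < frame + 3L) stop("translate_nt: sequence shorter than one codon")
  s <- substr(s, frame + 1L, nchar(s))
  n <- nchar(s) %/% 3L
  if (n == 0L) return("")
  starts <- (seq_len(n) - 1L) * 3L + 1L
  codons <- substring(s, starts, starts + 2L)
  aa <- codon_table()[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# integer codon -> substitution-alphabet index map for the C++ kernel
codon_aa_map <- function(alpha) {
  bases <- c("A", "C", "G", "T")
  out <- integer(64)
  for (a in 0:3) for (b in 0:3) for (c in 0:3) {
    codon <- paste0(bases[a + 1], bases[b + 1], bases[c + 1])
    aa <- codon_table()[[codon]]
    idx <- match(aa, alpha)
    out[16 * a + 4 * b + c + 1] <- (if (is.na(idx)) match("X", alpha) else idx) - 1L
  }
  out
}

#' Frameshift-aware alignment of a nucleotide query to protein references
#'
#' Dynamic program in which each reference residue may consume 2 or 4
#' (one-base frameshift) or 1 or 5 (two-base frameshift) query
#' nucleotides instead of a codon, at a penalty per unit of shift;
#' damaged codons are repaired against the reference (best completion or
#' base deletion under BLOSUM62), substitutions are scored with BLOSUM62
#' and gaps are affine. The highest-scoring reference wins, ties broken
#' by lexicographic reference id. Results failing the identity or
#' aligned-length floors are flagged `no_frame` (and reported, not
#' dropped).
#'
#' @param nt_query nucleotide [seq_record()] or string.
#' @param references list of amino-acid [seq_record()]s.
#' @param frameshift_penalty score penalty per unit of frameshift
#'   (default 20, half-bits).
#' @param gap_open,gap_ext affine gap penalties (default 11 / 1; a gap of
#'   length k costs `gap_open + k * gap_ext`).
#' @param min_identity,min_aligned acceptance floors (defaults 0.4 and 80
#'   aligned reference residues).
#' @param max_shift largest |frameshift| considered per reference residue
#'   (default 2).
#' @return A `frame_alignment`: `query_id`, `reference_id`,
#'   `corrected_aa` (gap-free), `identity`, `score`, `frameshifts`
#'   (data.frame offset/shift, offsets strictly increasing), `no_frame`
#'   flag, and `has_stop`.
#' @export
framebot_align <- function(nt_query, references, frameshift_penalty = 20,
                           gap_open = 11, gap_ext = 1, min_identity = 0.4,
                           min_aligned = 80L, max_shift = 2L) {
  if (!length(references)) stop("framebot_align: empty reference set")
  q <- as_seqchar(nt_query)
  if (nchar(q$residues) < 30L)
    stop("framebot_align: query shorter than 30 nt")
  B <- blosum62()
  alpha <- rownames(B)
  caa <- codon_aa_map(alpha)
  xa <- match("X", alpha) - 1L
  qs <- chartr("U", "T", toupper(q$residues))
  qv <- match(strsplit(qs, "")[[1]], c("A", "C", "G", "T")) - 1L
  qv[is.na(qv)] <- -1L

  best <- NULL
  ord <- order(vapply(references, `[[`, "", "id"))
  for (ref in references[ord]) {
    rv <- match(strsplit(toupper(ref$residues), "")[[1]], alpha) - 1L
    if (anyNA(rv)) stop("framebot_align: reference ", ref$id,
                        " has residues outside the substitution alphabet")
    r <- .framebot_cpp(qv, rv, caa, xa, B, frameshift_penalty,
                       gap_open, gap_ext, max_shift)
    if (is.null(best) || r$score > best$res$score)
      best <- list(ref = ref, res = r)
  }
  res <- best$res; ref <- best$ref
  rchars <- strsplit(toupper(ref$residues), "")[[1]]
  emit <- res$aa >= 0
  corrected <- paste(alpha[res$aa[emit] + 1L], collapse = "")
  iscol <- res$type %in% c(0L, 1L, 2L)
  matches <- sum(res$type == 0L &
                 alpha[res$aa + 1L] == rchars[pmax(res$ref, 1L)],
                 na.rm = TRUE)
  identity <- matches / sum(iscol)
  aligned_ref <- sum(res$type %in% c(0L, 2L))
  fs <- res$shift != 0L & res$type == 0L
  # shift = extra (+) or missing (-) bases in the consumed chunk
  frameshifts <- data.frame(offset = res$qpos[fs],
                            shift = res$shift[fs])
  frameshifts <- frameshifts[order(frameshifts$offset), , drop = FALSE]
  structure(list(
    query_id = q$id, reference_id = ref$id, corrected_aa = corrected,
    identity = identity, score = res$score, frameshifts = frameshifts,
    no_frame = identity < min_identity || aligned_ref < min_aligned,
    has_stop = grepl("*", corrected, fixed = TRUE)),
    class = "frame_alignment")
}

#' @export
print.frame_alignment <- function(x, ...) {
  cat(sprintf(
    "<frame_alignment> %s vs %s: score %.1f, identity %.3f, %d frameshift(s)%s\n",
    x$query_id, x$reference_id, x$score, x$identity, nrow(x$frameshifts),
    if (x$no_frame) " [no_frame]" else ""))
  invisible(x)
}
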