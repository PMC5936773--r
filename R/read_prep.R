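#' Merge a read pair into a contig
#'
#' The reverse read is reverse-complemented, then every overlap length
#' `o >= min_overlap` (up to full containment) between the forward read's
#' suffix and the reverse-complemented read's prefix is examined. Among
#' candidates whose mismatch fraction is at most `max_mismatch_frac`, the
#' one maximising `overlap_length - 4 * mismatches` is chosen; ties go to
#' the longest overlap, making the merge deterministic. At disagreeing
#' overlap positions the higher-quality base wins (tie: forward base);
#' merged quality is the per-position maximum of the two reads.
#'
#' @param fwd,rev forward and reverse [seq_record()]s with quality.
#' @param min_overlap minimum overlap length (default 10).
#' @param max_mismatch_frac maximum fraction of mismatching overlap
#'   positions (default 0.25).
#' @return A `merge_result` list: `merged` (a [seq_record()] or `NULL`),
#'   `overlap_length`, `overlap_mismatches`, and `status` (one of
#'   `"merged"`, `"no_overlap"`, `"too_many_mismatches"`).
#' @export
merge_pair <- function(fwd, rev, min_overlap = 10L, max_mismatch_frac = 0.25) {
  if (is.null(fwd$quality) || is.null(rev$quality))
    stop("merge_pair: both reads need quality scores")
  rc <- reverse_record(rev)
  f <- residue_vec(fwd); r <- residue_vec(rc)
  fq <- fwd$quality; rq <- rc$quality
  nf <- length(f); nr <- length(r)
  best <- NULL; best_score <- -Inf; any_candidate <- FALSE
  rejected_mm <- FALSE
  omax <- min(nf, nr)
  omin <- max(min_overlap, 1L)
  overlaps <- if (omax >= omin) seq(omax, omin) else integer()
  for (o in overlaps) {
    fo <- f[(nf - o + 1L):nf]
    ro <- r[1:o]
    mm <- sum(fo != ro)
    any_candidate <- TRUE
    if (mm / o > max_mismatch_frac) { rejected_mm <- TRUE; next }
    score <- o - 4 * mm
    if (score > best_score) {  # first hit at a score is the longest overlap
      best_score <- score
      best <- list(o = o, mm = mm)
    }
  }
  if (is.null(best)) {
    status <- if (any_candidate && rejected_mm) "too_many_mismatches" else "no_overlap"
    return(structure(list(merged = NULL, overlap_length = 0L,
                          overlap_mismatches = 0L, status = status),
                     class = "merge_result"))
  }
  o <- best$o
  head_res <- if (o < nf) f[1:(nf - o)] else character()
  head_q <- if (o < nf) fq[1:(nf - o)] else integer()
  fo_idx <- (nf - o + 1L):nf
  ov_res <- character(o); ov_q <- integer(o)
  for (k in seq_len(o)) {
    fb <- f[fo_idx[k]]; rb <- r[k]
    qf <- fq[fo_idx[k]]; qr <- rq[k]
    if (fb == rb) {
      ov_res[k] <- fb; ov_q[k] <- max(qf, qr)
    } else if (qr > qf) {
      ov_res[k] <- rb; ov_q[k] <- qr
    } else {
      ov_res[k] <- fb; ov_q[k] <- qf
    }
  }
  tail_res <- if (o < nr) r[(o + 1L):nr] else character()
  tail_q <- if (o < nr) rq[(o + 1L):nr] else integer()
  merged <- seq_record(fwd$id, paste(c(head_res, ov_res, tail_res), collapse = ""),
                       "nucleotide", quality = c(head_q, ov_q, tail_q))
  structure(list(merged = merged, overlap_length = o,
                 overlap_mismatches = best$mm, status = "merged"),
            class = "merge_result")
}

#' Trim amplification primers from a merged contig
#'
#' Locates the forward primer at the 5' terminus and the reverse primer at
#' the 3' terminus (compared on the reverse complement, per the primer
#' orientation convention), allowing up to `max_mismatches` each, removes
#' both, and normalises the insert to the forward strand. If the primers
#' are not found, the reverse-complemented contig is tried before
#' rejecting.
#'
#' @param contig merged [seq_record()].
#' @param fwd,rev [primer_spec()]s for the pair.
#' @param max_mismatches tolerated mismatches per primer (default 2).
#' @return list with `status` (`"trimmed"` or `"rejected"`), `insert`
#'   (a [seq_record()] or `NULL`), `orientation` (`"forward"` or
#'   `"reverse"`), and `reason` when rejected.
#' @export
trim_primers <- function(contig, fwd, rev, max_mismatches = 2L) {
  lf <- nchar(fwd$iupac); lr <- nchar(rev$iupac)
  n <- nchar(contig$residues)
  if (n <= lf + lr)
    return(list(status = "rejected", insert = NULL, orientation = NA_character_,
                reason = "contig shorter than combined primer length"))
  try_orient <- function(rec, orientation) {
    s <- rec$residues
    m5 <- count_mismatches(fwd, substr(s, 1L, lf))
    m3 <- count_mismatches(rev, revcomp(substr(s, n - lr + 1L, n)))
    if (m5 <= max_mismatches && m3 <= max_mismatches) {
      q <- if (!is.null(rec$quality)) rec$quality[(lf + 1L):(n - lr)] else NULL
      list(status = "trimmed",
           insert = seq_record(rec$id, substr(s, lf + 1L, n - lr),
                               "nucleotide", rec$description, q),
           orientation = orientation, reason = NA_character_)
    } else NULL
  }
  res <- try_orient(contig, "forward")
  if (is.null(res)) res <- try_orient(reverse_record(contig), "reverse")
  if (is.null(res))
    res <- list(status = "rejected", insert = NULL, orientation = NA_character_,
                reason = "primer not found at terminus in either orientation")
  res
}

#' Expected-error quality filter
#'
#' Keeps a read iff its expected number of errors,
#' `sum(10^(-Q_i / 10))`, does not exceed `max_expected_errors` (the
#' standard maxEE criterion of amplicon workflows).
#'
#' @param record a [seq_record()] with quality.
#' @param max_expected_errors maxEE threshold (default 1.0).
#' @return logical scalar.
#' @export
quality_filter <- function(record, max_expected_errors = 1.0) {
  if (is.null(record$quality)) stop("quality_filter: record has no quality")
  sum(10^(-record$quality / 10)) <= max_expected_errors
}
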