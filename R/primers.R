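#' Degenerate primer specification
#'
#' A primer is stored with its IUPAC sequence (spaces removed, upper case);
#' inosine (`I`) is permitted and treated as matching all four bases, like
#' `N` — inosine pairs promiscuously, which is exactly why nifH primers use
#' it. Degeneracy is the product of per-position code cardinalities.
#'
#' @param name primer name.
#' @param direction `"F"` (forward) or `"R"` (reverse).
#' @param iupac IUPAC nucleotide string; internal spaces are ignored.
#' @param reference_position optional 1-based inclusive interval (length-2
#'   integer vector) on the Azotobacter vinelandii nifH coordinate system.
#'   Stored verbatim for reporting only; never used for arithmetic.
#' @param citation free-text provenance.
#' @param coverage_claims optional named numeric vector (names = allowed
#'   mismatches, values = percent coverage) as reported for the primer
#'   against a reference database.
#' @return An object of class `primer_spec`.
#' @export
primer_spec <- function(name, direction = c("F", "R"), iupac,
                        reference_position = NULL, citation = "",
                        coverage_claims = NULL) {
  direction <- match.arg(direction)
  iupac <- toupper(gsub("[[:space:]]", "", iupac))
  bad <- setdiff(unique(strsplit(iupac, "")[[1]]), names(IUPAC_SETS))
  if (length(bad)) stop("primer_spec: unknown IUPAC symbol(s): ",
                        paste(bad, collapse = ", "))
  structure(list(name = name, direction = direction, iupac = iupac,
                 reference_position = reference_position,
                 citation = citation, coverage_claims = coverage_claims),
            class = "primer_spec")
}

# IUPAC nucleotide sets; I (inosine) matches all four bases.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"), I = c("A", "C", "G", "T"))

#' @export
print.primer_spec <- function(x, ...) {
  cat(sprintf("<primer_spec %s (%s)> 5'-%s-3', degeneracy %d\n",
              x$name, x$direction, x$iupac, primer_degeneracy(x)))
  invisible(x)
}

#' Degeneracy of a primer
#'
#' Product of per-position IUPAC code cardinalities, with inosine counted
#' as 4.
#' @param primer a [primer_spec()].
#' @return integer degeneracy.
#' @export
primer_degeneracy <- function(primer) {
  prod(vapply(strsplit(primer$iupac, "")[[1]],
              function(ch) length(IUPAC_SETS[[ch]]), integer(1)))
}

#' Expand a degenerate primer to all concrete sequences
#'
#' @param primer a [primer_spec()] (or plain IUPAC string).
#' @return character vector of all concrete ACGT sequences; its length
#'   equals [primer_degeneracy()].
#' @export
expand_iupac <- function(primer) {
  iupac <- if (inherits(primer, "primer_spec")) primer$iupac else
    toupper(gsub("[[:space:]]", "", primer))
  chars <- strsplit(iupac, "")[[1]]
  bad <- setdiff(unique(chars), names(IUPAC_SETS))
  if (length(bad)) stop("expand_iupac: unknown symbol(s): ",
                        paste(bad, collapse = ", "))
  sets <- lapply(chars, function(ch) IUPAC_SETS[[ch]])
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  out
}

#' Count primer/template mismatches
#'
#' Position-wise IUPAC-compatible comparison of a primer against a
#' template window of equal length: a position matches iff the template
#' base is in the primer code's set (inosine matches everything).
#'
#' Orientation convention: the window must be given in the primer's own
#' reading direction. For a reverse primer this is the reverse complement
#' of the template's plus strand at the binding site — i.e. pass
#' `revcomp(template_window)` for reverse primers (helpers in this package
#' do so).
#'
#' @param primer a [primer_spec()] or IUPAC string.
#' @param window nucleotide string of the same length as the primer.
#' @return integer number of incompatible positions.
#' @export
count_mismatches <- function(primer, window) {
  iupac <- if (inherits(primer, "primer_spec")) primer$iupac else
    toupper(gsub("[[:space:]]", "", primer))
  window <- toupper(window)
  if (nchar(iupac) != nchar(window))
    stop("count_mismatches: window length (", nchar(window),
         ") != primer length (", nchar(iupac), ")")
  p <- strsplit(iupac, "")[[1]]
  w <- strsplit(window, "")[[1]]
  sum(!mapply(function(code, base) base %in% IUPAC_SETS[[code]], p, w))
}

#' Fraction of targets covered by a primer
#'
#' Each target must be (or contain at its designated coordinates) the
#' primer-binding window; the caller is responsible for supplying windows
#' in primer orientation (see [count_mismatches()]).
#'
#' @param primer a [primer_spec()] or IUPAC string.
#' @param targets character vector of binding windows, one per target.
#' @param max_mismatches maximum tolerated mismatches.
#' @return fraction in \[0, 1\]; monotone non-decreasing in
#'   `max_mismatches`.
#' @export
primer_coverage <- function(primer, targets, max_mismatches = 0L) {
  if (!length(targets)) stop("primer_coverage: empty target list")
  hits <- vapply(targets, function(t) count_mismatches(primer, t),
                 numeric(1)) <= max_mismatches
  mean(hits)
}

#' Standard broad-coverage nifH primers
#'
#' The widely used degenerate nifH primer set (forward: Nh21F, Ueda19F,
#' F2, IGK3; reverse: nifH1, nifH3, R6, DVV), with published binding
#' positions on the A. vinelandii nifH coordinate system and reported
#' in-silico coverage percentages at 0/1/2 mismatches. Positions are
#' stored verbatim for reporting only.
#'
#' @return named list of [primer_spec()]s.
#' @export
nifh_primers <- function() {
  p <- function(...) primer_spec(...)
  list(
    Nh21F   = p("Nh21F",  "F", "GCI WTY TAY GGN AAR GG", c(19L, 35L),
                "Dedysh et al.", c(`0` = 81, `1` = 94, `2` = 98)),
    Ueda19F = p("Ueda19F", "F", "GCI WTY TAY GGI AAR GGI GG", c(19L, 38L),
                "Ueda et al.", c(`0` = 81, `1` = 94, `2` = 98)),
    F2      = p("F2",     "F", "TGY GAY CCI AAI GCI GA", c(115L, 131L),
                "Marusina et al.", c(`0` = 87, `1` = 91, `2` = 98)),
    IGK3    = p("IGK3",   "F", "GCI WTH TAY GGI AAR GGI GGI ATH GGI AA",
                c(19L, 47L), "Ando et al.", c(`0` = 83, `1` = 96, `2` = 98)),
    nifH1   = p("nifH1",  "R", "ADN GCC ATC ATY TCN CC", c(406L, 476L),
                "Zehr & McReynolds", c(`0` = 85, `1` = 93, `2` = 95)),
    nifH3   = p("nifH3",  "R", "ATR TTR TTN GCN GCR TA", c(478L, 494L),
                "Zani et al.", c(`0` = 89, `1` = 93, `2` = 96)),
    R6      = p("R6",     "R", "GCC ATC ATY TCI CCI GA", c(457L, 473L),
                "Marusina et al.", c(`0` = 90, `1` = 93, `2` = 96)),
    DVV     = p("DVV",    "R", "ATI GCR AAI CCI CCR CAI ACI ACR TC",
                c(388L, 413L), "Ando et al.", c(`0` = 96, `1` = 98, `2` = 99)))
}

#' Read primers from TSV
#'
#' Columns: name, direction, sequence, position (optional, "a-b"),
#' citation (optional).
#' @param path TSV file path.
#' @return named list of [primer_spec()]s.
#' @export
read_primers_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "direction", "sequence")
  if (!all(need %in% names(df)))
    stop("primer TSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i) {
    pos <- NULL
    if ("position" %in% names(df) && nzchar(df$position[i]))
      pos <- as.integer(strsplit(df$position[i], "-")[[1]])
    primer_spec(df$name[i], df$direction[i], df$sequence[i], pos,
                if ("citation" %in% names(df)) df$citation[i] else "")
  })
  names(out) <- df$name
  out
}

#' Sample manifest
#'
#' Associates sample ids with their forward/reverse FASTQ paths and the
#' primer pair used to amplify them.
#'
#' @param sample_id character vector of unique sample ids.
#' @param fwd,rev FASTQ paths.
#' @param primer_pair name of the primer pair, `"<F>-<R>"`.
#' @param metadata optional data.frame of per-sample metadata.
#' @return object of class `sample_manifest` (a data.frame).
#' @export
sample_manifest <- function(sample_id, fwd, rev, primer_pair,
                            metadata = NULL) {
  if (anyDuplicated(sample_id)) stop("sample ids must be unique")
  df <- data.frame(sample_id = sample_id, fwd = fwd, rev = rev,
                   primer_pair = primer_pair, stringsAsFactors = FALSE)
  if (!is.null(metadata)) df <- cbind(df, metadata)
  class(df) <- c("sample_manifest", "data.frame")
  df
}

#' @rdname sample_manifest
#' @param path TSV with columns sample_id, fwd, rev, primer_pair.
#' @export
read_manifest_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  extra <- setdiff(names(df), c("sample_id", "fwd", "rev", "primer_pair"))
  sample_manifest(df$sample_id, df$fwd, df$rev, df$primer_pair,
                  if (length(extra)) df[extra] else NULL)
}

#' Resolve a primer-pair name against a primer set
#'
#' @param pair_name `"<forward>-<reverse>"`.
#' @param primers named list of [primer_spec()]s.
#' @return list with elements `fwd` and `rev`.
#' @export
resolve_primer_pair <- function(pair_name, primers = nifh_primers()) {
  parts <- strsplit(pair_name, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("primer pair must be '<F>-<R>': ", pair_name)
  fwd <- primers[[parts[1]]]; rev <- primers[[parts[2]]]
  if (is.null(fwd) || is.null(rev))
    stop("unknown primer in pair: ", pair_name)
  if (fwd$direction != "F" || rev$direction != "R")
    stop("pair ", pair_name, " does not resolve to one F and one R primer")
  list(fwd = fwd, rev = rev)
}
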