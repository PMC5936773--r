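#' Build a profile HMM from a multiple sequence alignment
#'
#' Columns whose gap fraction is below `match_rule` become match states;
#' all other columns feed insert states. Emissions are Laplace-smoothed
#' residue counts; node transition probabilities (M->M/I/D, I->M/I,
#' D->M/D) are estimated from the observed state paths with the same
#' pseudocount. The background distribution is the overall residue
#' frequency of the alignment, floored at 1e-4 and renormalised.
#'
#' The scoring architecture is local and multihit: uniform 1/L entry into
#' any match state, a fixed per-node early-exit mass (`exit_prob`), and
#' flanking states whose emissions cancel against the null model (see the
#' methods vignette). These begin/end masses are part of the model object.
#'
#' @param msa list of aligned [seq_record()]s (equal lengths, `-` = gap).
#' @param name model name.
#' @param match_rule gap-fraction threshold below which a column is a
#'   match state (default 0.5).
#' @param pseudocount Laplace pseudocount added to every emission and
#'   transition count (default 1).
#' @param exit_prob per-node local exit probability (default 0.05).
#' @return An object of class `profile_hmm`.
#' @export
build_hmm <- function(msa, name = "model", match_rule = 0.5, pseudocount = 1,
                      exit_prob = 0.05) {
  if (!length(msa)) stop("build_hmm: empty alignment")
  alphabet <- msa[[1]]$alphabet
  symbols <- hmm_symbols(alphabet)
  K <- length(symbols)
  mat <- do.call(rbind, lapply(msa, residue_vec))
  if (length(unique(nchar(vapply(msa, `[[`, "", "residues")))) != 1L)
    stop("build_hmm: records have unequal aligned lengths")
  mat[mat == "U"] <- "T"
  ncol_aln <- ncol(mat)
  gapfrac <- colMeans(mat == "-" | mat == ".")
  is_match <- gapfrac < match_rule
  L <- sum(is_match)
  if (L < 1L) stop("build_hmm: zero match columns")
  match_cols <- which(is_match)

  count_row <- function(chars) {
    tab <- table(factor(chars[chars %in% symbols], levels = symbols))
    as.numeric(tab)
  }
  # emissions
  me <- matrix(0, L, K, dimnames = list(NULL, symbols))
  for (j in seq_len(L)) me[j, ] <- count_row(mat[, match_cols[j]])
  me <- sweep(me + pseudocount, 1, rowSums(me + pseudocount), "/")

  ie <- matrix(0, L + 1L, K, dimnames = list(NULL, symbols))
  # insert region k (0..L) = columns between match col k and k+1
  bounds <- c(0L, match_cols, ncol_aln + 1L)
  for (k in 0:L) {
    lo <- bounds[k + 1L] + 1L; hi <- bounds[k + 2L] - 1L
    if (lo <= hi) ie[k + 1L, ] <- count_row(as.vector(mat[, lo:hi]))
  }
  ie <- sweep(ie + pseudocount, 1, rowSums(ie + pseudocount), "/")

  # transitions from observed state paths
  cnt <- matrix(0, L, 7, dimnames = list(NULL,
    c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  for (s in seq_len(nrow(mat))) {
    row <- mat[s, ]
    # state at each node: M or D; inserts counted between nodes
    node_state <- ifelse(row[match_cols] %in% symbols, "M", "D")
    ins_len <- integer(L + 1L)
    for (k in 0:L) {
      lo <- bounds[k + 1L] + 1L; hi <- bounds[k + 2L] - 1L
      ins_len[k + 1L] <- if (lo <= hi) sum(row[lo:hi] %in% symbols) else 0L
    }
    for (j in seq_len(L - 1L)) {
      from <- node_state[j]; to <- node_state[j + 1L]; ni <- ins_len[j + 1L]
      if (from == "M") {
        if (ni > 0L) {
          cnt[j, "MI"] <- cnt[j, "MI"] + 1
          cnt[j, "II"] <- cnt[j, "II"] + (ni - 1L)
          cnt[j, "IM"] <- cnt[j, "IM"] + 1  # inserts then advance
        } else if (to == "M") cnt[j, "MM"] <- cnt[j, "MM"] + 1
        else cnt[j, "MD"] <- cnt[j, "MD"] + 1
        if (ni > 0L && to == "D") {
          # I -> D is not in the architecture; treat as I -> M of next node
          # (counted above); no extra delete transition recorded
        }
      } else {
        if (to == "M" || ni > 0L) cnt[j, "DM"] <- cnt[j, "DM"] + 1
        else cnt[j, "DD"] <- cnt[j, "DD"] + 1
      }
    }
  }
  tr <- matrix(0, L, 7, dimnames = dimnames(cnt))
  norm3 <- function(v) (v + pseudocount) / sum(v + pseudocount)
  for (j in seq_len(L)) {
    tr[j, 1:3] <- norm3(cnt[j, 1:3])
    tr[j, 4:5] <- norm3(cnt[j, 4:5])
    tr[j, 6:7] <- norm3(cnt[j, 6:7])
  }

  res_all <- as.vector(mat)
  bg <- count_row(res_all[res_all %in% symbols])
  bg <- bg / sum(bg)
  bg <- pmax(bg, 1e-4)
  bg <- bg / sum(bg)
  names(bg) <- symbols

  structure(list(name = name, alphabet = alphabet, L = L, symbols = symbols,
                 match_emissions = me, insert_emissions = ie,
                 transitions = tr, background = bg, exit_prob = exit_prob,
                 match_rule = match_rule, pseudocount = pseudocount),
            class = "profile_hmm")
}

hmm_symbols <- function(alphabet) {
  if (alphabet == "nucleotide") c("A", "C", "G", "T") else AA20
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("<profile_hmm %s> %s, L = %d match states\n",
              x$name, x$alphabet, x$L))
  invisible(x)
}

#' Consensus sequence of a profile HMM
#'
#' The highest-probability residue of each match state.
#' @param hmm a [build_hmm()] model.
#' @return character scalar of length `L`.
#' @export
hmm_consensus <- function(hmm) {
  paste(hmm$symbols[apply(hmm$match_emissions, 1, which.max)], collapse = "")
}

#' Serialize and read profile HMMs
#'
#' Plain-text tabular format: a header (name, alphabet, L, exit mass,
#' symbols), then the match-emission, insert-emission and transition
#' tables and the background row, all to 10 decimal places. Lines starting
#' with `#` are comments and are ignored by the reader; writing the same
#' model twice is byte-identical.
#'
#' @param hmm a `profile_hmm`.
#' @param path output/input file path.
#' @return `write_hmm()`: the path, invisibly; `read_hmm()`: a
#'   `profile_hmm`.
#' @export
write_hmm <- function(hmm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) sprintf("%.10f", x)
  w <- function(...) writeLines(paste(..., sep = "\t"), con)
  writeLines(c("# profile-hmm v1",
               paste0("NAME\t", hmm$name),
               paste0("ALPH\t", hmm$alphabet),
               paste0("LENG\t", hmm$L),
               paste0("EXIT\t", fmt(hmm$exit_prob)),
               paste0("SYM\t", paste(hmm$symbols, collapse = "\t"))), con)
  w("BG", paste(fmt(hmm$background), collapse = "\t"))
  for (j in seq_len(hmm$L))
    w("MAT", j, paste(fmt(hmm$match_emissions[j, ]), collapse = "\t"))
  for (j in seq_len(hmm$L + 1L))
    w("INS", j - 1L, paste(fmt(hmm$insert_emissions[j, ]), collapse = "\t"))
  for (j in seq_len(hmm$L))
    w("TRN", j, paste(fmt(hmm$transitions[j, ]), collapse = "\t"))
  invisible(path)
}

#' @rdname write_hmm
#' @export
read_hmm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  field <- function(key) {
    ln <- lines[startsWith(lines, paste0(key, "\t"))]
    strsplit(ln, "\t")[[1]][-1]
  }
  name <- field("NAME"); alphabet <- field("ALPH")
  L <- as.integer(field("LENG")); exit_prob <- as.numeric(field("EXIT"))
  symbols <- field("SYM")
  parse_tab <- function(key, nrows) {
    lns <- lines[startsWith(lines, paste0(key, "\t"))]
    stopifnot(length(lns) == nrows)
    m <- do.call(rbind, lapply(strsplit(lns, "\t"), function(p)
      as.numeric(p[-(1:2)])))
    colnames(m) <- symbols
    m
  }
  me <- parse_tab("MAT", L)
  ie <- parse_tab("INS", L + 1L)
  tr <- lines[startsWith(lines, "TRN\t")]
  tr <- do.call(rbind, lapply(strsplit(tr, "\t"), function(p)
    as.numeric(p[-(1:2)])))
  colnames(tr) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  bg <- as.numeric(strsplit(lines[startsWith(lines, "BG\t")], "\t")[[1]][-1])
  names(bg) <- symbols
  structure(list(name = name, alphabet = alphabet, L = L, symbols = symbols,
                 match_emissions = me, insert_emissions = ie, transitions = tr,
                 background = bg, exit_prob = exit_prob,
                 match_rule = NA_real_, pseudocount = NA_real_),
            class = "profile_hmm")
}
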