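# Encoding and scoring wrappers around the C++ profile-HMM kernels.

encode_obs <- function(hmm, residues) {
  chars <- strsplit(toupper(residues), "")[[1]]
  if (hmm$alphabet == "nucleotide") chars[chars == "U"] <- "T"
  idx <- match(chars, hmm$symbols) - 1L
  idx[is.na(idx)] <- -1L  # ambiguity codes emit background (odds 1)
  idx
}

hmm_log_par <- function(hmm) {
  list(lmat = log(hmm$match_emissions),
       lins = log(hmm$insert_emissions),
       ltr = log(hmm$transitions),
       lbg = log(hmm$background))
}

# Length-conditioned flank/null loop probability: eta = n / (n + 1), the
# standard target-length parameterisation under which flanking residues
# contribute odds exactly 1.
flank_eta <- function(n) n / (n + 1)

#' Forward log-odds score
#'
#' `log2` of the ratio between the forward probability of the sequence
#' under the local multihit profile HMM and its probability under the
#' background null model. Ambiguity codes (N, X, ...) contribute odds 1.
#'
#' @param hmm a [build_hmm()] model.
#' @param seq a [seq_record()] (or plain string) of the model's alphabet.
#' @param eta optional flank/null loop probability; defaults to the
#'   length-conditioned `n/(n+1)`.
#' @return An `hmm_score` list: `model`, `sequence`, `bits`.
#' @export
forward_bits <- function(hmm, seq, eta = NULL) {
  sq <- as_seqchar(seq)
  if (!nzchar(sq$residues)) stop("forward_bits: empty sequence")
  obs <- encode_obs(hmm, sq$residues)
  if (is.null(eta)) eta <- flank_eta(length(obs))
  p <- hmm_log_par(hmm)
  bits <- .hmm_forward_cpp(obs, p$lmat, p$lins, p$ltr, p$lbg,
                           hmm$exit_prob, eta)
  structure(list(model = hmm$name, sequence = sq$id, bits = bits,
                 path = NULL), class = "hmm_score")
}

#' Viterbi score and state path
#'
#' Maximum-probability path under the same architecture as
#' [forward_bits()]; Viterbi bits are never above forward bits.
#'
#' @inheritParams forward_bits
#' @return An `hmm_score` with a `path` data.frame (state, node, pos).
#' @export
viterbi <- function(hmm, seq, eta = NULL) {
  sq <- as_seqchar(seq)
  if (!nzchar(sq$residues)) stop("viterbi: empty sequence")
  obs <- encode_obs(hmm, sq$residues)
  if (is.null(eta)) eta <- flank_eta(length(obs))
  p <- hmm_log_par(hmm)
  v <- .hmm_viterbi_cpp(obs, p$lmat, p$lins, p$ltr, p$lbg,
                        hmm$exit_prob, eta)
  states <- c("N", "B", "M", "I", "D", "E", "J", "C")
  path <- data.frame(state = states[v$state + 1L], node = v$node,
                     pos = v$pos, stringsAsFactors = FALSE)
  structure(list(model = hmm$name, sequence = sq$id, bits = v$bits,
                 path = path), class = "hmm_score")
}

#' @export
print.hmm_score <- function(x, ...) {
  cat(sprintf("<hmm_score> %s vs %s: %.3f bits%s\n", x$sequence, x$model,
              x$bits, if (is.null(x$path)) "" else " (with path)"))
  invisible(x)
}

as_seqchar <- function(seq) {
  if (is.list(seq) && !is.null(seq$residues))
    list(id = if (is.null(seq$id)) "query" else seq$id,
         residues = toupper(seq$residues))
  else list(id = "query", residues = toupper(as.character(seq)))
}

#' Nucleotide pre-filter against a profile HMM
#'
#' Partitions contigs into kept/discarded by forward log-odds against the
#' nucleotide model. The default acceptance threshold of 0 bits keeps any
#' sequence more likely under the model than under background — the
#' permissive analog of accepting every database hit regardless of score,
#' so that homologous genes survive to the dedicated arbitration step.
#'
#' @param contigs list of nucleotide [seq_record()]s.
#' @param nuc_model nucleotide [build_hmm()] model.
#' @param accept_bits acceptance threshold in bits (default 0).
#' @return list with `kept`, `discarded` (lists of records) and `bits`
#'   (named numeric vector over all inputs).
#' @export
hmm_filter <- function(contigs, nuc_model, accept_bits = 0) {
  if (!length(contigs))
    return(list(kept = list(), discarded = list(), bits = numeric()))
  # score unique residue strings once; amplicon sets are highly redundant
  seqs <- vapply(contigs, `[[`, "", "residues")
  uq <- unique(seqs)
  ub <- vapply(uq, function(s) forward_bits(nuc_model, s)$bits, numeric(1))
  bits <- ub[match(seqs, uq)]
  names(bits) <- vapply(contigs, `[[`, "", "id")
  keep <- bits >= accept_bits
  list(kept = contigs[keep], discarded = contigs[!keep], bits = bits)
}

#' Rank amino-acid models for one sequence
#'
#' Scores the sequence against every model and returns the scores sorted
#' by descending bits (ties broken by model name) — the arbitration
#' substrate for nifH vs homolog calls.
#'
#' @param seq_aa amino-acid [seq_record()] or string.
#' @param models list of amino-acid `profile_hmm`s.
#' @return list of `hmm_score`, best first.
#' @export
hmm_scan <- function(seq_aa, models) {
  if (!length(models)) stop("hmm_scan: need at least one model")
  for (m in models)
    if (m$alphabet != "amino-acid")
      stop("hmm_scan: model ", m$name, " is not amino-acid")
  scores <- lapply(models, forward_bits, seq = seq_aa)
  bits <- vapply(scores, `[[`, numeric(1), "bits")
  nms <- vapply(scores, `[[`, "", "model")
  scores[order(-bits, nms)]
}

#' Project a sequence onto the match columns of a model
#'
#' The Viterbi path is projected onto the L match states: a match state
#' emits its residue, a deleted or unvisited match state emits `-`, and
#' insert-state residues are dropped. Output length is exactly `L`.
#'
#' @inheritParams forward_bits
#' @return character scalar of length `L`.
#' @export
align_to_model <- function(hmm, seq_aa) {
  sq <- as_seqchar(seq_aa)
  if (!nzchar(sq$residues)) stop("align_to_model: empty sequence")
  v <- viterbi(hmm, sq)
  out <- rep("-", hmm$L)
  chars <- strsplit(toupper(sq$residues), "")[[1]]
  mrows <- v$path[v$path$state == "M", , drop = FALSE]
  for (k in seq_len(nrow(mrows))) {
    j <- mrows$node[k]
    if (out[j] == "-") out[j] <- chars[mrows$pos[k]]
  }
  paste(out, collapse = "")
}
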