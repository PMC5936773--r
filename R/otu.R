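# Dereplication, chimera checking, greedy centroid clustering and global
# read mapping (UPARSE-style, exact dynamic programming -- inputs here are
# desk-scale so no k-mer acceleration is used).

#' Dereplicate contigs
#'
#' Groups contigs by exact full-length residue identity. Output is sorted
#' by count descending, ties broken lexicographically by residues, so the
#' greedy clustering pass downstream is deterministic.
#'
#' @param contigs list of nucleotide [seq_record()]s.
#' @return data.frame with columns `residues`, `count`, and list-column
#'   `member_ids`; `sum(count)` equals `length(contigs)`.
#' @export
dereplicate <- function(contigs) {
  if (!length(contigs))
    return(data.frame(residues = character(), count = integer(),
                      member_ids = I(list())))
  seqs <- vapply(contigs, `[[`, "", "residues")
  ids <- vapply(contigs, `[[`, "", "id")
  grp <- split(ids, seqs)
  df <- data.frame(residues = names(grp),
                   count = vapply(grp, length, integer(1)),
                   stringsAsFactors = FALSE)
  df$member_ids <- I(unname(grp))
  df <- df[order(-df$count, df$residues), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Remove singleton unique sequences
#'
#' @param uniques a [dereplicate()] table.
#' @return the table restricted to `count >= 2`.
#' @export
remove_singletons <- function(uniques) {
  out <- uniques[uniques$count >= 2L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

nt_submat <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2, baseOnly = FALSE)
    cache
  }
})

align_pair_nt <- function(a, b) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = nt_submat(), gapOpening = 10, gapExtension = 1)
}

# identity over alignment columns excluding terminal-gap columns
identity_from_strings <- function(pa, sa) {
  p <- strsplit(pa, "")[[1]]; s <- strsplit(sa, "")[[1]]
  gap <- p == "-" | s == "-"
  nong <- which(!gap)
  if (!length(nong)) return(0)
  cols <- nong[1]:nong[length(nong)]
  sum(p[cols] == s[cols]) / length(cols)
}

#' Pairwise nucleotide identity
#'
#' End-to-end global alignment (match +1, mismatch -2, gap open -10, gap
#' extend -1 per position); identity is the fraction of matching columns
#' over the alignment, with terminal-gap columns excluded from both
#' numerator and denominator. See the methods vignette for why terminal
#' gaps are penalised in scoring but excluded from the identity.
#'
#' @param a,b nucleotide strings or [seq_record()]s.
#' @return fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  a <- as_seqchar(a)$residues; b <- as_seqchar(b)$residues
  if (!nzchar(a) || !nzchar(b)) stop("pairwise_identity: empty sequence")
  aln <- align_pair_nt(a, b)
  identity_from_strings(as.character(Biostrings::pattern(aln)),
                        as.character(Biostrings::subject(aln)))
}

# per-query-position cumulative match/column profiles against one parent
chimera_profiles <- function(query, parent) {
  aln <- align_pair_nt(query, parent)
  p <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  qpos <- cumsum(p != "-")
  ismatch <- p == s & p != "-"
  n <- max(qpos)
  cm <- numeric(n); cc <- numeric(n)
  for (i in seq_along(p)) {
    k <- qpos[i]
    if (k >= 1) {
      cm[k] <- cm[k] + (if (ismatch[i]) 1 else 0)
      cc[k] <- cc[k] + 1
    }
  }
  list(cum_match = cumsum(cm), cum_cols = cumsum(cc))
}

#' De-novo two-parent chimera check
#'
#' A query is called chimeric when some ordered pair of more-abundant
#' centroids (each with abundance at least twice the query count) and a
#' breakpoint splits the query into a left segment matching the first
#' parent and a right segment matching the second at `segment_identity`
#' or better, while full-length identity to each parent stays below the
#' clustering threshold. A reduced UPARSE-style model: crossover only, no
#' abundance-skew score.
#'
#' @param query one row of a [dereplicate()] table (or a list with
#'   `residues` and `count`).
#' @param centroids list of `otu_record`s (see [cluster_otus()]).
#' @param segment_identity per-segment identity threshold (default 0.99).
#' @param full_identity full-length identity below which a parent is
#'   "distinct enough" (default 0.97).
#' @param min_segment minimum segment length in query bases (default 16).
#' @return logical scalar.
#' @export
detect_chimera <- function(query, centroids, segment_identity = 0.99,
                           full_identity = 0.97, min_segment = 16L) {
  if (length(centroids) < 2L) return(FALSE)
  qcount <- if (!is.null(query$count)) query$count else 1L
  qres <- query$residues
  parents <- Filter(function(ct) sum(ct$abundance) >= 2L * qcount, centroids)
  if (length(parents) < 2L) return(FALSE)
  profs <- lapply(parents, function(ct) chimera_profiles(qres, ct$centroid$residues))
  fulls <- vapply(parents, function(ct)
    pairwise_identity(qres, ct$centroid$residues), numeric(1))
  n <- nchar(qres)
  bps <- seq(min_segment, n - min_segment)
  if (!length(bps)) return(FALSE)
  for (i in seq_along(parents)) {
    if (fulls[i] >= full_identity) next
    li <- profs[[i]]
    lid <- li$cum_match[bps] / pmax(li$cum_cols[bps], 1)
    for (k in seq_along(parents)) {
      if (k == i || fulls[k] >= full_identity) next
      rk <- profs[[k]]
      tm <- rk$cum_match[n]; tc <- rk$cum_cols[n]
      rid <- (tm - rk$cum_match[bps]) / pmax(tc - rk$cum_cols[bps], 1)
      if (any(lid >= segment_identity & rid >= segment_identity))
        return(TRUE)
    }
  }
  FALSE
}

new_otu_record <- function(otu_id, centroid, count) {
  structure(list(otu_id = otu_id, centroid = centroid,
                 abundance = count, flags = "chimera_parent_checked"),
            class = "otu_record")
}

#' Greedy centroid clustering at a fixed radius
#'
#' Single greedy pass over uniques sorted by decreasing abundance: a
#' unique joins the first existing centroid within `radius` (identity
#' `>= 1 - radius`); otherwise, unless it is flagged as a chimera of two
#' existing centroids, it founds a new OTU. By construction all centroid
#' pairs are separated by more than the radius.
#'
#' @param uniques [dereplicate()] table (singletons normally removed).
#' @param radius clustering radius (default 0.03, i.e. 97\% identity).
#' @param chimera_check run [detect_chimera()] on would-be founders
#'   (default TRUE).
#' @return list of `otu_record`s (ids `OTU_1`, `OTU_2`, ... in founding
#'   order).
#' @export
cluster_otus <- function(uniques, radius = 0.03, chimera_check = TRUE) {
  otus <- list()
  if (!nrow(uniques)) return(otus)
  for (r in seq_len(nrow(uniques))) {
    u <- uniques[r, ]
    joined <- FALSE
    for (ct in otus) {
      if (pairwise_identity(u$residues, ct$centroid$residues) >= 1 - radius) {
        joined <- TRUE
        break
      }
    }
    if (joined) next
    if (chimera_check && detect_chimera(u, otus, full_identity = 1 - radius))
      next
    id <- paste0("OTU_", length(otus) + 1L)
    otus[[length(otus) + 1L]] <-
      new_otu_record(id, seq_record(id, u$residues, "nucleotide"), u$count)
  }
  otus
}

#' Map reads to OTU centroids
#'
#' Global alignment of every contig (prior to dereplication, so reads
#' removed as singletons still participate) against every centroid; each
#' contig is assigned to the highest-identity centroid with identity at
#' least `min_identity` (ties to the first centroid in table order),
#' otherwise counted as unmapped.
#'
#' @param contigs_by_sample named list: sample id -> list of contig
#'   [seq_record()]s.
#' @param centroids list of `otu_record`s from [cluster_otus()].
#' @param min_identity mapping identity threshold (default 0.97).
#' @return An `otu_table`: list with `otus` (data.frame otu_id x sample
#'   counts), `centroids`, `samples`, `unmapped` (named vector), and
#'   `assignment` (per unique sequence).
#' @export
map_reads <- function(contigs_by_sample, centroids, min_identity = 0.97) {
  if (!length(centroids)) stop("map_reads: no centroids")
  samples <- names(contigs_by_sample)
  if (is.null(samples)) stop("map_reads: contigs_by_sample must be named")
  all_seqs <- unlist(lapply(contigs_by_sample, function(cs)
    vapply(cs, `[[`, "", "residues")), use.names = FALSE)
  uq <- unique(all_seqs)
  # identity of each unique sequence vs each centroid
  idm <- matrix(0, length(uq), length(centroids))
  for (k in seq_along(centroids)) {
    cres <- centroids[[k]]$centroid$residues
    idm[, k] <- vapply(uq, function(s) pairwise_identity(s, cres), numeric(1))
  }
  best_k <- integer(length(uq))
  for (i in seq_along(uq)) {
    ok <- which(idm[i, ] >= min_identity)
    best_k[i] <- if (!length(ok)) 0L else ok[which.max(idm[i, ok])]
  }
  otu_ids <- vapply(centroids, `[[`, "", "otu_id")
  counts <- matrix(0L, length(centroids), length(samples),
                   dimnames = list(otu_ids, samples))
  unmapped <- setNames(integer(length(samples)), samples)
  for (s in samples) {
    seqs <- vapply(contigs_by_sample[[s]], `[[`, "", "residues")
    ks <- best_k[match(seqs, uq)]
    unmapped[s] <- sum(ks == 0L)
    tab <- table(factor(ks[ks > 0L], levels = seq_along(centroids)))
    counts[, s] <- as.integer(tab)
  }
  structure(list(otus = counts, centroids = centroids, samples = samples,
                 unmapped = unmapped,
                 assignment = data.frame(residues = uq, otu = ifelse(
                   best_k > 0L, otu_ids[pmax(best_k, 1L)], NA_character_),
                   stringsAsFactors = FALSE)),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d OTUs x %d samples; unmapped: %s\n",
              nrow(x$otus), length(x$samples),
              paste(x$unmapped, collapse = ", ")))
  print(x$otus)
  invisible(x)
}

#' Write an OTU table as TSV
#'
#' Rows are OTUs, columns samples; first column is the OTU id, the last
#' column the centroid sequence. A final `unmapped` row carries the
#' per-sample unmapped counts.
#'
#' @param table an `otu_table`.
#' @param path output path.
#' @export
write_otu_table <- function(table, path) {
  df <- data.frame(otu_id = rownames(table$otus), table$otus,
                   centroid = vapply(table$centroids, function(ct)
                     ct$centroid$residues, ""),
                   check.names = FALSE, stringsAsFactors = FALSE)
  un <- data.frame(otu_id = "unmapped", t(table$unmapped), centroid = "",
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(rbind(df, un), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
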