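# Homolog arbitration (nifH vs bchX / chlL-bchL), best-hit taxonomic
# classification, CART assignment to nifH phylogenetic clusters, and
# nearest-reference placement.

#' Arbitrate nifH vs homolog models for a set of OTUs
#'
#' Every amino-acid OTU representative is scanned against the supplied
#' models ([hmm_scan()]); the verdict is the unique top-scoring model
#' (nifH keeps the OTU, a homolog model excludes it, a tie is
#' `undetermined` and conservatively excluded). Read-level fractions are
#' computed by weighting each OTU's verdict with its mapped read counts
#' per sample. parA-like sequences, which have no dedicated model, are
#' captured by the bchX model and reported under that label.
#'
#' @param otus_aa named list (otu_id -> amino-acid [seq_record()] or
#'   string) of OTU representatives.
#' @param models named list of amino-acid `profile_hmm`s; the nifH model
#'   is identified by `nifh_name`.
#' @param otu_table an `otu_table` from [map_reads()] (for read
#'   weighting).
#' @param nifh_name name of the nifH model (default `"nifH"`).
#' @return list with `retained` (character vector of nifH otu ids),
#'   `verdicts` (data.frame otu_id, label, one bits column per model) and
#'   `report` (a `contamination_report`).
#' @export
screen_homologs <- function(otus_aa, models, otu_table,
                            nifh_name = "nifH") {
  if (!length(models)) stop("screen_homologs: no models")
  mnames <- vapply(models, `[[`, "", "name")
  if (!nifh_name %in% mnames)
    stop("screen_homologs: missing model '", nifh_name, "'")
  otu_ids <- names(otus_aa)
  bits <- matrix(NA_real_, length(otu_ids), length(mnames),
                 dimnames = list(otu_ids, sort(mnames)))
  label <- character(length(otu_ids))
  for (i in seq_along(otu_ids)) {
    sc <- hmm_scan(otus_aa[[i]], models)
    b <- vapply(sc, `[[`, numeric(1), "bits")
    nm <- vapply(sc, `[[`, "", "model")
    bits[i, nm] <- b
    label[i] <- if (sum(b == max(b)) > 1L) "undetermined" else nm[1]
  }
  verdicts <- data.frame(otu_id = otu_ids, label = label,
                         stringsAsFactors = FALSE)
  verdicts <- cbind(verdicts, as.data.frame(bits))
  retained <- otu_ids[label == nifh_name]

  counts <- otu_table$otus[otu_ids, , drop = FALSE]
  is_nifh <- label == nifh_name
  per_sample <- lapply(otu_table$samples, function(s) {
    tot <- sum(counts[, s])
    read_frac <- if (tot > 0) sum(counts[!is_nifh, s]) / tot else NA_real_
    present <- counts[, s] > 0
    notu <- sum(present)
    otu_frac <- if (notu > 0) sum(present & !is_nifh) / notu else NA_real_
    by_label <- vapply(split(counts[, s], label), sum, numeric(1)) /
      max(tot, 1)
    list(sample = s, reads_non_nifh = read_frac, otus_non_nifh = otu_frac,
         breakdown = by_label)
  })
  report <- structure(list(per_sample = per_sample, nifh_name = nifh_name),
                      class = "contamination_report")
  list(retained = retained, verdicts = verdicts, report = report)
}

#' @export
print.contamination_report <- function(x, ...) {
  cat("<contamination_report>\n")
  for (p in x$per_sample)
    cat(sprintf("  %s: non-%s reads %.1f%%, OTUs %.1f%%\n", p$sample,
                x$nifh_name, 100 * p$reads_non_nifh, 100 * p$otus_non_nifh))
  invisible(x)
}

#' Write a contamination report as TSV
#'
#' Two fraction columns per sample (reads, OTUs), mirroring a
#' reads-vs-OTUs contamination bar chart.
#' @param report a `contamination_report`.
#' @param path output path.
#' @export
write_contamination_tsv <- function(report, path) {
  df <- do.call(rbind, lapply(report$per_sample, function(p)
    data.frame(sample = p$sample, reads_non_nifh = p$reads_non_nifh,
               otus_non_nifh = p$otus_non_nifh)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Best-hit protein classification against a labeled reference set
#'
#' Local alignment (BLOSUM62, affine gaps -11/-1) of the query against
#' every labeled reference; the best bit score wins, ties broken by
#' lexicographic reference id and flagged. Reference headers follow
#' `id|lineage|cluster`.
#'
#' @param query_aa amino-acid [seq_record()] or string.
#' @param labeled_refs list of amino-acid [seq_record()]s whose `id` (or
#'   `id|lineage|cluster` composite) carries the labels.
#' @return a `taxonomy_assignment`: `best_ref_id`, `taxon_label`,
#'   `cluster_label`, `percent_identity`, `bit_score`, `tie`.
#' @export
classify_besthit <- function(query_aa, labeled_refs) {
  if (!length(labeled_refs)) stop("classify_besthit: empty reference set")
  q <- as_seqchar(query_aa)
  B <- blosum62()
  scores <- vapply(labeled_refs, function(ref) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(q$residues), Biostrings::AAString(ref$residues),
      type = "local", substitutionMatrix = B, gapOpening = 11,
      gapExtension = 1)
    Biostrings::score(aln)
  }, numeric(1))
  ids <- vapply(labeled_refs, `[[`, "", "id")
  best <- order(-scores, ids)[1]
  tie <- sum(scores == scores[best]) > 1L
  ref <- labeled_refs[[best]]
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q$residues), Biostrings::AAString(ref$residues),
    type = "local", substitutionMatrix = B, gapOpening = 11,
    gapExtension = 1)
  pid <- identity_from_strings(as.character(Biostrings::pattern(aln)),
                               as.character(Biostrings::subject(aln))) * 100
  parts <- strsplit(paste(ref$id, ref$description, sep = ""), "|",
                    fixed = TRUE)[[1]]
  structure(list(
    query_id = q$id, best_ref_id = parts[1],
    taxon_label = if (length(parts) >= 2) parts[2] else NA_character_,
    cluster_label = if (length(parts) >= 3) parts[3] else NA_character_,
    percent_identity = pid, bit_score = scores[best], tie = tie),
    class = "taxonomy_assignment")
}

#' @export
print.taxonomy_assignment <- function(x, ...) {
  cat(sprintf("<taxonomy_assignment> %s -> %s (%s), %.1f%% id, score %.1f%s\n",
              x$query_id, x$best_ref_id,
              if (is.na(x$taxon_label)) "?" else x$taxon_label,
              x$percent_identity, x$bit_score,
              if (x$tie) " [tie]" else ""))
  invisible(x)
}

# ---- CART over aligned amino-acid columns ---------------------------------

gini <- function(labels) {
  p <- table(labels) / length(labels)
  1 - sum(p^2)
}

majority_label <- function(labels) {
  tab <- sort(table(labels), decreasing = TRUE)
  names(tab)[1]
}

# candidate residue subsets at a column: all non-empty proper subsets of
# the residues observed there (gaps never match any subset)
column_subsets <- function(residues) {
  resid <- sort(unique(residues[residues != "-"]))
  if (length(resid) < 1L) return(list())
  if (length(resid) == 1L) return(list(resid))
  subs <- list()
  for (sz in seq_len(length(resid) - 1L)) {
    cmb <- utils::combn(resid, sz, simplify = FALSE)
    subs <- c(subs, cmb)
  }
  subs
}

best_split <- function(mat, labels) {
  n <- length(labels)
  parent <- gini(labels)
  best <- NULL
  for (col in seq_len(ncol(mat))) {
    subs <- column_subsets(mat[, col])
    for (s in subs) {
      inset <- mat[, col] %in% s
      nl <- sum(inset)
      if (nl == 0L || nl == n) next
      imp <- (nl * gini(labels[inset]) + (n - nl) * gini(labels[!inset])) / n
      gain <- parent - imp
      key <- paste(s, collapse = "")
      if (is.null(best) || gain > best$gain + 1e-12) {
        best <- list(col = col, subset = s, gain = gain, key = key)
      }
      # deterministic tie-break: lowest column, then lexicographic subset
      # (loop order visits columns ascending and subsets in lexicographic
      # order within a size; strict '>' keeps the first optimum)
    }
  }
  if (!is.null(best) && best$gain <= 1e-12) best <- NULL
  best
}

grow_tree <- function(mat, labels, depth, max_depth, min_leaf) {
  if (length(unique(labels)) == 1L || depth >= max_depth ||
      length(labels) < 2L * min_leaf) {
    return(list(leaf = TRUE, label = majority_label(labels),
                support = length(labels)))
  }
  sp <- best_split(mat, labels)
  if (is.null(sp)) {
    return(list(leaf = TRUE, label = majority_label(labels),
                support = length(labels)))
  }
  inset <- mat[, sp$col] %in% sp$subset
  if (sum(inset) < min_leaf || sum(!inset) < min_leaf) {
    return(list(leaf = TRUE, label = majority_label(labels),
                support = length(labels)))
  }
  list(leaf = FALSE, col = sp$col, subset = sp$subset,
       yes = grow_tree(mat[inset, , drop = FALSE], labels[inset],
                       depth + 1L, max_depth, min_leaf),
       no = grow_tree(mat[!inset, , drop = FALSE], labels[!inset],
                      depth + 1L, max_depth, min_leaf))
}

#' Train a decision tree for nifH cluster assignment
#'
#' CART with Gini impurity over binary tests of the form "residue at
#' aligned column c is in subset S". Rows are sequences projected onto
#' the match columns of a profile HMM ([align_to_model()]); gap
#' characters fail every subset test. Greedy best-gain splitting with
#' deterministic tie-breaks (lowest column index, then lexicographically
#' smallest subset); growth stops at purity, `max_depth`, or `min_leaf`.
#' Single-label input yields a single-leaf tree.
#'
#' @param rows character vector of equal-length aligned sequences.
#' @param labels cluster label per row.
#' @param max_depth maximum tree depth (default 10).
#' @param min_leaf minimum rows per leaf (default 1).
#' @return object of class `cluster_tree`.
#' @export
train_cluster_tree <- function(rows, labels, max_depth = 10L, min_leaf = 1L) {
  stopifnot(length(rows) == length(labels), length(rows) >= 1L)
  if (length(unique(nchar(rows))) != 1L)
    stop("train_cluster_tree: rows must have equal aligned length")
  mat <- do.call(rbind, strsplit(toupper(rows), ""))
  root <- grow_tree(mat, as.character(labels), 0L, max_depth, min_leaf)
  structure(list(root = root, L = ncol(mat),
                 labels = sort(unique(as.character(labels)))),
            class = "cluster_tree")
}

tree_depth <- function(node) {
  if (node$leaf) 0L else 1L + max(tree_depth(node$yes), tree_depth(node$no))
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree> %d label(s), depth %d\n",
              length(x$labels), tree_depth(x$root)))
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      cat(pad, "leaf: ", node$label, " (n=", node$support, ")\n", sep = "")
    } else {
      cat(pad, "col ", node$col, " in {",
          paste(node$subset, collapse = ","), "}?\n", sep = "")
      show(node$yes, indent + 1L)
      show(node$no, indent + 1L)
    }
  }
  show(x$root, 1L)
  invisible(x)
}

#' Assign a cluster label with a trained tree
#'
#' Root-to-leaf descent; a gap at a tested column fails the subset test
#' and descends to the "no" child. All-gap inputs are flagged low
#' confidence.
#'
#' @param tree a [train_cluster_tree()] tree.
#' @param query_aligned aligned sequence (length `tree$L`), e.g. from
#'   [align_to_model()].
#' @return list with `label` and `low_confidence`.
#' @export
assign_cluster <- function(tree, query_aligned) {
  chars <- strsplit(toupper(query_aligned), "")[[1]]
  if (length(chars) != tree$L)
    stop("assign_cluster: query length ", length(chars),
         " != tree column count ", tree$L)
  node <- tree$root
  while (!node$leaf)
    node <- if (chars[node$col] %in% node$subset) node$yes else node$no
  list(label = node$label, low_confidence = all(chars == "-"))
}

#' Nearest-reference placement
#'
#' Places a query on a labeled reference alignment by normalised Hamming
#' distance over mutually ungapped columns; a stand-in for full
#' phylogenetic placement (no tree required). Queries sharing fewer than
#' `min_columns` comparable columns are unassigned.
#'
#' @param ref_alignment character vector of aligned reference rows.
#' @param ref_labels cluster/taxon label per reference row.
#' @param query_aligned aligned query (same column space, e.g. via
#'   [align_to_model()]).
#' @param min_columns minimum comparable columns (default 20).
#' @return list `nearest` (reference index or NA), `label`, `distance`,
#'   `columns`.
#' @export
place_nearest <- function(ref_alignment, ref_labels, query_aligned,
                          min_columns = 20L) {
  q <- strsplit(toupper(query_aligned), "")[[1]]
  best <- list(nearest = NA_integer_, label = "unassigned",
               distance = NA_real_, columns = 0L)
  for (i in seq_along(ref_alignment)) {
    r <- strsplit(toupper(ref_alignment[i]), "")[[1]]
    if (length(r) != length(q))
      stop("place_nearest: reference row ", i, " has different length")
    comp <- q != "-" & r != "-"
    nc <- sum(comp)
    if (nc < min_columns) next
    d <- sum(q[comp] != r[comp]) / nc
    if (is.na(best$distance) || d < best$distance ||
        (d == best$distance && i < best$nearest)) {
      best <- list(nearest = i, label = ref_labels[i], distance = d,
                   columns = nc)
    }
  }
  best
}
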