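# End-to-end orchestration: merge -> trim -> quality filter -> nucleotide
# HMM pre-filter -> OTU clustering/mapping -> frameshift-corrected
# translation -> homolog arbitration -> classification -> diversity.

#' Pipeline configuration
#'
#' All tunable stage parameters in one serializable object; defaults are
#' the package defaults of each stage.
#'
#' @param ... overrides of individual defaults (see the returned names).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_overlap = 10L, max_mismatch_frac = 0.25, max_expected_errors = 1.0,
    trim_max_mismatches = 2L, accept_bits = 0, otu_radius = 0.03,
    map_identity = 0.97, frameshift_penalty = 20, gap_open = 11,
    gap_ext = 1, framebot_min_identity = 0.4, framebot_min_aligned = 80L,
    cart_max_depth = 10L, cart_min_leaf = 1L,
    diversity_iterations = 100L, drop_percentile = 15, seed = 1L,
    version = "1")
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown pipeline_config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path file path for the plain-text serialized form (lossless
#'   round-trip).
#' @export
write_pipeline_config <- function(config, path) {
  dput(unclass(config), file = path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  structure(dget(path), class = "pipeline_config")
}

merge_sample <- function(fwd, rev, config) {
  # merge unique (fwd, rev) residue pairs once; amplicon runs are highly
  # redundant
  keyf <- vapply(fwd, `[[`, "", "residues")
  keyr <- vapply(rev, `[[`, "", "residues")
  key <- paste(keyf, keyr)
  uq <- !duplicated(key)
  cache <- list()
  for (i in which(uq))
    cache[[key[i]]] <- merge_pair(fwd[[i]], rev[[i]], config$min_overlap,
                                  config$max_mismatch_frac)
  merged <- vector("list", length(fwd))
  status <- character(length(fwd))
  for (i in seq_along(fwd)) {
    res <- cache[[key[i]]]
    status[i] <- res$status
    if (res$status == "merged") {
      m <- res$merged
      m$id <- fwd[[i]]$id
      merged[[i]] <- m
    }
  }
  list(merged = merged[status == "merged"], status = status)
}

stage_counts <- function(...) {
  vals <- list(...)
  data.frame(stage = names(vals), count = unlist(vals), row.names = NULL)
}

#' Run the full amplicon pipeline on a synthetic mock experiment
#'
#' Executes every stage on the bundle produced by
#' [simulate_mock_experiment()]: read merging, primer trimming,
#' expected-error filtering, nucleotide profile-HMM pre-filtering,
#' dereplication/singleton removal/chimera-checked greedy OTU clustering,
#' global read mapping, frameshift-corrected translation, homolog
#' arbitration with per-sample contamination reporting, best-hit
#' classification, decision-tree cluster assignment, nearest-reference
#' placement, bootstrapped diversity, and a mock-recovery evaluation.
#'
#' @param experiment output of [simulate_mock_experiment()].
#' @param config a [pipeline_config()].
#' @param outdir optional directory for the stage reports (created if
#'   needed); `NULL` skips writing.
#' @return a `pipeline_result` list; see elements `otu_table`,
#'   `screen`, `member_percent`, `mock_eval`, `diversity`, `summary`.
#' @export
run_pipeline <- function(experiment, config = pipeline_config(),
                         outdir = NULL) {
  pp <- experiment$primers
  models <- build_pipeline_models(experiment, config)

  samples <- list()
  logs <- list()
  for (r in seq_along(experiment$run)) {
    sname <- sprintf("rep%d", r)
    rep <- experiment$run[[r]]
    n_in <- length(rep$fwd)
    mg <- merge_sample(rep$fwd, rep$rev, config)
    trimmed <- list(); n_trim_rej <- 0L
    for (ct in mg$merged) {
      tr <- trim_primers(ct, pp$fwd, pp$rev, config$trim_max_mismatches)
      if (tr$status == "trimmed") trimmed[[length(trimmed) + 1L]] <- tr$insert
      else n_trim_rej <- n_trim_rej + 1L
    }
    qpass <- Filter(function(x)
      quality_filter(x, config$max_expected_errors), trimmed)
    flt <- hmm_filter(qpass, models$nuc, config$accept_bits)
    samples[[sname]] <- flt$kept
    logs[[sname]] <- stage_counts(
      input_pairs = n_in, merged = length(mg$merged),
      trimmed = length(trimmed), quality_passed = length(qpass),
      hmm_kept = length(flt$kept))
  }

  all_contigs <- unlist(samples, recursive = FALSE)
  uniques <- remove_singletons(dereplicate(all_contigs))
  otus <- cluster_otus(uniques, config$otu_radius)
  if (!length(otus)) stop("pipeline: no OTUs formed")
  table <- map_reads(samples, otus, config$map_identity)

  # frameshift-corrected translation of OTU representatives
  protein_refs <- unname(experiment$families$nifH)
  frames <- lapply(otus, function(ot)
    framebot_align(ot$centroid, protein_refs,
                   frameshift_penalty = config$frameshift_penalty,
                   gap_open = config$gap_open, gap_ext = config$gap_ext,
                   min_identity = config$framebot_min_identity,
                   min_aligned = config$framebot_min_aligned))
  otus_aa <- lapply(frames, function(fr)
    seq_record(fr$query_id, fr$corrected_aa, "amino-acid"))
  names(otus_aa) <- vapply(otus, `[[`, "", "otu_id")

  scr <- screen_homologs(otus_aa, models$aa, table, nifh_name = "nifH")

  labeled_refs <- make_labeled_refs(experiment)
  taxonomy <- lapply(otus_aa[scr$retained], classify_besthit,
                     labeled_refs = labeled_refs)

  # decision tree over model-aligned reference rows
  ref_rows <- vapply(experiment$families$nifH, function(p)
    align_to_model(models$aa[["nifH"]], p), "")
  tree <- train_cluster_tree(ref_rows,
                             experiment$cluster_labels[names(ref_rows)],
                             config$cart_max_depth, config$cart_min_leaf)
  clusters <- lapply(otus_aa[scr$retained], function(rec) {
    al <- align_to_model(models$aa[["nifH"]], rec)
    list(cart = assign_cluster(tree, al),
         placement = place_nearest(ref_rows,
                                   experiment$cluster_labels[names(ref_rows)],
                                   al))
  })

  retained_counts <- table$otus[scr$retained, , drop = FALSE]
  diversity <- bootstrap_diversity(retained_counts,
                                   iterations = config$diversity_iterations,
                                   drop_percentile = config$drop_percentile,
                                   seed = config$seed)

  # mock recovery: member percentages from truth-linked OTU assignment
  member_percent <- member_recovery(experiment, table)
  mock_eval <- evaluate_mock(
    setNames(member_percent$reads, member_percent$member), experiment$spec)

  summary <- do.call(rbind, lapply(names(logs), function(s) {
    lg <- logs[[s]]
    data.frame(sample = s, t(setNames(lg$count, lg$stage)),
               mapped = sum(table$otus[, s]), unmapped = table$unmapped[[s]])
  }))

  result <- structure(list(
    config = config, models = models, otu_table = table, frames = frames,
    otus_aa = otus_aa, screen = scr, taxonomy = taxonomy, tree = tree,
    clusters = clusters, diversity = diversity,
    member_percent = member_percent, mock_eval = mock_eval,
    summary = summary), class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  result
}

build_pipeline_models <- function(experiment, config) {
  nuc <- build_hmm(experiment$nuc_ref_msa, "nifH_nuc")
  aa <- list(
    nifH = build_hmm(unname(experiment$families$nifH), "nifH"),
    bchX = build_hmm(unname(experiment$families$bchX), "bchX"),
    `chlL-bchL` = build_hmm(unname(experiment$families$chlL_bchL),
                            "chlL-bchL"))
  list(nuc = nuc, aa = aa)
}

make_labeled_refs <- function(experiment) {
  labs <- experiment$cluster_labels
  refs <- lapply(names(experiment$families$nifH), function(id)
    seq_record(paste(id, "Bacteria;nifH", labs[[id]], sep = "|"),
               experiment$families$nifH[[id]]$residues, "amino-acid"))
  homs <- lapply(c(experiment$families$bchX, experiment$families$chlL_bchL),
                 function(p)
                   seq_record(paste(p$id, "Bacteria;homolog", "unassigned",
                                    sep = "|"),
                              p$residues, "amino-acid"))
  c(refs, unname(homs))
}

# per-member read recovery: link each member's clone insert to its OTU
member_recovery <- function(experiment, table) {
  members <- experiment$spec$members
  total_mapped <- sum(table$otus)
  # map member -> OTU by aligning its clone insert to centroids
  out <- lapply(members, function(m) {
    cl <- experiment$clones[[m]]
    insert <- substr(cl$residues, attr(cl, "insert_start"),
                     attr(cl, "insert_end"))
    ids <- vapply(table$centroids, function(ct)
      pairwise_identity(insert, ct$centroid$residues), numeric(1))
    k <- which.max(ids)
    otu <- if (ids[k] >= 0.97) table$centroids[[k]]$otu_id else NA_character_
    reads <- if (!is.na(otu)) sum(table$otus[otu, ]) else 0
    data.frame(member = m, otu = otu,
               reads = reads,
               percent = 100 * reads / max(total_mapped, 1))
  })
  do.call(rbind, out)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("%d OTUs, %d retained as nifH\n", nrow(x$otu_table$otus),
              length(x$screen$retained)))
  print(x$member_percent, row.names = FALSE)
  invisible(x)
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(result$summary, file.path(outdir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_otu_table(result$otu_table, file.path(outdir, "otu_table.tsv"))
  write_fasta(lapply(result$otu_table$centroids, `[[`, "centroid"),
              file.path(outdir, "otu_centroids.fasta"))
  write_fasta(unname(result$otus_aa),
              file.path(outdir, "otu_proteins.fasta"))
  utils::write.table(result$screen$verdicts,
                     file.path(outdir, "homolog_verdicts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_contamination_tsv(result$screen$report,
                          file.path(outdir, "contamination.tsv"))
  utils::write.table(result$diversity, file.path(outdir, "diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$member_percent,
                     file.path(outdir, "mock_recovery.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_pipeline_config(result$config, file.path(outdir, "config.R"))
  invisible(outdir)
}
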