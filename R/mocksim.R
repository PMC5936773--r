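# Synthetic data generator: homolog protein families with controlled
# divergence, reverse-translated amplicons carrying primer sites,
# even/tiered mock pools, MiSeq-like paired reads, chimeras, and labeled
# reference alignments for HMM/CART training. Everything is deterministic
# under a fixed seed (R's Mersenne-Twister, integer residue sampling).

#' Simulation configuration
#'
#' Defaults emulate the mock-community experiment the package is designed
#' to benchmark: six community members, a ~150-aa nifH fragment (the
#' scale of a broad-coverage forward/reverse primer amplicon), 2x300
#' paired reads, and even (1/6 each) or tiered (10/20/40/5/20/5 percent)
#' pool designs.
#'
#' @param seed integer seed controlling every random draw.
#' @param protein_length fragment length in amino acids (default 150).
#' @param within_divergence expected aa substitutions/site between a
#'   family member and the family ancestor (default 0.10).
#' @param between_divergence aa substitutions/site between family
#'   ancestors (default 0.45).
#' @param cluster_divergence aa substitutions/site between a nifH
#'   subcluster ancestor and the family ancestor (default 0.07); members
#'   diverge from their subcluster ancestor by the remainder of
#'   `within_divergence`.
#' @param nifh_clusters number of labeled nifH subclusters (default 4).
#' @param nifh_per_cluster nifH family members per subcluster (default 8).
#' @param homolog_family_size members per homolog family (default 20).
#' @param read_length read length in nt (default 300).
#' @param sub_error per-base substitution error rate (default 0.001).
#' @param indel_error per-base indel error rate (default 0).
#' @param members number of mock community members (default 6).
#' @param proportions named list of pool designs (`even`, `tiered`).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, protein_length = 150L,
                       within_divergence = 0.10, between_divergence = 0.45,
                       cluster_divergence = 0.07, nifh_clusters = 4L,
                       nifh_per_cluster = 8L, homolog_family_size = 20L,
                       read_length = 300L, sub_error = 0.001,
                       indel_error = 0, members = 6L,
                       proportions = list(
                         even = rep(1 / 6, 6),
                         tiered = c(0.10, 0.20, 0.40, 0.05, 0.20, 0.05))) {
  stopifnot(all(vapply(proportions, function(p)
    abs(sum(p) - 1) < 1e-9, logical(1))))
  structure(list(seed = as.integer(seed), protein_length = protein_length,
                 within_divergence = within_divergence,
                 between_divergence = between_divergence,
                 cluster_divergence = cluster_divergence,
                 nifh_clusters = nifh_clusters,
                 nifh_per_cluster = nifh_per_cluster,
                 homolog_family_size = homolog_family_size,
                 read_length = read_length, sub_error = sub_error,
                 indel_error = indel_error, members = members,
                 proportions = proportions),
            class = "sim_config")
}

mutate_aa <- function(chars, divergence) {
  n <- length(chars)
  k <- round(divergence * n)
  if (k == 0L) return(chars)
  pos <- sample.int(n, k)
  for (p in pos) {
    alt <- AA20[AA20 != chars[p]]
    chars[p] <- alt[sample.int(length(alt), 1L)]
  }
  chars
}

mean_pairwise_identity <- function(rows_a, rows_b = NULL) {
  ids <- c()
  if (is.null(rows_b)) {
    n <- length(rows_a)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      ids <- c(ids, mean(rows_a[[i]] == rows_a[[j]]))
  } else {
    for (a in rows_a) for (b in rows_b) ids <- c(ids, mean(a == b))
  }
  mean(ids)
}

#' Simulate nifH and homolog protein families
#'
#' Star-phylogeny families: a random ancestor per family (family
#' ancestors separated by the configured between-family divergence from a
#' common root), members mutated independently from the ancestor. The
#' nifH family is subdivided into labeled subclusters via intermediate
#' subcluster ancestors so the labels are learnable from sequence. The
#' draw is resampled (up to 100 times) until the mean within-family
#' identity exceeds the mean between-family identity by at least 0.15.
#' Because the star phylogeny introduces no indels, each family's true
#' MSA is the family itself.
#'
#' @param cfg a [sim_config()].
#' @return list with `families` (named list of aa [seq_record()] lists
#'   for `nifH`, `bchX`, `chlL_bchL`), `cluster_labels` (named vector for
#'   nifH members), and `identity` (within/between summary).
#' @export
simulate_families <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  P <- cfg$protein_length
  member_div <- max(cfg$within_divergence - cfg$cluster_divergence, 0.01)
  for (attempt in seq_len(100L)) {
    root <- AA20[sample.int(20L, P, replace = TRUE)]
    anc <- list(nifH = mutate_aa(root, cfg$between_divergence / 2),
                bchX = mutate_aa(root, cfg$between_divergence / 2),
                chlL_bchL = mutate_aa(root, cfg$between_divergence / 2))
    fams <- list()
    labels <- character()
    # nifH: subcluster ancestors, then members
    cl_names <- c("IA", "IB", "IG", "IJ", "IIIC", "IIIE", "IVA", "IVB",
                  "II", "IK")[seq_len(cfg$nifh_clusters)]
    nifh <- list()
    for (ci in seq_len(cfg$nifh_clusters)) {
      canc <- mutate_aa(anc$nifH, cfg$cluster_divergence)
      for (m in seq_len(cfg$nifh_per_cluster)) {
        id <- sprintf("nifH_%s_%02d", cl_names[ci], m)
        nifh[[id]] <- mutate_aa(canc, member_div)
        labels[id] <- cl_names[ci]
      }
    }
    fams$nifH <- nifh
    for (fam in c("bchX", "chlL_bchL")) {
      fm <- list()
      for (m in seq_len(cfg$homolog_family_size)) {
        id <- sprintf("%s_%02d", fam, m)
        fm[[id]] <- mutate_aa(anc[[fam]], cfg$within_divergence)
      }
      fams[[fam]] <- fm
    }
    within <- mean(vapply(fams, mean_pairwise_identity, numeric(1)))
    between <- mean(c(
      mean_pairwise_identity(fams$nifH, fams$bchX),
      mean_pairwise_identity(fams$nifH, fams$chlL_bchL),
      mean_pairwise_identity(fams$bchX, fams$chlL_bchL)))
    if (within - between >= 0.15) {
      out <- lapply(names(fams), function(fn)
        lapply(names(fams[[fn]]), function(id)
          seq_record(id, paste(fams[[fn]][[id]], collapse = ""),
                     "amino-acid")))
      names(out) <- names(fams)
      for (fn in names(out))
        names(out[[fn]]) <- vapply(out[[fn]], `[[`, "", "id")
      return(list(families = out, cluster_labels = labels,
                  identity = c(within = within, between = between,
                               margin = within - between)))
    }
  }
  stop("simulate_families: identity margin unsatisfiable after 100 resamples")
}

CODONS_BY_AA <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc_tab <- Biostrings::GENETIC_CODE
      cache <<- split(names(gc_tab), unname(gc_tab))
    }
    cache
  }
})

#' Reverse-translate a protein into a primered amplicon
#'
#' Uniform random synonymous codon choice; the 5' terminus is a random
#' concrete expansion of the forward primer and the 3' terminus the
#' reverse complement of a random expansion of the reverse primer, so
#' [trim_primers()] recovers the insert exactly and translating the
#' insert reproduces the protein.
#'
#' @param protein amino-acid [seq_record()] or string.
#' @param fwd_primer,rev_primer [primer_spec()]s.
#' @return nucleotide [seq_record()] of the full amplicon, with
#'   attributes `insert_start`/`insert_end` (1-based) recording the
#'   insert coordinates.
#' @export
make_clone <- function(protein, fwd_primer, rev_primer) {
  p <- as_seqchar(protein)
  aa <- strsplit(p$residues, "")[[1]]
  tabs <- CODONS_BY_AA()
  cds <- vapply(aa, function(a) {
    cods <- tabs[[a]]
    if (is.null(cods)) stop("make_clone: no codon for residue ", a)
    cods[sample.int(length(cods), 1L)]
  }, "")
  fwd_site <- sample(expand_iupac(fwd_primer), 1L)
  rev_site <- revcomp(sample(expand_iupac(rev_primer), 1L))
  amp <- paste0(fwd_site, paste(cds, collapse = ""), rev_site)
  out <- seq_record(p$id, amp, "nucleotide")
  attr(out, "insert_start") <- nchar(fwd_site) + 1L
  attr(out, "insert_end") <- nchar(amp) - nchar(rev_site)
  out
}

exact_counts <- function(total, props) {
  # largest-remainder rounding to the declared proportions
  raw <- total * props
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

apply_read_errors <- function(chars, sub_error, indel_error) {
  bases <- c("A", "C", "G", "T")
  n <- length(chars)
  if (sub_error > 0) {
    hit <- runif(n) < sub_error
    for (i in which(hit)) {
      alt <- bases[bases != chars[i]]
      chars[i] <- alt[sample.int(3L, 1L)]
    }
  }
  if (indel_error > 0) {
    out <- character(0)
    for (i in seq_len(n)) {
      r <- runif(1)
      if (r < indel_error / 2) {
        # deletion: skip the base
      } else if (r < indel_error) {
        out <- c(out, chars[i], bases[sample.int(4L, 1L)])
      } else {
        out <- c(out, chars[i])
      }
    }
    chars <- out
  }
  chars
}

#' Simulate a paired-end sequencing run of a mock pool
#'
#' Draws read pairs per member either with exact largest-remainder counts
#' (`exact = TRUE`, making downstream proportions deterministic) or
#' multinomially; applies substitution/indel errors per base; assigns a
#' flat Phred quality consistent with the substitution rate.
#'
#' @param clones named list of amplicon [seq_record()]s (from
#'   [make_clone()]), one per member.
#' @param spec a [mock_spec()] over the clone names.
#' @param depth_total total read pairs per replicate.
#' @param cfg a [sim_config()] (read length and error rates).
#' @param replicates number of replicate libraries (default 1).
#' @param exact exact member counts instead of multinomial (default TRUE).
#' @return list of replicates, each with `fwd`, `rev` (lists of
#'   [seq_record()]s) and `truth` (data.frame read_id, member).
#' @export
simulate_run <- function(clones, spec, depth_total, cfg = sim_config(),
                         replicates = 1L, exact = TRUE) {
  stopifnot(all(spec$members %in% names(clones)))
  q <- if (cfg$sub_error > 0)
    min(40L, as.integer(round(-10 * log10(cfg$sub_error)))) else 40L
  lapply(seq_len(replicates), function(rep_i) {
    counts <- if (exact) exact_counts(depth_total, spec$proportions)
    else as.integer(rmultinom(1, depth_total, spec$proportions))
    fwd <- list(); rev <- list(); truth <- list()
    for (mi in seq_along(spec$members)) {
      member <- spec$members[mi]
      amp <- clones[[member]]$residues
      for (k in seq_len(counts[mi])) {
        rid <- sprintf("%s_r%d_%04d", member, rep_i, k)
        tpl <- strsplit(amp, "")[[1]]
        tpl <- apply_read_errors(tpl, cfg$sub_error, cfg$indel_error)
        n <- length(tpl)
        rl <- min(cfg$read_length, n)
        f <- paste(tpl[1:rl], collapse = "")
        r <- revcomp(paste(tpl[(n - rl + 1L):n], collapse = ""))
        fwd[[length(fwd) + 1L]] <-
          seq_record(rid, f, "nucleotide", quality = rep(q, nchar(f)))
        rev[[length(rev) + 1L]] <-
          seq_record(rid, r, "nucleotide", quality = rep(q, nchar(r)))
        truth[[length(truth) + 1L]] <-
          data.frame(read_id = rid, member = member)
      }
    }
    list(fwd = fwd, rev = rev, truth = do.call(rbind, truth))
  })
}

#' Construct two-parent chimeric amplicons
#'
#' The chimera takes the first `breakpoint_fraction` of `clone_a` and the
#' remainder of `clone_b` (fraction 1 reproduces `clone_a`, 0 reproduces
#' `clone_b`).
#'
#' @param clone_a,clone_b nucleotide [seq_record()]s of equal scale.
#' @param breakpoint_fraction position of the crossover in \[0, 1\].
#' @param n number of copies to emit.
#' @return list of chimeric [seq_record()]s.
#' @export
make_chimeras <- function(clone_a, clone_b, breakpoint_fraction = 0.5,
                          n = 1L) {
  la <- nchar(clone_a$residues)
  k <- round(breakpoint_fraction * la)
  left <- if (k >= 1) substr(clone_a$residues, 1, k) else ""
  right <- if (k < nchar(clone_b$residues))
    substr(clone_b$residues, k + 1L, nchar(clone_b$residues)) else ""
  ch <- paste0(left, right)
  lapply(seq_len(n), function(i)
    seq_record(sprintf("chimera_%s_%s_%02d", clone_a$id, clone_b$id, i),
               ch, "nucleotide"))
}

#' One-call synthetic mock experiment
#'
#' Generates the full benchmark bundle: protein families and labeled
#' reference alignments, six mock clones (pairwise nucleotide identity
#' verified below the clustering threshold), primered amplicons, and an
#' error-model paired-read run of the chosen pool design. Optionally a
#' homolog (bchX-like) member is spiked into the pool to exercise the
#' arbitration stage.
#'
#' @param preset `"even"` or `"tiered"`.
#' @param cfg a [sim_config()]; its seed drives everything.
#' @param depth_total total read pairs (default 600).
#' @param replicates replicate libraries (default 1).
#' @param exact exact member counts (default TRUE).
#' @param primer_pair primer pair name (default `"Ueda19F-R6"`).
#' @param spikein_fraction proportion of reads drawn from a bchX-like
#'   member (default 0: none).
#' @return list: `cfg`, `families`, `cluster_labels`, `clones`, `spec`,
#'   `run` (replicate list from [simulate_run()]), `primers`,
#'   `nuc_ref_msa` (nucleotide reference alignment of the nifH family
#'   inserts), `spiked_member` (name or NA).
#' @export
simulate_mock_experiment <- function(preset = c("even", "tiered"),
                                     cfg = sim_config(), depth_total = 600L,
                                     replicates = 1L, exact = TRUE,
                                     primer_pair = "Ueda19F-R6",
                                     spikein_fraction = 0) {
  preset <- match.arg(preset)
  fams <- simulate_families(cfg)   # seeds the RNG stream
  pp <- resolve_primer_pair(primer_pair)

  # nucleotide reference MSA: reverse-translated nifH family inserts
  # (independent codon draws; star phylogeny means no gaps)
  nuc_ref_msa <- lapply(fams$families$nifH, function(p) {
    cl <- make_clone(p, pp$fwd, pp$rev)
    seq_record(p$id, substr(cl$residues, attr(cl, "insert_start"),
                            attr(cl, "insert_end")), "nucleotide")
  })

  # mock members: one clone from each of the first `members` nifH records,
  # spread across subclusters; verify pairwise nucleotide separation
  cl_labels <- fams$cluster_labels
  pick <- character(0)
  per_cluster <- ceiling(cfg$members / length(unique(cl_labels)))
  for (lab in unique(cl_labels)) {
    in_cl <- names(cl_labels)[cl_labels == lab]
    pick <- c(pick, in_cl[seq_len(min(per_cluster, length(in_cl)))])
  }
  pick <- pick[seq_len(cfg$members)]
  clones <- lapply(fams$families$nifH[pick], make_clone, fwd_primer = pp$fwd,
                   rev_primer = pp$rev)
  ins <- lapply(clones, function(cl)
    substr(cl$residues, attr(cl, "insert_start"), attr(cl, "insert_end")))
  for (i in seq_len(length(ins) - 1L)) for (j in (i + 1L):length(ins)) {
    pid <- pairwise_identity(ins[[i]], ins[[j]])
    if (pid >= 0.97)
      stop("simulate_mock_experiment: clones ", i, " and ", j,
           " at ", round(100 * pid, 1), "% nucleotide identity")
  }

  props <- cfg$proportions[[preset]][seq_len(cfg$members)]
  members <- names(clones)
  spiked <- NA_character_
  if (spikein_fraction > 0) {
    spk <- fams$families$bchX[[1]]
    spk_clone <- make_clone(spk, pp$fwd, pp$rev)
    spiked <- spk_clone$id
    clones[[spiked]] <- spk_clone
    props <- c(props * (1 - spikein_fraction), spikein_fraction)
    members <- c(members, spiked)
  }
  spec <- mock_spec(members, props)
  run <- simulate_run(clones, spec, depth_total, cfg, replicates, exact)
  list(cfg = cfg, families = fams$families,
       cluster_labels = fams$cluster_labels, clones = clones, spec = spec,
       run = run, primers = pp, nuc_ref_msa = nuc_ref_msa,
       spiked_member = spiked)
}
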