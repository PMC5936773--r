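aa_letters <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

fake_otu_table <- function(counts) {
  # counts: named matrix otu x sample
  structure(list(otus = counts, centroids = list(),
                 samples = colnames(counts),
                 unmapped = setNames(rep(0L, ncol(counts)),
                                     colnames(counts))),
            class = "otu_table")
}

two_family_models <- function(seed = 60) {
  set.seed(seed)
  a <- rand_seq(40, aa_letters)
  achars <- strsplit(a, "")[[1]]
  bchars <- achars
  pos <- sample(40, 18)
  for (p in pos) bchars[p] <- sample(setdiff(aa_letters, bchars[p]), 1)
  fam_a <- lapply(1:8, function(i) {
    ch <- achars; mut <- sample(40, 4)
    for (p in mut) ch[p] <- sample(setdiff(aa_letters, ch[p]), 1)
    seq_record(paste0("a", i), paste(ch, collapse = ""), "amino-acid")
  })
  fam_b <- lapply(1:8, function(i) {
    ch <- bchars; mut <- sample(40, 4)
    for (p in mut) ch[p] <- sample(setdiff(aa_letters, ch[p]), 1)
    seq_record(paste0("b", i), paste(ch, collapse = ""), "amino-acid")
  })
  list(nifH = build_hmm(fam_a, "nifH"), bchX = build_hmm(fam_b, "bchX"),
       fam_a = fam_a, fam_b = fam_b)
}

test_that("screen_homologs weights verdicts by mapped reads", {
  mod <- two_family_models()
  otus_aa <- list(OTU_1 = mod$fam_a[[1]], OTU_2 = mod$fam_b[[1]])
  counts <- matrix(c(1L, 9L), 2, 1,
                   dimnames = list(c("OTU_1", "OTU_2"), "s1"))
  tab <- fake_otu_table(counts)
  scr <- screen_homologs(otus_aa, list(mod$nifH, mod$bchX), tab)
  expect_equal(scr$verdicts$label, c("nifH", "bchX"))
  expect_equal(scr$retained, "OTU_1")
  p <- scr$report$per_sample[[1]]
  expect_equal(p$reads_non_nifh, 0.9)
  expect_equal(p$otus_non_nifh, 0.5)

  # all-nifH input: zero contamination everywhere
  otus_all <- list(OTU_1 = mod$fam_a[[1]], OTU_2 = mod$fam_a[[2]])
  scr2 <- screen_homologs(otus_all, list(mod$nifH, mod$bchX), tab)
  expect_equal(scr2$report$per_sample[[1]]$reads_non_nifh, 0)

  # fractions sum to one (reads and OTUs separately)
  expect_equal(sum(scr$report$per_sample[[1]]$breakdown), 1)

  expect_error(screen_homologs(otus_aa, list(mod$bchX), tab),
               "missing model")
})

test_that("arbitration is invariant to model list order and ties exclude", {
  mod <- two_family_models(61)
  otus_aa <- list(OTU_1 = mod$fam_a[[2]])
  counts <- matrix(5L, 1, 1, dimnames = list("OTU_1", "s1"))
  tab <- fake_otu_table(counts)
  s1 <- screen_homologs(otus_aa, list(mod$nifH, mod$bchX), tab)
  s2 <- screen_homologs(otus_aa, list(mod$bchX, mod$nifH), tab)
  expect_equal(s1$verdicts$label, s2$verdicts$label)
  expect_equal(s1$retained, s2$retained)

  # an exact tie (duplicate model under both names) is undetermined
  nifH_dup <- mod$bchX; nifH_dup$name <- "nifH"
  s3 <- screen_homologs(otus_aa, list(nifH_dup, mod$bchX), tab)
  expect_equal(s3$verdicts$label, "undetermined")
  expect_length(s3$retained, 0)
})

test_that("classify_besthit finds the reference and breaks ties by id", {
  set.seed(62)
  refs <- lapply(1:4, function(i)
    seq_record(sprintf("ref%d|Lineage%d|IA", i, i),
               paste(sample(aa_letters, 30, replace = TRUE), collapse = ""),
               "amino-acid"))
  q <- refs[[2]]$residues
  ta <- classify_besthit(q, refs)
  expect_equal(ta$best_ref_id, "ref2")
  expect_equal(ta$taxon_label, "Lineage2")
  expect_equal(ta$cluster_label, "IA")
  expect_equal(ta$percent_identity, 100)
  expect_false(ta$tie)

  dup <- list(seq_record("zz|L|IA", q, "amino-acid"),
              seq_record("aa|L|IA", q, "amino-acid"))
  tie <- classify_besthit(q, dup)
  expect_equal(tie$best_ref_id, "aa")
  expect_true(tie$tie)
  expect_error(classify_besthit(q, list()), "empty")
})

test_that("best-hit scores agree with the exhaustive local oracle", {
  set.seed(63)
  B <- nifamp:::blosum62()
  for (rep in 1:5) {
    q <- paste(sample(aa_letters, sample(6:9, 1), replace = TRUE),
               collapse = "")
    refs <- lapply(1:3, function(i)
      seq_record(paste0("r", i),
                 paste(sample(aa_letters, sample(6:10, 1), replace = TRUE),
                       collapse = ""), "amino-acid"))
    oracle_scores <- vapply(refs, function(r)
      local_align_oracle(q, r$residues, B), numeric(1))
    ta <- classify_besthit(q, refs)
    best <- order(-oracle_scores, vapply(refs, `[[`, "", "id"))[1]
    expect_equal(ta$best_ref_id, refs[[best]]$id)
    expect_equal(ta$bit_score, max(oracle_scores), tolerance = 1e-9)
  }
})

test_that("train_cluster_tree separates a single-column toy perfectly", {
  rows <- c("AAAAKAAAA", "CAAAKAACA", "AAAARAAAA", "ACAARAAAA")
  labels <- c("A", "A", "B", "B")
  tree <- train_cluster_tree(rows, labels)
  expect_equal(nifamp:::tree_depth(tree$root), 1)
  expect_equal(tree$root$col, 5)
  for (i in seq_along(rows))
    expect_equal(assign_cluster(tree, rows[i])$label, labels[i])

  leaf <- train_cluster_tree(rows, rep("X", 4))
  expect_true(leaf$root$leaf)
  expect_equal(assign_cluster(leaf, rows[1])$label, "X")
})

test_that("gaps fail every subset test and all-gap rows are flagged", {
  rows <- c("KKKK", "KKKK", "RRRR", "RRRR")
  labels <- c("A", "A", "B", "B")
  tree <- train_cluster_tree(rows, labels)
  res <- assign_cluster(tree, "----")
  expect_true(res$low_confidence)
  # the all-gap query descends through "no" branches to a leaf
  expect_true(res$label %in% c("A", "B"))
  expect_error(assign_cluster(tree, "KK"), "length")
})

test_that("held-out accuracy on simulated labeled clusters is high", {
  cfg <- sim_config(seed = 64, nifh_per_cluster = 20L)
  fam <- simulate_families(cfg)
  labs <- fam$cluster_labels
  rows <- vapply(fam$families$nifH, `[[`, "", "residues")
  set.seed(65)
  test_idx <- unlist(lapply(unique(labs), function(l)
    sample(which(labs == l), 5)))
  train_idx <- setdiff(seq_along(rows), test_idx)
  tree <- train_cluster_tree(rows[train_idx], labs[train_idx])
  pred <- vapply(rows[test_idx], function(r)
    assign_cluster(tree, r)$label, "")
  expect_gte(mean(pred == labs[test_idx]), 0.9)
})

test_that("place_nearest uses comparable columns with a floor", {
  set.seed(66)
  refs <- vapply(1:5, function(i)
    paste(sample(aa_letters, 30, replace = TRUE), collapse = ""), "")
  labels <- paste0("L", 1:5)
  res <- place_nearest(refs, labels, refs[3])
  expect_equal(res$nearest, 3)
  expect_equal(res$distance, 0)
  expect_equal(res$label, "L3")

  sparse <- paste0(substr(refs[3], 1, 10), strrep("-", 20))
  res2 <- place_nearest(refs, labels, sparse)
  expect_equal(res2$label, "unassigned")
})
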