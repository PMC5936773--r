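test_that("dereplicate groups exact duplicates and conserves counts", {
  recs <- make_msa(list("AAAA", "AAAA", "CCCC"))
  uq <- dereplicate(recs)
  expect_equal(uq$residues, c("AAAA", "CCCC"))
  expect_equal(uq$count, c(2L, 1L))
  expect_equal(uq$member_ids[[1]], c("s1", "s2"))

  expect_equal(nrow(dereplicate(list())), 0)

  set.seed(40)
  recs2 <- make_msa(as.list(sample(c("AC", "GT", "AC", "AC", "TT"), 30,
                                   replace = TRUE)))
  expect_equal(sum(dereplicate(recs2)$count), 30)
  # ties in count broken lexicographically
  tie <- dereplicate(make_msa(list("TT", "AA")))
  expect_equal(tie$residues, c("AA", "TT"))
})

test_that("remove_singletons drops count-1 uniques only", {
  uq <- dereplicate(make_msa(list("AAAA", "AAAA", "CCCC")))
  expect_equal(remove_singletons(uq)$residues, "AAAA")
  all_single <- dereplicate(make_msa(list("AA", "CC")))
  expect_equal(nrow(remove_singletons(all_single)), 0)
  no_single <- dereplicate(make_msa(list("AA", "AA", "CC", "CC")))
  expect_equal(remove_singletons(no_single), no_single)
})

test_that("pairwise_identity matches hand values and the exhaustive oracle", {
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT"), 1.0)
  expect_equal(pairwise_identity("ACGT", "ACGA"), 0.75)
  expect_error(pairwise_identity("", "ACGT"), "empty")

  # oracle agreement: all pairs over {A, C} up to length 3, plus sampled
  # longer pairs up to length 6
  strings <- unlist(lapply(1:3, function(n)
    apply(do.call(expand.grid, rep(list(c("A", "C")), n)), 1, paste,
          collapse = "")))
  pairs <- expand.grid(a = strings, b = strings, stringsAsFactors = FALSE)
  set.seed(41)
  longer <- replicate(40, list(a = rand_seq(sample(4:6, 1), c("A", "C")),
                               b = rand_seq(sample(4:6, 1), c("A", "C"))),
                      simplify = FALSE)
  cases <- c(split(pairs, seq_len(nrow(pairs))), longer)
  for (cs in cases) {
    o <- align_enumerate(cs$a, cs$b)
    got <- pairwise_identity(cs$a, cs$b)
    expect_true(any(abs(o$identities - got) < 1e-9),
                info = paste(cs$a, cs$b, got,
                             paste(o$identities, collapse = "/")))
  }
})

make_divergent_pair <- function(n = 200L, divergence = 0.10) {
  a <- rand_seq(n)
  chars <- strsplit(a, "")[[1]]
  pos <- sample(n, round(divergence * n))
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                            chars[p]), 1)
  list(a = a, b = paste(chars, collapse = ""))
}

test_that("detect_chimera flags two-parent crossovers only", {
  set.seed(42)
  pr <- make_divergent_pair(200, 0.10)          # parents ~90% identical
  expect_lt(pairwise_identity(pr$a, pr$b), 0.97)
  p1 <- nifamp:::new_otu_record("OTU_1", seq_record("OTU_1", pr$a,
                                                    "nucleotide"), 50L)
  p2 <- nifamp:::new_otu_record("OTU_2", seq_record("OTU_2", pr$b,
                                                    "nucleotide"), 50L)
  chim <- paste0(substr(pr$a, 1, 100), substr(pr$b, 101, 200))
  q <- list(residues = chim, count = 5L)
  expect_true(detect_chimera(q, list(p1, p2)))

  ident <- list(residues = pr$a, count = 5L)    # identical to a centroid
  expect_false(detect_chimera(ident, list(p1, p2)))

  expect_false(detect_chimera(q, list(p1)))     # < 2 centroids

  # parents must be at least twice as abundant
  q_big <- list(residues = chim, count = 40L)
  expect_false(detect_chimera(q_big, list(p1, p2)))
})

test_that("cluster_otus is a greedy radius clustering with chimera removal", {
  set.seed(43)
  pr <- make_divergent_pair(200, 0.10)
  recs <- c(rep(list(pr$a), 6), rep(list(pr$b), 4))
  uq <- dereplicate(make_msa(recs))
  otus <- cluster_otus(uq)
  expect_length(otus, 2)

  dup <- dereplicate(make_msa(rep(list(pr$a), 5)))
  expect_length(cluster_otus(dup), 1)

  # a chimera of the two abundant parents founds no OTU
  chim <- paste0(substr(pr$a, 1, 100), substr(pr$b, 101, 200))
  recs3 <- c(rep(list(pr$a), 10), rep(list(pr$b), 8), rep(list(chim), 2))
  otus3 <- cluster_otus(dereplicate(make_msa(recs3)))
  expect_length(otus3, 2)

  # centroid separation: all centroid pairs below the radius threshold
  for (i in seq_along(otus3)) for (j in seq_len(i - 1))
    expect_lt(pairwise_identity(otus3[[i]]$centroid$residues,
                                otus3[[j]]$centroid$residues), 0.97)
})

test_that("map_reads assigns by best identity and conserves counts", {
  set.seed(44)
  pr <- make_divergent_pair(200, 0.10)
  cents <- list(
    nifamp:::new_otu_record("OTU_1", seq_record("OTU_1", pr$a, "nucleotide"), 5L),
    nifamp:::new_otu_record("OTU_2", seq_record("OTU_2", pr$b, "nucleotide"), 5L))
  far <- make_divergent_pair(200, 0.30)$b       # < 95% to both centroids
  samples <- list(
    s1 = make_msa(c(rep(list(pr$a), 3), list(far))),
    s2 = make_msa(rep(list(pr$b), 2)))
  tab <- map_reads(samples, cents)
  expect_equal(unname(tab$otus[, "s1"]), c(3L, 0L))
  expect_equal(unname(tab$otus[, "s2"]), c(0L, 2L))
  expect_equal(unname(tab$unmapped), c(1L, 0L))
  # conservation per sample
  expect_equal(colSums(tab$otus) + tab$unmapped,
               c(s1 = 4, s2 = 2))
})

test_that("clustering is deterministic on identical input", {
  set.seed(45)
  seqs <- c(replicate(4, make_divergent_pair(150, 0.12)$a),
            replicate(2, make_divergent_pair(150, 0.12)$b))
  recs <- make_msa(as.list(rep(seqs, times = 3)))
  u1 <- dereplicate(recs); u2 <- dereplicate(recs)
  expect_identical(u1, u2)
  o1 <- cluster_otus(u1); o2 <- cluster_otus(u2)
  expect_identical(vapply(o1, function(x) x$centroid$residues, ""),
                   vapply(o2, function(x) x$centroid$residues, ""))
})
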