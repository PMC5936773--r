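test_that("build_hmm assigns match states by gap fraction and normalises", {
  h <- build_hmm(make_msa(list("ACGTACG")), "single")
  expect_equal(h$L, 7)

  msa <- make_msa(list("ACGT", "A-GT", "A-GT", "A-GT"))  # col 2: 75% gaps
  h2 <- build_hmm(msa, "gappy")
  expect_equal(h2$L, 3)

  expect_true(all(abs(rowSums(h2$match_emissions) - 1) < 1e-9))
  expect_true(all(abs(rowSums(h2$insert_emissions) - 1) < 1e-9))
  expect_true(all(abs(rowSums(h2$transitions[, 1:3]) - 1) < 1e-9))
  expect_true(all(abs(rowSums(h2$transitions[, 4:5]) - 1) < 1e-9))
  expect_true(all(abs(rowSums(h2$transitions[, 6:7]) - 1) < 1e-9))
  expect_true(abs(sum(h2$background) - 1) < 1e-9)

  expect_error(build_hmm(make_msa(list("----", "----", "A---"))),
               "zero match columns")
})

test_that("forward and Viterbi equal the path-enumeration oracle", {
  set.seed(30)
  for (alphabet in c("nucleotide", "amino-acid")) {
    alpha <- if (alphabet == "nucleotide") c("A", "C", "G", "T") else
      strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (L in 2:4) {
      h <- random_hmm(L, nseq = 3L, alphabet = alphabet)
      for (n in c(1L, 3L, 5L)) {
        s <- rand_seq(n, alpha)
        eta <- flank_eta(n)
        oracle <- hmm_oracle_bits(h, strsplit(s, "")[[1]], eta)
        expect_equal(forward_bits(h, s)$bits, oracle$forward,
                     tolerance = 1e-9)
        expect_equal(viterbi(h, s)$bits, oracle$viterbi, tolerance = 1e-9)
      }
    }
  }
})

test_that("Viterbi bits never exceed forward bits", {
  set.seed(31)
  for (rep in 1:20) {
    h <- random_hmm(sample(2:6, 1), nseq = 4L)
    s <- rand_seq(sample(3:12, 1))
    expect_lte(viterbi(h, s)$bits, forward_bits(h, s)$bits + 1e-9)
  }
})

test_that("a background-identical degenerate model scores near zero", {
  # one free-entry match state emitting the background: every path's
  # emission odds are 1, so only the small length-model residue remains
  msa <- make_msa(list("A", "C", "G", "T"))
  h <- build_hmm(msa, "degenerate")
  expect_equal(h$L, 1)
  expect_true(all(abs(h$match_emissions - 0.25) < 1e-9))
  for (n in c(1, 5, 20)) {
    s <- rand_seq(n)
    expect_lt(abs(forward_bits(h, s)$bits), 2)
  }
})

test_that("probability over all sequences of a given length stays below 1", {
  set.seed(32)
  h <- random_hmm(2, nseq = 3L)
  eta <- 0.6
  for (n in 1:3) {
    seqs <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), n))
    tot <- sum(apply(seqs, 1, function(chars)
      hmm_enumerate(h, as.character(chars), eta)$total))
    expect_lte(tot, 1 + 1e-9)
    expect_gt(tot, 0)
  }
})

test_that("consensus of a peaked model aligns all-match; deletions emit gaps", {
  set.seed(33)
  cons <- rand_seq(20)
  h <- peaked_hmm(cons)
  v <- viterbi(h, cons)
  expect_equal(sum(v$path$state == "M"), 20)
  expect_equal(align_to_model(h, cons), cons)

  # drop two consensus positions -> exactly two gap columns
  chars <- strsplit(cons, "")[[1]]
  query <- paste(chars[-c(7, 13)], collapse = "")
  al <- align_to_model(h, query)
  expect_equal(nchar(al), 20)
  expect_equal(sum(strsplit(al, "")[[1]] == "-"), 2)

  # contract: output length is L for any input
  expect_equal(nchar(align_to_model(h, rand_seq(9))), 20)
})

test_that("hmm_filter keeps true amplicons and discards shuffles", {
  cfg <- sim_config(seed = 34, sub_error = 0)
  exp <- simulate_mock_experiment("even", cfg, depth_total = 60L)
  nuc <- build_hmm(exp$nuc_ref_msa, "nuc")
  inserts <- lapply(exp$clones, function(cl)
    seq_record(cl$id, substr(cl$residues, attr(cl, "insert_start"),
                             attr(cl, "insert_end")), "nucleotide"))
  flt <- hmm_filter(unname(inserts), nuc)
  expect_length(flt$kept, length(inserts))
  expect_length(flt$discarded, 0)

  set.seed(35)
  shuffled <- lapply(inserts, function(r)
    seq_record(r$id, shuffle_seq(r$residues), "nucleotide"))
  # score 30 shuffles (5 per clone) against the model
  many <- unlist(lapply(1:5, function(i) lapply(inserts, function(r)
    seq_record(r$id, shuffle_seq(r$residues), "nucleotide"))),
    recursive = FALSE)
  flt2 <- hmm_filter(many, nuc)
  expect_gte(length(flt2$discarded) / length(many), 0.95)

  empty <- hmm_filter(list(), nuc)
  expect_length(empty$kept, 0)
  expect_length(empty$discarded, 0)
})

test_that("hmm_scan ranks deterministically with name tie-breaks", {
  set.seed(36)
  h1 <- random_hmm(5, alphabet = "amino-acid", name = "alpha")
  h2 <- h1; h2$name <- "beta"
  s <- rand_seq(8, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  sc <- hmm_scan(s, list(h2, h1))
  expect_equal(sc[[1]]$model, "alpha")          # tie -> lexicographic
  expect_equal(sc[[1]]$bits, sc[[2]]$bits)
  single <- hmm_scan(s, list(h1))
  expect_equal(single[[1]]$model, "alpha")
  hn <- random_hmm(5, alphabet = "nucleotide")
  expect_error(hmm_scan(s, list(hn)), "not amino-acid")
})

test_that("model serialization round-trips and building is deterministic", {
  set.seed(37)
  msa_seqs <- replicate(5, rand_seq(15))
  h1 <- build_hmm(make_msa(msa_seqs), "m")
  h2 <- build_hmm(make_msa(msa_seqs), "m")
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_hmm(h1, f1); write_hmm(h2, f2)
  expect_identical(readLines(f1), readLines(f2))

  back <- read_hmm(f1)
  s <- rand_seq(12)
  expect_equal(forward_bits(back, s)$bits, forward_bits(h1, s)$bits,
               tolerance = 1e-9)

  expect_error(forward_bits(h1, ""), "empty")
})

test_that("ambiguity codes contribute odds one", {
  set.seed(38)
  h <- random_hmm(4, nseq = 4L)
  # an all-N sequence scores exactly like the empty-emission structure:
  # identical for any all-ambiguous sequence of the same length
  b1 <- forward_bits(h, "NNNN")$bits
  b2 <- forward_bits(h, "NNNN")$bits
  expect_equal(b1, b2)
  # an N at one position never changes the score more than the most
  # informative emission could
  s <- rand_seq(6)
  sN <- paste0(substr(s, 1, 3), "N", substr(s, 5, 6))
  expect_true(is.finite(forward_bits(h, sN)$bits))
})
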