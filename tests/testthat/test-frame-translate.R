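aa_alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n) paste(sample(aa_alpha, n, replace = TRUE),
                                    collapse = "")

reverse_translate <- function(protein) {
  tabs <- split(names(Biostrings::GENETIC_CODE),
                unname(Biostrings::GENETIC_CODE))
  paste(vapply(strsplit(protein, "")[[1]], function(a)
    sample(tabs[[a]], 1), ""), collapse = "")
}

test_that("translate_nt follows the standard code with frames and stops", {
  expect_equal(translate_nt("ATG"), "M")
  expect_equal(translate_nt("TAA"), "*")
  expect_equal(translate_nt("AATGGC", frame = 1), "M")  # tail dropped
  expect_equal(translate_nt("ATGNAA"), "MX")            # fuzzy codon -> X
  expect_error(translate_nt("AT"), "shorter")
})

test_that("an in-frame error-free CDS reduces to plain translation", {
  set.seed(50)
  prot <- random_protein(40)
  cds <- reverse_translate(prot)
  ref <- seq_record("ref1", prot, "amino-acid")
  fa <- framebot_align(cds, list(ref), min_aligned = 30L)
  expect_equal(fa$corrected_aa, prot)
  expect_equal(fa$corrected_aa, translate_nt(cds, 0))
  expect_equal(nrow(fa$frameshifts), 0)
  expect_equal(fa$identity, 1.0)
  expect_false(fa$no_frame)
})

test_that("a single inserted or deleted base is repaired to the protein", {
  set.seed(51)
  prot <- random_protein(40)
  cds <- reverse_translate(prot)
  mid <- 60L
  ins <- paste0(substr(cds, 1, mid), "G", substr(cds, mid + 1, nchar(cds)))
  ref <- seq_record("ref1", prot, "amino-acid")
  fa <- framebot_align(ins, list(ref), min_aligned = 30L)
  expect_equal(fa$corrected_aa, prot)
  expect_equal(nrow(fa$frameshifts), 1)
  expect_equal(fa$frameshifts$shift, 1)
  expect_lt(abs(fa$frameshifts$offset - mid), 4)

  del <- paste0(substr(cds, 1, mid), substr(cds, mid + 2, nchar(cds)))
  fa2 <- framebot_align(del, list(ref), min_aligned = 30L)
  expect_equal(fa2$corrected_aa, prot)
  expect_equal(nrow(fa2$frameshifts), 1)
  expect_equal(fa2$frameshifts$shift, -1)
})

test_that("the DP score equals exhaustive frameshift-placement search", {
  set.seed(52)
  B <- nifamp:::blosum62()
  for (rep in 1:6) {
    m <- sample(3:5, 1)
    prot <- random_protein(m)
    # query: CDS with a random single-base edit (or none)
    cds <- reverse_translate(prot)
    kind <- sample(c("none", "ins", "del"), 1)
    if (kind == "ins") {
      k <- sample(nchar(cds), 1)
      cds <- paste0(substr(cds, 1, k), sample(c("A", "C", "G", "T"), 1),
                    substr(cds, k + 1, nchar(cds)))
    } else if (kind == "del") {
      k <- sample(nchar(cds) - 1, 1)
      cds <- paste0(substr(cds, 1, k), substr(cds, k + 2, nchar(cds)))
    }
    oracle <- framebot_enumerate(cds, prot, B)
    expect_equal(framebot_score_raw(cds, prot), oracle, tolerance = 1e-9,
                 info = paste(kind, cds, prot))
  }
})

test_that("with an infinite frameshift penalty the DP is protein alignment", {
  set.seed(53)
  prot <- random_protein(35)
  cds <- reverse_translate(prot)
  # mutate a few codons so the alignment is not trivial
  qprot <- strsplit(translate_nt(cds), "")[[1]]
  ref_chars <- qprot
  for (p in sample(35, 5)) ref_chars[p] <- sample(aa_alpha, 1)
  ref <- paste(ref_chars, collapse = "")
  fa <- framebot_align(cds, list(seq_record("r", ref, "amino-acid")),
                       frameshift_penalty = 1e9, min_aligned = 30L)
  B <- nifamp:::blosum62()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(translate_nt(cds)), Biostrings::AAString(ref),
    type = "global", substitutionMatrix = B, gapOpening = 11,
    gapExtension = 1)
  expect_equal(fa$score, Biostrings::score(aln), tolerance = 1e-9)
  expect_equal(nrow(fa$frameshifts), 0)
})

test_that("best reference wins with lexicographic ties and floors apply", {
  set.seed(54)
  prot <- random_protein(40)
  cds <- reverse_translate(prot)
  refs <- list(seq_record("b_ref", prot, "amino-acid"),
               seq_record("a_ref", prot, "amino-acid"))
  fa <- framebot_align(cds, refs, min_aligned = 30L)
  expect_equal(fa$reference_id, "a_ref")

  expect_error(framebot_align(cds, list()), "empty reference")
  expect_error(framebot_align("ACGTACGT",
                              list(seq_record("r", prot, "amino-acid"))),
               "shorter than 30")

  # unrelated query trips the identity floor but is reported, not dropped
  junk <- rand_seq(120)
  fj <- framebot_align(junk, list(seq_record("r", prot, "amino-acid")),
                       min_aligned = 30L)
  expect_true(fj$no_frame)
})

test_that("frameshift offsets are strictly increasing with multiple indels", {
  set.seed(55)
  prot <- random_protein(50)
  cds <- reverse_translate(prot)
  x <- paste0(substr(cds, 1, 30), "A", substr(cds, 31, 90), "T",
              substr(cds, 91, nchar(cds)))
  fa <- framebot_align(x, list(seq_record("r", prot, "amino-acid")),
                       min_aligned = 30L)
  expect_equal(fa$corrected_aa, prot)
  expect_equal(nrow(fa$frameshifts), 2)
  expect_true(all(diff(fa$frameshifts$offset) > 0))
})
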