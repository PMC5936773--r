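# Shared fixture builders; everything is generated in code.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

make_msa <- function(seqs, alphabet = "nucleotide") {
  lapply(seq_along(seqs), function(i)
    seq_record(paste0("s", i), seqs[[i]], alphabet))
}

# a sharply peaked model built from identical copies of one sequence
peaked_hmm <- function(consensus, n = 12L, alphabet = "nucleotide",
                      name = "peaked") {
  build_hmm(make_msa(rep(consensus, n), alphabet), name)
}

# quality-bearing read
qread <- function(id, residues, q = 40L) {
  seq_record(id, residues, "nucleotide", quality = rep(q, nchar(residues)))
}

# random small HMM over random MSAs, both alphabets
random_hmm <- function(L, nseq = 4L, alphabet = "nucleotide",
                       name = "rand") {
  alpha <- if (alphabet == "nucleotide") c("A", "C", "G", "T") else
    strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- replicate(nseq, rand_seq(L, alpha))
  build_hmm(make_msa(seqs, alphabet), name)
}

shuffle_seq <- function(s) {
  paste(sample(strsplit(s, "")[[1]]), collapse = "")
}
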