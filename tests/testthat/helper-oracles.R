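# Independent brute-force oracles. These re-derive, by exhaustive
# enumeration, the quantities the package computes by dynamic programming;
# they share no code with the implementation.

# ---- profile HMM: path enumeration over the generative architecture ------

# Returns list(total = sum of path probabilities, best = max path
# probability) for emitting exactly `obs` under the model.
hmm_enumerate <- function(hmm, obs, eta) {
  sym <- hmm$symbols
  L <- hmm$L
  eps <- hmm$exit_prob
  n <- length(obs)
  em <- function(j, i) hmm$match_emissions[j, match(obs[i], sym)]
  ei <- function(j, i) hmm$insert_emissions[j + 1L, match(obs[i], sym)]
  bgp <- function(i) hmm$background[[match(obs[i], sym)]]
  tr <- hmm$transitions
  total <- 0
  best <- 0
  rec <- function(state, j, i, pr) {
    if (pr <= 0) return(invisible())
    if (state == "N") {
      if (i < n) rec("N", 0L, i + 1L, pr * eta * bgp(i + 1L))
      rec("B", 0L, i, pr * (1 - eta))
    } else if (state == "B") {
      if (i < n) for (jj in seq_len(L))
        rec("M", jj, i + 1L, pr / L * em(jj, i + 1L))
    } else if (state == "M") {
      rec("E", 0L, i, pr * (if (j == L) 1 else eps))
      if (j < L) {
        co <- 1 - eps
        if (i < n) rec("M", j + 1L, i + 1L, pr * co * tr[j, "MM"] * em(j + 1L, i + 1L))
        if (i < n) rec("I", j, i + 1L, pr * co * tr[j, "MI"] * ei(j, i + 1L))
        rec("D", j + 1L, i, pr * co * tr[j, "MD"])
      }
    } else if (state == "I") {
      if (i < n) rec("M", j + 1L, i + 1L, pr * tr[j, "IM"] * em(j + 1L, i + 1L))
      if (i < n) rec("I", j, i + 1L, pr * tr[j, "II"] * ei(j, i + 1L))
    } else if (state == "D") {
      if (j == L) rec("E", 0L, i, pr)
      else {
        if (i < n) rec("M", j + 1L, i + 1L, pr * tr[j, "DM"] * em(j + 1L, i + 1L))
        rec("D", j + 1L, i, pr * tr[j, "DD"])
      }
    } else if (state == "E") {
      rec("J", 0L, i, pr * 0.5)
      rec("C", 0L, i, pr * 0.5)
    } else if (state == "J") {
      if (i < n) rec("J", 0L, i + 1L, pr * eta * bgp(i + 1L))
      rec("B", 0L, i, pr * (1 - eta))
    } else if (state == "C") {
      if (i < n) rec("C", 0L, i + 1L, pr * eta * bgp(i + 1L))
      if (i == n) {
        p <- pr * (1 - eta)
        total <<- total + p
        if (p > best) best <<- p
      }
    }
  }
  rec("N", 0L, 0L, 1)
  list(total = total, best = best)
}

hmm_oracle_bits <- function(hmm, seq_chars, eta) {
  res <- hmm_enumerate(hmm, seq_chars, eta)
  bgp <- hmm$background[match(seq_chars, hmm$symbols)]
  pnull <- (1 - eta) * prod(eta * bgp)
  list(forward = unname(log2(res$total / pnull)),
       viterbi = unname(log2(res$best / pnull)))
}

# ---- global nucleotide alignment: exhaustive affine-gap enumeration ------

# Enumerates all end-to-end alignments of a and b; gap of length k costs
# open + k * ext; match +1, mismatch -2. Returns the maximum score and the
# identities (terminal-gap columns excluded) of all optimal alignments.
align_enumerate <- function(a, b, match = 1, mismatch = -2, open = 10,
                            ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  best <- -Inf
  idents <- c()
  ident_of <- function(pa, pb) {
    gap <- pa == "-" | pb == "-"
    non <- which(!gap)
    if (!length(non)) return(0)
    cols <- non[1]:non[length(non)]
    sum(pa[cols] == pb[cols]) / length(cols)
  }
  rec <- function(i, j, sc, last, pa, pb) {
    if (i > na && j > nb) {
      if (sc > best + 1e-12) {
        best <<- sc; idents <<- ident_of(pa, pb)
      } else if (abs(sc - best) <= 1e-12) {
        idents <<- unique(c(idents, ident_of(pa, pb)))
      }
      return(invisible())
    }
    if (i <= na && j <= nb)
      rec(i + 1L, j + 1L,
          sc + (if (av[i] == bv[j]) match else mismatch), "d",
          c(pa, av[i]), c(pb, bv[j]))
    if (i <= na)
      rec(i + 1L, j, sc - (if (last == "a") ext else open + ext), "a",
          c(pa, av[i]), c(pb, "-"))
    if (j <= nb)
      rec(i, j + 1L, sc - (if (last == "b") ext else open + ext), "b",
          c(pa, "-"), c(pb, bv[j]))
  }
  rec(1L, 1L, 0, "d", character(), character())
  list(score = best, identities = idents)
}

# ---- frameshift-aware alignment: exhaustive enumeration ------------------

aa_of_codon <- function(chars) {
  codon <- paste(chars, collapse = "")
  if (grepl("[^ACGT]", codon)) return("X")
  Biostrings::GENETIC_CODE[[codon]]
}

fb_repair_score <- function(qchars, raa, B) {
  bases <- c("A", "C", "G", "T")
  c <- length(qchars)
  if (c == 3) return(B[aa_of_codon(qchars), raa])
  if (c == 4) {
    return(max(vapply(1:4, function(d)
      B[aa_of_codon(qchars[-d]), raa], numeric(1))))
  }
  if (c == 2) {
    sc <- -Inf
    for (pos in 1:3) for (bb in bases) {
      t <- append(qchars, bb, after = pos - 1L)[1:3]
      sc <- max(sc, B[aa_of_codon(t), raa])
    }
    return(sc)
  }
  if (c == 5) {
    sc <- -Inf
    for (d in utils::combn(5, 2, simplify = FALSE))
      sc <- max(sc, B[aa_of_codon(qchars[-d]), raa])
    return(sc)
  }
  if (c == 1) return(B[raa, raa])
  stop("bad consumption")
}

framebot_enumerate <- function(qnt, raa, B, fs_pen = 20, open = 11, ext = 1) {
  qv <- strsplit(qnt, "")[[1]]; rv <- strsplit(raa, "")[[1]]
  n <- length(qv); m <- length(rv)
  best <- -Inf
  rec <- function(i, j, sc, last) {
    if (sc + 4 * (m - j) + 11 * ceiling((n - i) / 3) + 20 < best - 60)
      return(invisible())  # loose bound to tame the recursion
    if (i == n && j == m) {
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (j < m) {
      for (cc in 1:5) {
        if (i + cc > n) next
        s <- fb_repair_score(qv[(i + 1):(i + cc)], rv[j + 1], B)
        rec(i + cc, j + 1L, sc + s - fs_pen * abs(cc - 3), "m")
      }
      rec(i, j + 1L, sc - (if (last == "y") ext else open + ext), "y")
    }
    if (i + 3 <= n)
      rec(i + 3L, j, sc - (if (last == "x") ext else open + ext), "x")
  }
  rec(0L, 0L, 0, "m")
  best
}

# direct call into the frameshift DP kernel (no wrapper preconditions),
# for oracle comparisons on tiny inputs
framebot_score_raw <- function(qnt, raa, fs_pen = 20, open = 11, ext = 1) {
  B <- nifamp:::blosum62()
  alpha <- rownames(B)
  caa <- nifamp:::codon_aa_map(alpha)
  qv <- match(strsplit(qnt, "")[[1]], c("A", "C", "G", "T")) - 1L
  rv <- match(strsplit(raa, "")[[1]], alpha) - 1L
  res <- nifamp:::.framebot_cpp(qv, rv, caa, match("X", alpha) - 1L, B,
                                fs_pen, open, ext, 2L)
  res$score
}

# ---- local protein alignment: max over substring pairs -------------------

global_affine_score <- function(a, b, B, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  best <- -Inf
  rec <- function(i, j, sc, last) {
    if (i > na && j > nb) {
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i <= na && j <= nb)
      rec(i + 1L, j + 1L, sc + B[av[i], bv[j]], "d")
    if (i <= na)
      rec(i + 1L, j, sc - (if (last == "a") ext else open + ext), "a")
    if (j <= nb)
      rec(i, j + 1L, sc - (if (last == "b") ext else open + ext), "b")
  }
  rec(1L, 1L, 0, "d")
  best
}

local_align_oracle <- function(a, b, B, open = 11, ext = 1) {
  best <- 0
  for (i1 in seq_len(nchar(a))) for (i2 in i1:nchar(a))
    for (j1 in seq_len(nchar(b))) for (j2 in j1:nchar(b)) {
      s <- global_affine_score(substr(a, i1, i2), substr(b, j1, j2), B,
                               open, ext)
      if (s > best) best <- s
    }
  best
}
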