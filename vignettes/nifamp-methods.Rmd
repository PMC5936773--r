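---
title: "Models and methods behind nifamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nifamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nifamp` processes nifH amplicon reads through merging, profile-HMM
filtering, OTU clustering, frameshift-corrected translation, homolog
arbitration, classification and diversity estimation. This vignette
documents the models, the numerical choices, and what the synthetic
benchmark does and does not demonstrate.

## The profile HMM and its scoring architecture

`build_hmm()` estimates a plan-7-style profile from a multiple sequence
alignment: columns with gap fraction below 0.5 become match states;
emissions and node transitions (M→M/I/D, I→M/I, D→M/D) are
Laplace-smoothed counts (pseudocount 1). We deliberately use a flat
Laplace pseudocount rather than Dirichlet mixture priors: it is simpler,
exactly reproducible, and sufficient at the alignment sizes this package
targets (tens to hundreds of rows).

Scoring is local and multihit. The begin state enters any match state
uniformly (probability 1/L); every match state carries a fixed early-exit
mass (`exit_prob`, default 0.05, with exit probability 1 from the last
node); after the end state the model may re-enter (probability 0.5) for
further hits. Flanking states (before, between and after hits) emit the
background distribution with a length-conditioned loop probability
`eta = n/(n+1)`, the same loop the null model uses, so each flanking
residue contributes odds exactly 1 and the reported bit score

$$\mathrm{bits} = \log_2 \frac{P(\text{seq} \mid \text{model})}
                             {P(\text{seq} \mid \text{background})}$$

reflects only the aligned regions plus a small transition-structure
residue. That residue is why a degenerate model whose emissions equal the
background scores *near* zero rather than exactly zero: a proper
generative length model cannot make the model's and the null's length
distributions coincide exactly. The test suite pins the forward and
Viterbi recursions against a brute-force path-enumeration oracle
(identical generative definition, independent code) to 1e-9 bits on all
models with L ≤ 4 and sequences up to length 6, over both alphabets.

Ambiguity codes (N, X) emit probability 1 in every state including the
null, contributing odds 1. No E-values are computed: the pipeline only
needs bit scores (a fixed acceptance floor in step 2, rank order in step
5), so no random-sequence calibration is attempted.

**Filter threshold.** The nucleotide pre-filter keeps a contig when its
forward score is ≥ 0 bits (config-exposed). This is intentionally
permissive — the arbitration between nifH and its homologs happens later,
at the protein level, and the pre-filter must let homologs through to be
counted; it is meant only to discard non-homologous junk. Residue-shuffled
amplicons score well below 0, while true homologs retain long
high-scoring local islands and pass.

## Pairwise identity and clustering

`pairwise_identity()` uses end-to-end Needleman–Wunsch (match +1,
mismatch −2, gap open −10, gap extend −1 per position; a gap of length k
costs 10 + k) and computes identity over alignment columns *excluding*
terminal-gap columns. We score terminal gaps rather than leaving them
free: with genuinely free end gaps, two equal-length sequences differing
at a terminal base would shed the mismatch into unpenalized overhangs and
report identity 1.0, which is not what a 97% radius should mean. Leaving
terminal columns out of the identity itself still keeps length overhangs
from diluting the estimate. Alignments are computed by
`Biostrings::pairwiseAlignment`; the test suite checks the convention
against an exhaustive alignment enumeration on short strings.

Clustering follows the UPARSE recipe reduced to its documented core:
dereplication (exact string identity, ties broken lexicographically),
singleton removal, then one greedy pass in descending abundance where a
unique joins the first centroid within the 3% radius, or founds a new
OTU unless it looks like a chimera. The chimera model is a two-parent
crossover: parents must each be at least twice as abundant as the query
and below 97% full-length identity to it, and some breakpoint must give
≥ 0.99 identity of the left segment to one parent and of the right
segment to the other (segment identities are read off the per-parent
full-length alignments, minimum segment 16 bases). This is a deliberately
reduced stand-in for UPARSE's undocumented internal scoring; its
parameters are config-exposed. Reads removed as singletons still
participate in `map_reads()`, which assigns every pre-dereplication
contig to its best centroid at ≥ 97% identity (ties to table order) and
keeps per-sample unmapped counts so read totals always reconcile.

## Frameshift-aware translation

`framebot_align()` aligns a nucleotide query against each protein
reference with a dynamic program in which a reference residue may
consume 1–5 query nucleotides; consumptions other than 3 are frameshifts
penalized 20 half-bit units per base of shift, substitutions are scored
with BLOSUM62, and gaps are affine (−11 open, −1 extend; codon-sized on
the query side). Damaged codons are scored and emitted by
*reference-guided repair*: the best completion (short consumption) or
base deletion (long consumption) of the codon under the substitution
matrix. This makes the corrected protein of a read carrying one
sequencing indel equal the true protein exactly, which is what the
repair-rate benchmark measures. With the frameshift penalty sent to
infinity the program reduces to plain protein–protein global alignment
of the in-frame translation — a property the tests verify against an
independent aligner. FrameBot-style acceptance floors (identity ≥ 0.4,
≥ 80 aligned residues) flag, but do not silently drop, failures; stops
are kept as `*` and flagged.

## Arbitration, classification, placement

Each OTU protein is scanned against the nifH, bchX and chlL-bchL models;
the unique top scorer labels the OTU. Ties are labeled `undetermined`
and excluded from the retained set — a conservative reading of
"scored highest". parA has no model of its own: bchX's model captures it,
and reporting buckets such hits under bchX. Read-level contamination is
the verdict of each OTU weighted by its mapped reads per sample; read
and OTU fractions are reported separately and each sums to 1.

Best-hit classification replaces a remote database search with local
BLOSUM62 alignment against a user-supplied labeled reference FASTA
(`id|lineage|cluster` headers): the algorithmic content — best bit score
wins, lexicographic tie-break, percent identity over aligned columns —
is preserved without a network dependency.

Cluster assignment uses a CART trained on reference rows projected onto
the nifH model's match columns: binary tests "residue at column c ∈ S",
Gini impurity, greedy best gain, deterministic tie-breaks (lowest column,
then smallest subset), growth stopped at purity, depth or leaf-size
bounds. Gaps fail every subset test. The published tree of the original
nifH CART classifier is not reproducible from literature, so the tree is
always trained from whatever labeled alignment is supplied; the training
algorithm, not a frozen tree, is the deliverable. Nearest-reference
placement (normalized Hamming distance over mutually ungapped columns,
minimum 20 comparable columns) stands in for maximum-likelihood
phylogenetic placement, which is out of scope together with base-tree
construction.

## Diversity and qPCR

Inverse Simpson is computed from the printed formula
`1/D = 1/Σ p_i²`. The bootstrap protocol drops samples whose depth falls
below the nearest-rank 15th percentile (the percentile convention is our
choice; the source protocol names none), subsamples the survivors
without replacement to the minimum surviving depth — "bootstrapped" is
read as iterated subsampling, matching the protocol's own wording — and
reports means and standard deviations across iterations. qPCR curves are
ordinary least squares of Cq on log10(copies); efficiency is
`10^(−1/slope) − 1` (the field's standard formula; sources print
efficiencies without one); replicate Cq values are averaged before
inversion, and corrected copy numbers are `copies × nifH read fraction`.

## The synthetic benchmark: what it shows and what it cannot

`mocksim` generates star-phylogeny protein families — one nifH family
subdivided into ≥ 4 labeled subclusters, plus bchX-like and
chlL/bchL-like homolog families — with within-family divergence 0.10
aa/site and between-family divergence 0.45, resampled until the mean
within-family identity exceeds between-family identity by ≥ 0.15. A star
phylogeny is used deliberately: it controls identity margins exactly and
keeps the true alignment trivial (no indels). Six members spread across
subclusters become mock clones: reverse-translated with uniform
synonymous codon choice at 150 aa (the scale of the longest
broad-coverage amplicon, ~390–490 bp with primers), flanked by concrete
expansions of real degenerate primer sites. Reads are 2×300 with flat
qualities matching the configured substitution rate (default 0.001,
MiSeq-like; indels default 0, reflecting the platform's low indel rate);
an exact-count mode (largest-remainder rounding) exists so that the
even/tiered recovery benchmarks are deterministic rather than
multinomial-noisy.

Problem sizes are kept at desk scale throughout — 600 read pairs per
run, family sizes of tens, bootstrap iterations in the tens to hundreds
— which the package's tests and the acceptance script complete in
minutes on one CPU.

What passing these benchmarks shows: the pipeline's bookkeeping is exact
(read conservation, deterministic clustering, exact recovery of declared
proportions on clean data), the arbitration separates families at
realistic divergences, and the DP kernels are provably correct against
enumeration oracles. What it does not show: behavior under real PCR
amplification bias (the benchmark's clones match their primers
perfectly by construction, whereas real mock experiments show large
primer-dependent distortions — that biological finding is precisely not
a computable target), realistic quality profiles, tag switching, or
reference databases with uneven taxon coverage. Conclusions about real
samples still require a sequenced mock community in the run.

## Degenerate inputs and tie-breaks, in one place

* Merging: best overlap maximizes `length − 4·mismatches`; ties go to
  the longest overlap; disagreements to the higher-quality base, then to
  the forward read.
* Dereplication: count ties broken lexicographically by sequence.
* Mapping: identity ties go to the earlier centroid.
* `hmm_scan`: bit ties broken by model name; in arbitration a bit tie is
  `undetermined`.
* CART: gain ties broken by lowest column, then smallest subset;
  single-label input yields a single leaf (not an error).
* Placement: distance ties go to the earlier reference row; fewer than
  20 comparable columns means `unassigned`.
* Empty inputs raise errors only where the operation is meaningless
  (empty sequence to score, empty reference set, all-zero counts);
  filters and partitions return empty partitions instead.
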