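Package: nifamp
Title: Profile-HMM Based Analysis of nifH Functional-Gene Amplicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for processing paired-end MiSeq
    amplicon data of the nifH gene (dinitrogenase reductase), the standard
    marker for nitrogen-fixing microorganisms. Implements paired-read
    merging, a nucleotide profile-HMM pre-filter, UPARSE-style greedy OTU
    clustering with a chimera check, frameshift-corrected translation
    against protein references, profile-HMM arbitration between nifH and
    its homologs (bchX, chlL/bchL, parA), best-hit taxonomic classification,
    decision-tree assignment to nifH phylogenetic clusters, bootstrapped
    alpha-diversity estimation, and qPCR standard-curve quantification with
    a non-nifH read-fraction correction. Ships a deterministic synthetic
    mock-community generator (even and tiered designs) for end-to-end
    benchmarking without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
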