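Package: akmer
Title: DNA Word Enrichment with an Average (k-1)-mer Background Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detection of overrepresented DNA words (k-mers) in sequence
    sets using the Ak-1 statistical background model, in which the expected
    count of a k-mer is derived from the frequencies of its two (k-1)-mer
    subwords combined with the frequency of the remaining mononucleotide,
    and the two resulting fold enrichments are averaged. Also provides the
    single-mismatch (C0/C1) neighborhood background and maximum-likelihood
    Markov-chain backgrounds of arbitrary order for comparison,
    Bonferroni-corrected overrepresentation calling, k-mer spectrum surveys
    across a range of word lengths, equal-width fold-score binning with
    cross-species bin-overlap profiles, GC-controlled random sequence
    generation, and a motif-implantation simulation benchmark. Counting
    uses greedy non-overlapping occurrences aggregated over both strands.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    methods,
    Rcpp,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
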