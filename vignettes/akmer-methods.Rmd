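---
title: "Background models and design choices in akmer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Background models and design choices in akmer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(akmer)
```

## The problem

Scanning a genome for overrepresented words of length k requires a null
model for how often each word is *expected* to occur. The classic choices —
Markov chains fitted to the input, or the mean count of a word's
single-mismatch neighborhood — carry the input's base composition into the
expectation, so an AT-rich genome produces AT-rich "enriched" lists. The
Ak-1 model conditions each word on the observed abundances of its own two
(k-1)-mer subwords instead, which cancels most of the compositional signal
and favors words that are abundant *beyond* what their subwords explain.

## Counting

Every statistic in the package rests on one counting scheme:

* **Non-overlapping occurrences**, realized as a greedy left-to-right scan
  (after a match at position i the scan resumes at i + k). For occurrences
  of equal length the greedy rule provably attains the maximum number of
  mutually non-overlapping occurrences, which makes the count
  orientation-invariant and reproducible.
* **Both strands aggregated** by default: a word's count is its forward
  count plus the count in the reverse complement of each record. A word and
  its reverse complement remain *distinct* table keys carrying the same
  aggregated count; they are not collapsed to a canonical form, because
  enriched-word lists are conventionally reported as oriented words.
* Windows containing N are skipped; N is excluded from mononucleotide
  denominators; matches never span two FASTA records.

The normalization totals N (for (k-1)-mers) and M (for k-mers) are the sums
of the non-overlapping counts themselves, so the frequencies used by the
models sum to exactly 1 over the table. An alternative reading — totals as
the number of valid (overlapping) window positions, roughly L − k + 1 per
record per strand — is retained in every table (`window_positions`) and
selectable via `normalization = "windows"` in the background functions for
sensitivity checks. The two differ by at most a few percent for k ≥ 4 at
genome scale and not at all in fold *rankings* of a fixed k, because the
choice rescales every expectation by a common factor.

## The Ak-1 score

For word w with observed count O, subword counts C1 (prefix) and C2
(suffix), totals N and M, and mononucleotide frequencies p():

E1 = (C1/N) p(last base) M, E2 = (C2/N) p(first base) M,
F1 = O/E1, F2 = O/E2, F = (F1+F2)/2, Ē = (E1+E2)/2,
Z = (O − Ē)/√Ē, with the upper-tail normal p-value.

Choices a user should know about:

* **Z-score spread.** √Ē is the Poisson approximation, the simplest
  variance model consistent with count data. The binomial alternative
  √(Ē(1−Ē/M)) is available via `variance = "binomial"`; for words rare
  relative to M the two are numerically indistinguishable.
* **Undefined records.** If either expectation vanishes (a subword was
  never observed) the record carries `defined = FALSE` and NA scores rather
  than an infinite fold. Only observed words (O > 0) are scored at all;
  absent words are out of scope.
* **Ties.** All rankings break ties by descending Z-score, then
  lexicographic word order, so output is deterministic. One visible
  consequence of strand aggregation: a word and its reverse complement have
  identical scores, and the lexicographically smaller one ranks first.

## The comparison backgrounds

**C0/C1 (single mismatch).** The expectation for w is the arithmetic mean
of the counts of its 3k single-substitution neighbors (w itself excluded),
with fold C0/C1 and Z = (C0−C1)/√C1. No pseudocount is added by default —
an all-zero neighborhood yields an undefined record — but
`pseudocount =` adds a uniform additive count for exploration.

**Markov of order m.** The maximum-likelihood estimate
E(w) = M · Π f(w[i..i+m]) / Π f(w[i..i+m−1]) (numerator over the k−m
(m+1)-subwords, denominator over the k−m−1 inner m-subwords), with each
frequency taken relative to its own table's total. At m = 0 this reduces to
the Bernoulli composition product; at m = k−2 it approaches the
self-consistent limit where E equals O on perfectly repetitive input. The
estimate uses the same strand-aggregated non-overlapping tables as the rest
of the package, not any external tool's internal counting, so numerical
agreement with web services implementing the same order is approximate by
design. Rankings may use the Z-score with binomial variance or the exact
binomial upper tail P(X ≥ O), X ~ Binomial(M, E/M).

## Significance calling

One-sided upper-tail p-values throughout: the package calls only
*over*representation. The Bonferroni family size defaults to the number of
distinct observed words scored at that k — that is what is actually tested —
not 4^k; pass `n_tests = 4^k` to a `significance_config()` to correct
against the full sequence space. The default level is alpha = 0.05.

## Cross-species bin-overlap comparison

Each species' ranked list is divided into 8 equal-width bins spanning *that
species' own* fold-score range; bins correspond across species by index,
not by shared numeric edges. This follows the protocol of computing the
statistical range per list; the cost is species-specific bin widths, the
benefit is that every list populates all 8 bins regardless of scale. Bins
are half-open [lo, hi) with the last bin closed so the maximum-fold word is
always binned; a degenerate all-equal list is widened by machine epsilon
and collapses into bin 1. For a combination of species, a reference word is
"shared" only if it sits in the same-index bin of *every* species in the
combination (intersection semantics), so adding a species can only keep or
lower a percentage. Empty reference bins report NA, not 0. Undefined words
are excluded from a species' partition with a message.

## The simulation generator

`random_sequences()` draws iid bases with P(G) = P(C) = gc/2; the default
gc = 0.38 matches the S. cerevisiae genome used as the reference
composition for the benchmark. `implant_motif()` *overwrites* a uniformly
placed window per sequence (lengths preserved) rather than inserting;
implanted copies are non-overlapping within a sequence. The benchmark
defaults — 6,000 sequences of 500 bp, one implant of ATGCCGTA — are the
standard sensitivity test for word-enrichment backgrounds; with them the
motif's Z-rank is 1 essentially always, while its fold-rank fluctuates
within the top ten across seeds because extreme-composition words
(homopolymer-like 8-mers) compete on fold but not on Z.

`synthetic_species()` derives species from one ancestral iid genome by iid
substitutions (the mutated base drawn uniformly from the three others), so
expected species-to-species identity is (1−r)² + r²/3. This exercises the
comparison machinery; it is *not* an evolutionary simulation — no indels,
no rate heterogeneity, no phylogenetic structure — so passing comparison
tests demonstrates correctness of the binning arithmetic, not realism of
the divergence model. Likewise the iid generator has no repeats, no
isochores and no motif grammar: benchmark results quantify sensitivity to a
planted signal in a compositionally matched background, nothing more.

All generators require an explicit integer seed; stochastic workflows are
reproducible by construction. The benchmark derives its implantation stream
from seed + 1 so one config seed fixes the entire run.

## Problem sizes

The test suite exercises: oracle equivalence of the counting kernel on
200 bp strings against a brute-force maximum-independent-set oracle;
law-of-large-numbers checks of all three backgrounds on a 1 Mb iid
sequence; five full-scale (6,000 × 500 bp) benchmark realizations for the
Z- and fold-ranking results; twenty full-scale null (no-implant)
realizations for the false-positive calibration; and cross-species
comparisons on 4–30 kb synthetic genomes. These sizes were chosen so each
check's sampling noise is far below its assertion margin.

## Known limitations

* The Ak-1 expectation is only as informative as the (k−1)-mer spectrum: in
  regimes where nearly all 4^k words occur at similar counts (small k in a
  large genome), most observed words score as overrepresented and the model
  adds little discrimination until k is large enough for the observed
  spectrum to deviate from saturation.
* Underrepresentation is not scored; the lower tail is untested by design.
* Markov expectations are capped at order k−2; higher orders are refused
  rather than approximated.
* Counting is exact-match only: no degenerate alphabets, no mismatch
  tolerance in the occurrence counts themselves.
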