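# Shared fixtures and independent oracles for the test suite.

# Independent oracle for the maximum number of mutually non-overlapping
# occurrences of `word` in `sequence`: enumerate all (possibly overlapping)
# occurrence start positions by brute force, then solve the maximum
# independent set of equal-length intervals by dynamic programming over the
# sorted starts. Deliberately shares no code with the package's greedy scan.
oracle_nonoverlap_count <- function(sequence, word) {
  k <- nchar(word)
  n <- nchar(sequence)
  if (k > n) return(0L)
  starts <- which(vapply(seq_len(n - k + 1L),
                         function(i) substr(sequence, i, i + k - 1L) == word,
                         logical(1)))
  if (length(starts) == 0L) return(0L)
  m <- length(starts)
  best <- integer(m + 1L)  # best[i] = max count using occurrences i..m
  for (i in m:1) {
    nxt <- which(starts >= starts[i] + k)
    nxt <- nxt[nxt > i]
    take <- 1L + if (length(nxt)) best[min(nxt)] else 0L
    best[i] <- max(best[i + 1L], take)
  }
  best[1L]
}

# Hand-rolled complement for cross-checking reverse_complement().
oracle_revcomp <- function(w) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(w, "")[[1]]]), collapse = "")
}

# Deterministic random DNA string (uniform base composition).
random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# All 4^k words of length k, lexicographic.
all_words <- function(k) {
  g <- expand.grid(rep(list(c("A", "C", "G", "T")), k),
                   stringsAsFactors = FALSE)
  sort(do.call(paste0, g))
}

extdata <- function(name) {
  path <- system.file("extdata", name, package = "akmer")
  stopifnot(nzchar(path))
  path
}

# Memoized 1 Mb iid uniform sequence set shared by law-of-large-numbers
# checks (built once per test run).
iid_megabase <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- random_sequences(1L, 1e6, gc = 0.5, seed = 424242,
                                 label = "iid_1mb")
    cache
  }
})
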