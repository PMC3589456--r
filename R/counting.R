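#' Count non-overlapping occurrences of a single word
#'
#' Greedy left-to-right scan: after a match at position i, scanning resumes
#' at i + nchar(word). For equal-length matches this attains the maximum
#' number of mutually non-overlapping occurrences. Windows containing N never
#' match (the word itself is ACGT-only, so this follows from exact matching).
#'
#' @param sequence Single DNA string.
#' @param word Single DNA word over `{A,C,G,T}`.
#' @return Integer count.
#' @examples
#' count_nonoverlapping("AAAAA", "AA")  # 2
#' @export
count_nonoverlapping <- function(sequence, word) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            is.character(word), length(word) == 1L)
  if (!nzchar(word)) stop("empty word", call. = FALSE)
  if (grepl("[^ACGT]", word)) stop("word must be over {A,C,G,T}", call. = FALSE)
  m <- gregexpr(word, sequence, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) 0L else length(m)
}

#' Build a k-mer count table
#'
#' Counts the greedy non-overlapping occurrences of every word of length `k`
#' observed in a sequence set. Under `strand_policy = "both"` (the default)
#' counts from the forward strand and from the reverse complement of each
#' record are aggregated, so `counts[w] == counts[reverse_complement(w)]`
#' for every word. Records are counted independently (no match spans two
#' records) and windows containing N are skipped.
#'
#' @param seqs A [sequence_set()].
#' @param k Word length (1--31).
#' @param strand_policy `"both"` or `"forward_only"`.
#' @return An object of class `KmerCountTable`: list with `k`, `counts`
#'   (named numeric vector, lexicographic word order), `total_occurrences`
#'   (sum of counts, the default normalization total), `window_positions`
#'   (number of valid, possibly overlapping window positions; alternative
#'   normalization total), `region_length` (total residues in `seqs`),
#'   `strand_policy`, and `label`.
#' @examples
#' tb <- build_count_table(sequence_set(c(s = "ACGT")), k = 2)
#' tb$counts
#' @export
build_count_table <- function(seqs, k,
                              strand_policy = c("both", "forward_only")) {
  stopifnot(inherits(seqs, "SequenceSet"))
  strand_policy <- match.arg(strand_policy)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer", call. = FALSE)
  widths <- Biostrings::width(seqs$seq)
  if (all(widths < k))
    stop("k exceeds all sequence lengths", call. = FALSE)
  fwd <- as.character(seqs$seq)
  res <- count_kmers_cpp(fwd, k)
  counts <- stats::setNames(res$count, res$kmer)
  n_windows <- res$n_windows
  if (strand_policy == "both") {
    rev <- as.character(Biostrings::reverseComplement(seqs$seq))
    res2 <- count_kmers_cpp(rev, k)
    c2 <- stats::setNames(res2$count, res2$kmer)
    all_words <- sort(unique(c(names(counts), names(c2))))
    merged <- numeric(length(all_words))
    names(merged) <- all_words
    merged[names(counts)] <- counts
    merged[names(c2)] <- merged[names(c2)] + c2
    counts <- merged
    n_windows <- n_windows + res2$n_windows
  }
  structure(list(
    k = k,
    counts = counts,
    total_occurrences = sum(counts),
    window_positions = n_windows,
    region_length = sum(widths),
    strand_policy = strand_policy,
    label = seqs$label
  ), class = "KmerCountTable")
}

#' @export
print.KmerCountTable <- function(x, ...) {
  cat(sprintf(
    "KmerCountTable '%s': k=%d, %d distinct words, total=%g, L=%d, strands=%s\n",
    x$label, x$k, length(x$counts), x$total_occurrences, x$region_length,
    x$strand_policy))
  invisible(x)
}

#' Query counts for specific words
#'
#' @param table A `KmerCountTable`.
#' @param words Character vector of words of length `table$k`.
#' @return Numeric vector of counts; words absent from the table return 0.
#' @export
kmer_count <- function(table, words) {
  stopifnot(inherits(table, "KmerCountTable"))
  if (any(nchar(words) != table$k))
    stop("word length does not match table k", call. = FALSE)
  i <- match(words, names(table$counts))
  out <- ifelse(is.na(i), 0, table$counts[i])
  names(out) <- words
  out
}

#' Mononucleotide frequencies of a sequence set
#'
#' Base fractions among non-N residues. Under `strand_policy = "both"` the
#' forward and complement residues are pooled, so `freq[A] == freq[T]` and
#' `freq[C] == freq[G]` exactly.
#'
#' @inheritParams build_count_table
#' @return Named numeric vector over A, C, G, T summing to 1.
#' @export
mono_frequencies <- function(seqs, strand_policy = c("both", "forward_only")) {
  stopifnot(inherits(seqs, "SequenceSet"))
  strand_policy <- match.arg(strand_policy)
  n <- colSums(Biostrings::letterFrequency(seqs$seq, c("A", "C", "G", "T")))
  if (sum(n) == 0) stop("no ACGT residues in input", call. = FALSE)
  if (strand_policy == "both") {
    at <- (n[["A"]] + n[["T"]]) / 2
    cg <- (n[["C"]] + n[["G"]]) / 2
    n <- c(A = at, C = cg, G = cg, T = at)
  }
  n / sum(n)
}

#' Write a count table to TSV
#'
#' Two columns (`kmer`, `count`) preceded by a `#` metadata header carrying
#' k, the normalization totals, the region length and the strand policy.
#'
#' @param table A `KmerCountTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "KmerCountTable"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# k=%d total=%g windows=%g length=%d strands=%s",
                     table$k, table$total_occurrences, table$window_positions,
                     table$region_length, table$strand_policy), con)
  writeLines("kmer\tcount", con)
  writeLines(paste(names(table$counts), format(table$counts, trim = TRUE,
                                               scientific = FALSE),
                   sep = "\t"), con)
  invisible(path)
}
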