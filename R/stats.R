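#' Configure significance calling
#'
#' @param alpha Per-family significance level in (0, 1); default 0.05.
#' @param correction `"bonferroni"` (per-test threshold alpha / n_tests) or
#'   `"none"`.
#' @param n_tests Number of tests in the family. The convention throughout
#'   the package is the number of distinct observed k-mers scored at that k;
#'   pass `4^k` explicitly to test against the full sequence space instead.
#' @return Object of class `SignificanceConfig`.
#' @export
significance_config <- function(alpha = 0.05,
                                correction = c("bonferroni", "none"),
                                n_tests = 1L) {
  correction <- match.arg(correction)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  if (!is.numeric(n_tests) || length(n_tests) != 1L || n_tests < 1)
    stop("n_tests must be >= 1", call. = FALSE)
  structure(list(alpha = alpha, correction = correction,
                 n_tests = as.numeric(n_tests)),
            class = "SignificanceConfig")
}

#' Flag overrepresented k-mers
#'
#' Sets the `significant` flag of each enrichment record: significant iff
#' the upper-tail p-value is below alpha / n_tests (Bonferroni) or alpha
#' (no correction). Undefined records are never significant.
#'
#' @param records Enrichment record `data.frame` with a `pvalue` column.
#' @param config A [significance_config()].
#' @return The records with `significant` updated.
#' @export
call_overrepresented <- function(records, config) {
  stopifnot(inherits(config, "SignificanceConfig"), "pvalue" %in% names(records))
  thr <- if (config$correction == "bonferroni")
    config$alpha / config$n_tests else config$alpha
  records$significant <- records$defined & !is.na(records$pvalue) &
    records$pvalue < thr
  records
}

#' Top-ranked words of a ranked list
#'
#' @param list A `RankedList` from [enrich()] or [rank_records()].
#' @param n Number of words to return (>= 1); truncated to the list size.
#' @return Character vector of the first `min(n, size)` words in rank order.
#' @export
top_n <- function(list, n) {
  stopifnot(inherits(list, "RankedList"), n >= 1)
  utils::head(list$kmer, n)
}

#' Mean GC content of a word list, in percent
#'
#' Unweighted mean over the words of 100 * (G + C count) / word length.
#' Full precision is returned; display conventionally rounds half-up to one
#' decimal.
#'
#' @param words Non-empty character vector of DNA words (lengths may mix).
#' @return Mean GC percentage.
#' @examples
#' mean_gc_percent(c("GGGG", "ATAT"))  # 50
#' @export
mean_gc_percent <- function(words) {
  if (length(words) == 0L) stop("empty word list", call. = FALSE)
  gc <- vapply(strsplit(toupper(words), "", fixed = TRUE),
               function(ch) mean(ch %in% c("G", "C")), numeric(1))
  mean(gc) * 100
}

#' Overlap between two ranked k-mer lists
#'
#' Set intersection of two ordered word lists, optionally excluding the
#' first `skip_top` ranks of both lists. Shared words are reported with
#' their (full-list) rank in each input.
#'
#' @param reference Ordered character vector of words.
#' @param other Ordered character vector of words.
#' @param skip_top Number of leading ranks excluded from both lists.
#' @return List with `shared` (a `data.frame` of word, rank_reference,
#'   rank_other) and `count`.
#' @export
list_overlap <- function(reference, other, skip_top = 0L) {
  stopifnot(skip_top >= 0L)
  ref <- if (skip_top > 0L) reference[-seq_len(skip_top)] else reference
  oth <- if (skip_top > 0L) other[-seq_len(skip_top)] else other
  shared <- intersect(ref, oth)
  list(shared = data.frame(word = shared,
                           rank_reference = match(shared, reference),
                           rank_other = match(shared, other),
                           stringsAsFactors = FALSE),
       count = length(shared))
}

#' Survey the k-mer spectrum over a range of word lengths
#'
#' For each k in `k_range`: the number of distinct observed words, the
#' number observed two or more times, the number called overrepresented
#' under the chosen background at the configured significance level, and the
#' theoretical maximum 4^k.
#'
#' @param seqs A [sequence_set()].
#' @param k_range Integer vector of word lengths (e.g. `4:16`).
#' @param spec A [background_spec()].
#' @param alpha Significance level (Bonferroni-corrected per k over the
#'   distinct observed words at that k).
#' @param correction `"bonferroni"` or `"none"`.
#' @param strand_policy `"both"` or `"forward_only"`.
#' @param ... Passed on to [enrich()].
#' @return `data.frame` with columns k, distinct, ge2, overrepresented,
#'   theoretical_max.
#' @export
survey_spectrum <- function(seqs, k_range, spec = background_spec("ak1"),
                            alpha = 0.05,
                            correction = c("bonferroni", "none"),
                            strand_policy = c("both", "forward_only"), ...) {
  correction <- match.arg(correction)
  strand_policy <- match.arg(strand_policy)
  k_range <- sort(unique(as.integer(k_range)))
  rows <- lapply(k_range, function(k) {
    tab <- build_count_table(seqs, k, strand_policy)
    ranked <- enrich(seqs, k, spec, strand_policy = strand_policy, ...)
    cfg <- significance_config(alpha, correction, n_tests = nrow(ranked))
    called <- call_overrepresented(ranked, cfg)
    data.frame(k = k,
               distinct = length(tab$counts),
               ge2 = sum(tab$counts >= 2),
               overrepresented = sum(called$significant),
               theoretical_max = 4^k)
  })
  do.call(rbind, rows)
}

#' Write a spectrum survey to TSV
#'
#' @param survey Output of [survey_spectrum()].
#' @param path Output path.
#' @param header Optional named character vector echoed as `# key=value`.
#' @return `path`, invisibly.
#' @export
write_survey <- function(survey, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(sprintf("# %s=%s", names(header), unname(header)), con)
  utils::write.table(survey, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
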