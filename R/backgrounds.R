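#' Specify a statistical background model
#'
#' Bundles the choice of null model and its parameters. Three models are
#' supported: `"ak1"` (average (k-1)-mer: the expected count of a word is
#' derived from each of its two (k-1)-mer subwords combined with the
#' remaining mononucleotide, and the two fold enrichments are averaged),
#' `"c0c1"` (single-mismatch neighborhood: the expectation is the mean count
#' of the 3k one-substitution neighbors), and `"markov"` (maximum-likelihood
#' Markov chain of a given order estimated from the input).
#'
#' @param model `"ak1"`, `"c0c1"` or `"markov"`.
#' @param markov_order Markov order m (required for `"markov"`, must satisfy
#'   0 <= m <= k-2 at scoring time; disallowed otherwise).
#' @param rank_statistic Statistic used to order ranked lists: `"fold"`,
#'   `"zscore"`, or `"binomial"` (binomial only with the Markov model).
#'   Defaults: fold for ak1 and c0c1, zscore for markov.
#' @return Object of class `BackgroundSpec`.
#' @examples
#' background_spec("markov", markov_order = 3, rank_statistic = "zscore")
#' @export
background_spec <- function(model = c("ak1", "c0c1", "markov"),
                            markov_order = NULL,
                            rank_statistic = NULL) {
  model <- match.arg(model)
  if (model == "markov") {
    if (is.null(markov_order))
      stop("markov_order is required for the Markov model", call. = FALSE)
    markov_order <- as.integer(markov_order)
    if (is.na(markov_order) || markov_order < 0L)
      stop("markov_order must be a non-negative integer", call. = FALSE)
  } else if (!is.null(markov_order)) {
    stop("markov_order applies only to the Markov model", call. = FALSE)
  }
  if (is.null(rank_statistic))
    rank_statistic <- if (model == "markov") "zscore" else "fold"
  rank_statistic <- match.arg(rank_statistic, c("fold", "zscore", "binomial"))
  if (rank_statistic == "binomial" && model != "markov")
    stop("binomial ranking is only available for the Markov model",
         call. = FALSE)
  structure(list(model = model, markov_order = markov_order,
                 rank_statistic = rank_statistic),
            class = "BackgroundSpec")
}

#' @export
print.BackgroundSpec <- function(x, ...) {
  cat("BackgroundSpec:", x$model,
      if (!is.null(x$markov_order)) paste0("(order ", x$markov_order, ")"),
      "ranked by", x$rank_statistic, "\n")
  invisible(x)
}

# Shared record layout for every background model.
.enrichment_records <- function(kmer, observed, e1, e2, f1, f2, zscore,
                                pvalue, defined) {
  emean <- (e1 + e2) / 2
  fold <- (f1 + f2) / 2
  data.frame(kmer = kmer, observed = observed,
             expected_1 = e1, expected_2 = e2, expected_mean = emean,
             fold_1 = f1, fold_2 = f2, fold = fold,
             zscore = zscore, pvalue = pvalue,
             significant = FALSE, defined = defined,
             stringsAsFactors = FALSE, row.names = NULL)
}

.z_from_expected <- function(observed, expected, total,
                             variance = c("poisson", "binomial")) {
  variance <- match.arg(variance)
  v <- if (variance == "poisson") expected
       else expected * pmax(0, 1 - expected / total)
  z <- (observed - expected) / sqrt(v)
  z[expected > 0 & v == 0] <- NA_real_
  z
}

#' Ak-1 expected counts of k-mers
#'
#' For a k-mer w with prefix w[1..k-1] and suffix w[2..k], using the
#' (k-1)-mer table (counts C1, C2; total N) and the k-mer table (total M):
#' `E1 = (C1/N) * p(last base) * M` and `E2 = (C2/N) * p(first base) * M`,
#' where p() are the mononucleotide frequencies. E1 pairs the left subword
#' with the appended right base; E2 pairs the right subword with the
#' prepended left base.
#'
#' @param kmer Character vector of words of length `table_k$k`.
#' @param table_k K-mer count table (length k).
#' @param table_km1 Count table at length k-1, built from the same sequences
#'   with the same strand policy.
#' @param mono Mononucleotide frequencies from [mono_frequencies()].
#' @param normalization `"occurrences"` (totals are sums of non-overlapping
#'   counts; the default) or `"windows"` (totals are valid window-position
#'   counts).
#' @return List with numeric vectors `E1` and `E2`.
#' @export
ak1_expected <- function(kmer, table_k, table_km1, mono,
                         normalization = c("occurrences", "windows")) {
  stopifnot(inherits(table_k, "KmerCountTable"),
            inherits(table_km1, "KmerCountTable"))
  normalization <- match.arg(normalization)
  k <- table_k$k
  if (table_km1$k != k - 1L)
    stop("table_km1 must have word length k-1", call. = FALSE)
  if (any(nchar(kmer) != k))
    stop("kmer length does not match table k", call. = FALSE)
  if (table_k$strand_policy != table_km1$strand_policy)
    stop("tables use different strand policies", call. = FALSE)
  n_tot <- if (normalization == "windows") table_km1$window_positions
           else table_km1$total_occurrences
  m_tot <- if (normalization == "windows") table_k$window_positions
           else table_k$total_occurrences
  if (n_tot == 0 || m_tot == 0) stop("empty tables", call. = FALSE)
  prefix <- substr(kmer, 1L, k - 1L)
  suffix <- substr(kmer, 2L, k)
  c1 <- unname(kmer_count(table_km1, prefix))
  c2 <- unname(kmer_count(table_km1, suffix))
  p_last <- unname(mono[substr(kmer, k, k)])
  p_first <- unname(mono[substr(kmer, 1L, 1L)])
  list(E1 = (c1 / n_tot) * p_last * m_tot,
       E2 = (c2 / n_tot) * p_first * m_tot)
}

#' Score k-mers under the Ak-1 background
#'
#' Computes, for each word, the two expected counts E1 and E2 (see
#' [ak1_expected()]), the fold enrichments F1 = O/E1 and F2 = O/E2, their
#' average F, the average expected count, the Z-score and an upper-tail
#' normal p-value. Records where either expectation vanishes are flagged
#' `defined = FALSE` and carry NA scores.
#'
#' @inheritParams ak1_expected
#' @param variance Spread model for the Z-score denominator: `"poisson"`
#'   (sqrt of the average expected count; default) or `"binomial"`.
#' @return `data.frame` of enrichment records (one row per word) with
#'   columns kmer, observed, expected_1, expected_2, expected_mean, fold_1,
#'   fold_2, fold, zscore, pvalue, significant, defined.
#' @export
ak1_score <- function(kmer, table_k, table_km1, mono,
                      variance = c("poisson", "binomial"),
                      normalization = c("occurrences", "windows")) {
  normalization <- match.arg(normalization)
  variance <- match.arg(variance)
  e <- ak1_expected(kmer, table_k, table_km1, mono, normalization)
  o <- unname(kmer_count(table_k, kmer))
  defined <- e$E1 > 0 & e$E2 > 0
  f1 <- ifelse(defined, o / e$E1, NA_real_)
  f2 <- ifelse(defined, o / e$E2, NA_real_)
  ebar <- (e$E1 + e$E2) / 2
  m_tot <- if (normalization == "windows") table_k$window_positions
           else table_k$total_occurrences
  z <- ifelse(defined, .z_from_expected(o, ebar, m_tot, variance), NA_real_)
  p <- ifelse(defined, stats::pnorm(z, lower.tail = FALSE), NA_real_)
  .enrichment_records(kmer, o, e$E1, e$E2, f1, f2, z, p, defined)
}

# All 3k single-substitution neighbors of each word, as a matrix with one
# row per word and 3k columns (the word itself never appears).
.mismatch_neighbors <- function(kmer) {
  k <- nchar(kmer[1L])
  bases <- c("A", "C", "G", "T")
  chars <- matrix(unlist(strsplit(kmer, "", fixed = TRUE), use.names = FALSE),
                  ncol = k, byrow = TRUE)
  idx <- matrix(match(chars, bases), ncol = k)
  out <- matrix(NA_character_, nrow = length(kmer), ncol = 3L * k)
  col <- 0L
  for (i in seq_len(k)) {
    for (d in 1:3) {  # the three bases cyclically offset from the original
      col <- col + 1L
      sub <- chars
      sub[, i] <- bases[(idx[, i] - 1L + d) %% 4L + 1L]
      out[, col] <- do.call(paste0, as.data.frame(sub,
                                                  stringsAsFactors = FALSE))
    }
  }
  out
}

#' Score k-mers under the C0/C1 single-mismatch background
#'
#' The observed count C0 of a word is compared against C1, the arithmetic
#' mean of the counts of its 3k single-substitution neighbors (the word
#' itself excluded). Fold enrichment is C0/C1 and the Z-score is
#' (C0 - C1)/sqrt(C1). When every neighbor is unobserved (C1 = 0) the record
#' is flagged `defined = FALSE`.
#'
#' @param kmer Character vector of words of length `table_k$k`.
#' @param table_k K-mer count table.
#' @param pseudocount Additive pseudocount applied to each neighbor count
#'   (default 0).
#' @return Enrichment record `data.frame` as in [ak1_score()]; the two
#'   expectation columns both carry C1.
#' @export
c0c1_score <- function(kmer, table_k, pseudocount = 0) {
  stopifnot(inherits(table_k, "KmerCountTable"), pseudocount >= 0)
  k <- table_k$k
  if (any(nchar(kmer) != k))
    stop("kmer length does not match table k", call. = FALSE)
  o <- unname(kmer_count(table_k, kmer))
  nb <- .mismatch_neighbors(kmer)
  idx <- match(nb, names(table_k$counts))
  cnt <- matrix(table_k$counts[idx], nrow = length(kmer))
  cnt[is.na(cnt)] <- 0
  c1 <- rowMeans(cnt + pseudocount)
  defined <- c1 > 0
  f <- ifelse(defined, o / c1, NA_real_)
  z <- ifelse(defined, (o - c1) / sqrt(c1), NA_real_)
  p <- ifelse(defined, stats::pnorm(z, lower.tail = FALSE), NA_real_)
  .enrichment_records(kmer, o, c1, c1, f, f, z, p, defined)
}

#' Markov-model expected counts of k-mers
#'
#' Maximum-likelihood Markov estimate of order m, computed from count tables
#' of lengths m+1 and m built with the same non-overlapping strand-aggregated
#' counting scheme as everything else:
#' `E(w) = M_k * prod(f(w[i..i+m]), i=1..k-m) / prod(f(w[i..i+m-1]), i=2..k-m)`
#' where f() is a subword's frequency in its own table and M_k the k-mer
#' total. For m = 0 this reduces to the Bernoulli composition product. E is 0
#' whenever a numerator subword is unobserved.
#'
#' @param kmer Character vector of words of equal length k.
#' @param seqs A [sequence_set()] the background is estimated from.
#' @param order Markov order m, 0 <= m <= k-2.
#' @param strand_policy `"both"` or `"forward_only"`.
#' @param normalization As in [ak1_expected()].
#' @return Numeric vector of expected counts.
#' @export
markov_expected <- function(kmer, seqs, order,
                            strand_policy = c("both", "forward_only"),
                            normalization = c("occurrences", "windows")) {
  strand_policy <- match.arg(strand_policy)
  normalization <- match.arg(normalization)
  k <- unique(nchar(kmer))
  if (length(k) != 1L) stop("kmers must share one length", call. = FALSE)
  m <- as.integer(order)
  if (is.na(m) || m < 0L) stop("order must be >= 0", call. = FALSE)
  if (m > k - 2L) stop("order too high for word length", call. = FALSE)
  table_k <- build_count_table(seqs, k, strand_policy)
  .markov_expected_tables(kmer, seqs, m, table_k, strand_policy, normalization)
}

.markov_expected_tables <- function(kmer, seqs, m, table_k, strand_policy,
                                    normalization = "occurrences") {
  k <- table_k$k
  m_tot <- if (normalization == "windows") table_k$window_positions
           else table_k$total_occurrences
  tab_num <- build_count_table(seqs, m + 1L, strand_policy)
  num_tot <- if (normalization == "windows") tab_num$window_positions
             else tab_num$total_occurrences
  log_e <- rep(log(m_tot), length(kmer))
  zero <- rep(FALSE, length(kmer))
  for (i in seq_len(k - m)) {
    w <- substr(kmer, i, i + m)
    cnt <- unname(kmer_count(tab_num, w))
    zero <- zero | cnt == 0
    log_e <- log_e + ifelse(cnt > 0, log(cnt / num_tot), 0)
  }
  if (m >= 1L && k - m >= 2L) {
    tab_den <- build_count_table(seqs, m, strand_policy)
    den_tot <- if (normalization == "windows") tab_den$window_positions
               else tab_den$total_occurrences
    for (i in 2:(k - m)) {
      w <- substr(kmer, i, i + m - 1L)
      cnt <- unname(kmer_count(tab_den, w))
      if (any(cnt == 0 & !zero))
        stop("zero denominator count with non-zero numerators", call. = FALSE)
      log_e <- log_e - ifelse(cnt > 0, log(cnt / den_tot), 0)
    }
  }
  e <- exp(log_e)
  e[zero] <- 0
  e
}

#' Score k-mers under a Markov background
#'
#' Expected counts from [markov_expected()]; fold = O/E; Z uses the binomial
#' variance `sqrt(E * (1 - E/M_k))`; the exact binomial upper tail
#' `P(X >= O)` for X ~ Binomial(M_k, E/M_k) is available as the p-value when
#' `rank_statistic = "binomial"` (otherwise the p-value is the normal upper
#' tail of Z). Words with E = 0 but O > 0 are flagged `defined = FALSE`.
#'
#' @inheritParams markov_expected
#' @param rank_statistic `"zscore"`, `"binomial"` or `"fold"`; recorded for
#'   downstream sorting and selects the p-value column's definition.
#' @return Enrichment record `data.frame` as in [ak1_score()]; both
#'   expectation columns carry E.
#' @export
markov_score <- function(kmer, seqs, order,
                         rank_statistic = c("zscore", "binomial", "fold"),
                         strand_policy = c("both", "forward_only"),
                         normalization = c("occurrences", "windows")) {
  rank_statistic <- match.arg(rank_statistic)
  strand_policy <- match.arg(strand_policy)
  normalization <- match.arg(normalization)
  k <- unique(nchar(kmer))
  if (length(k) != 1L) stop("kmers must share one length", call. = FALSE)
  table_k <- build_count_table(seqs, k, strand_policy)
  .markov_score_tables(kmer, seqs, as.integer(order), table_k, rank_statistic,
                       strand_policy, normalization)
}

.markov_score_tables <- function(kmer, seqs, m, table_k, rank_statistic,
                                 strand_policy, normalization = "occurrences") {
  k <- table_k$k
  if (m < 0L) stop("order must be >= 0", call. = FALSE)
  if (m > k - 2L) stop("order too high for word length", call. = FALSE)
  e <- .markov_expected_tables(kmer, seqs, m, table_k, strand_policy,
                               normalization)
  o <- unname(kmer_count(table_k, kmer))
  m_tot <- if (normalization == "windows") table_k$window_positions
           else table_k$total_occurrences
  defined <- e > 0
  f <- ifelse(e > 0, o / e, NA_real_)
  z <- ifelse(e > 0, .z_from_expected(o, e, m_tot, "binomial"), NA_real_)
  if (rank_statistic == "binomial") {
    pr <- pmin(e / m_tot, 1)
    p <- ifelse(e > 0,
                stats::pbinom(o - 1, size = round(m_tot), prob = pr,
                              lower.tail = FALSE),
                NA_real_)
  } else {
    p <- ifelse(e > 0, stats::pnorm(z, lower.tail = FALSE), NA_real_)
  }
  rec <- .enrichment_records(kmer, o, e, e, f, f, z, p, defined)
  attr(rec, "rank_statistic") <- rank_statistic
  rec
}

#' Score every observed k-mer and rank the list
#'
#' The main scoring entry point: builds the required count tables from a
#' sequence set, scores every observed word of length `k` under the chosen
#' background, and returns the records ranked by the model's rank statistic
#' (descending fold or Z-score, ascending binomial p-value). Ties are broken
#' by descending Z-score, then lexicographic word order; undefined records
#' sort last. Only observed words (O > 0) are scored.
#'
#' @param seqs A [sequence_set()].
#' @param k Word length.
#' @param spec A [background_spec()].
#' @param strand_policy `"both"` or `"forward_only"`.
#' @param variance Z-score spread model for the Ak-1 background (see
#'   [ak1_score()]).
#' @param pseudocount Neighbor pseudocount for the C0/C1 background.
#' @param normalization Normalization totals (see [ak1_expected()]).
#' @return A `RankedList`: a `data.frame` of enrichment records with a
#'   leading `rank` column, ordered by the rank statistic; attributes `k`,
#'   `statistic`, `spec`, and `label`.
#' @examples
#' ss <- random_sequences(5, 200, gc = 0.5, seed = 1)
#' head(enrich(ss, k = 3, background_spec("ak1")))
#' @export
enrich <- function(seqs, k, spec = background_spec("ak1"),
                   strand_policy = c("both", "forward_only"),
                   variance = c("poisson", "binomial"),
                   pseudocount = 0,
                   normalization = c("occurrences", "windows")) {
  stopifnot(inherits(seqs, "SequenceSet"), inherits(spec, "BackgroundSpec"))
  strand_policy <- match.arg(strand_policy)
  variance <- match.arg(variance)
  normalization <- match.arg(normalization)
  k <- as.integer(k)
  table_k <- build_count_table(seqs, k, strand_policy)
  words <- names(table_k$counts)
  rec <- switch(spec$model,
    ak1 = {
      if (k < 2L) stop("ak1 requires k >= 2", call. = FALSE)
      table_km1 <- build_count_table(seqs, k - 1L, strand_policy)
      mono <- mono_frequencies(seqs, strand_policy)
      ak1_score(words, table_k, table_km1, mono, variance, normalization)
    },
    c0c1 = c0c1_score(words, table_k, pseudocount),
    markov = .markov_score_tables(words, seqs, spec$markov_order, table_k,
                                  spec$rank_statistic, strand_policy,
                                  normalization)
  )
  ranked <- rank_records(rec, spec$rank_statistic)
  attr(ranked, "k") <- k
  attr(ranked, "spec") <- spec
  attr(ranked, "label") <- seqs$label
  ranked
}

#' Order enrichment records by a rank statistic
#'
#' Descending fold or Z-score, or ascending binomial p-value; ties broken by
#' descending Z-score then lexicographic word order; undefined records last.
#'
#' @param records Enrichment record `data.frame`.
#' @param statistic `"fold"`, `"zscore"` or `"binomial"`.
#' @return The records reordered, with a leading `rank` column (1-based) and
#'   attribute `statistic`; class `RankedList`.
#' @export
rank_records <- function(records, statistic = c("fold", "zscore", "binomial")) {
  statistic <- match.arg(statistic)
  ord <- switch(statistic,
    fold = order(-records$fold, -records$zscore, records$kmer, na.last = TRUE),
    zscore = order(-records$zscore, records$kmer, na.last = TRUE),
    binomial = order(records$pvalue, -records$zscore, records$kmer,
                     na.last = TRUE)
  )
  out <- records[ord, , drop = FALSE]
  row.names(out) <- NULL
  out <- cbind(rank = seq_len(nrow(out)), out)
  attr(out, "statistic") <- statistic
  class(out) <- c("RankedList", "data.frame")
  out
}

#' Write an enrichment report to TSV
#'
#' @param records Enrichment records (ranked or not).
#' @param path Output path.
#' @param header Optional named character vector echoed as `# key=value`
#'   metadata lines.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(records, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(sprintf("# %s=%s", names(header), unname(header)), con)
  df <- as.data.frame(records)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
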