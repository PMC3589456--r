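#' Partition a ranked list into equal-width fold-score bins
#'
#' The fold-enrichment range [min, max] of the defined records is divided
#' into `n_bins` equal intervals; each word goes to the bin whose interval
#' `[edge_i, edge_{i+1})` contains its fold score, with the last bin closed
#' on the right so the maximum-fold word is always binned. Undefined records
#' (vanished expectation) are excluded, with a message when any are dropped.
#' When every fold is identical the span is widened by machine epsilon and
#' all words land in the first bin.
#'
#' @param records Enrichment record `data.frame` (e.g. from [enrich()]).
#' @param n_bins Number of bins (default 8).
#' @param source_label Species/region tag; defaults to the records' `label`
#'   attribute if present.
#' @return Object of class `BinPartition`: list with `n_bins`, `edges`
#'   (length n_bins + 1), `members` (list of character vectors), and
#'   `source_label`.
#' @export
make_bins <- function(records, n_bins = 8L, source_label = NULL) {
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 1L)
  if (is.null(source_label))
    source_label <- attr(records, "label") %||% "list"
  if (nrow(records) == 0L) stop("empty record set", call. = FALSE)
  dropped <- sum(!records$defined)
  if (dropped > 0L)
    message(dropped, " undefined record(s) excluded from binning")
  rec <- records[records$defined, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no defined records to bin", call. = FALSE)
  lo <- min(rec$fold)
  hi <- max(rec$fold)
  if (hi <= lo) hi <- lo + max(1, abs(lo)) * .Machine$double.eps * n_bins
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- findInterval(rec$fold, edges, rightmost.closed = TRUE,
                      all.inside = FALSE)
  bin[bin < 1L] <- 1L  # guard against fp underflow at the left edge
  members <- split(rec$kmer, factor(bin, levels = seq_len(n_bins)))
  names(members) <- NULL
  structure(list(n_bins = n_bins, edges = edges, members = members,
                 source_label = source_label),
            class = "BinPartition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.BinPartition <- function(x, ...) {
  cat(sprintf("BinPartition '%s': %d bins over fold range [%.4g, %.4g]\n",
              x$source_label, x$n_bins, x$edges[1L],
              x$edges[x$n_bins + 1L]))
  cat("  sizes:", paste(vapply(x$members, length, integer(1)),
                        collapse = " "), "\n")
  invisible(x)
}

#' Per-bin overlap profile against a reference partition
#'
#' For each bin index i, the words of the reference bin that are also
#' present in bin i of every other partition are counted; the percentage is
#' 100 * shared / reference bin size, or NA when the reference bin is empty.
#' Each partition keeps its own fold-score edges; bins correspond by index.
#'
#' @param reference A `BinPartition` (the reference species).
#' @param others A `BinPartition` or list of them; all with the same
#'   `n_bins` as the reference.
#' @return Object of class `OverlapProfile`: list with `reference_label`,
#'   `other_labels`, and `per_bin`, a `data.frame` with columns bin,
#'   ref_bin_lo, ref_bin_hi, ref_count, shared_count, percent.
#' @export
overlap_profile <- function(reference, others) {
  stopifnot(inherits(reference, "BinPartition"))
  if (inherits(others, "BinPartition")) others <- list(others)
  stopifnot(length(others) >= 1L,
            all(vapply(others, inherits, logical(1), "BinPartition")))
  if (any(vapply(others, function(p) p$n_bins, integer(1)) !=
            reference$n_bins))
    stop("bin count mismatch between partitions", call. = FALSE)
  nb <- reference$n_bins
  rows <- lapply(seq_len(nb), function(i) {
    ref_words <- reference$members[[i]]
    shared <- Reduce(intersect,
                     lapply(others, function(p) p$members[[i]]),
                     ref_words)
    data.frame(bin = i,
               ref_bin_lo = reference$edges[i],
               ref_bin_hi = reference$edges[i + 1L],
               ref_count = length(ref_words),
               shared_count = length(shared),
               percent = if (length(ref_words) == 0L) NA_real_
                         else 100 * length(shared) / length(ref_words))
  })
  structure(list(reference_label = reference$source_label,
                 other_labels = vapply(others, function(p) p$source_label,
                                       character(1)),
                 per_bin = do.call(rbind, rows)),
            class = "OverlapProfile")
}

#' @export
print.OverlapProfile <- function(x, ...) {
  cat(sprintf("OverlapProfile: %s vs {%s}\n", x$reference_label,
              paste(x$other_labels, collapse = ", ")))
  print(x$per_bin, row.names = FALSE)
  invisible(x)
}

#' Cross-species fold-score bin-overlap comparison
#'
#' Scores every species' sequences at word length `k`, bins each ranked
#' list into `n_bins` equal fold-score intervals over that species' own
#' range, and computes an [overlap_profile()] of the reference species
#' against every non-empty combination of the other species (sizes 1 up to
#' all; combinations enumerated by size then lexicographic label order).
#'
#' @param species List of [sequence_set()] objects with distinct labels
#'   (at least 2, including the reference).
#' @param k Word length.
#' @param spec A [background_spec()].
#' @param reference_label Label of the reference species.
#' @param n_bins Number of bins (default 8).
#' @param strand_policy `"both"` or `"forward_only"`.
#' @param ... Passed on to [enrich()].
#' @return Named list of `OverlapProfile` objects, one per combination;
#'   names join the non-reference labels with `+`.
#' @export
run_comparison <- function(species, k, spec = background_spec("ak1"),
                           reference_label, n_bins = 8L,
                           strand_policy = c("both", "forward_only"), ...) {
  strand_policy <- match.arg(strand_policy)
  stopifnot(is.list(species))
  if (length(species) < 2L) stop("need at least 2 species", call. = FALSE)
  labels <- vapply(species, function(s) s$label, character(1))
  if (anyDuplicated(labels)) stop("duplicate species labels", call. = FALSE)
  if (!reference_label %in% labels)
    stop("reference species not among inputs", call. = FALSE)
  partitions <- lapply(species, function(s) {
    ranked <- enrich(s, k, spec, strand_policy = strand_policy, ...)
    make_bins(ranked, n_bins, source_label = s$label)
  })
  names(partitions) <- labels
  ref <- partitions[[reference_label]]
  rest <- sort(setdiff(labels, reference_label))
  profiles <- list()
  for (size in seq_along(rest)) {
    combos <- combn(rest, size, simplify = FALSE)
    for (cmb in combos) {
      profiles[[paste(cmb, collapse = "+")]] <-
        overlap_profile(ref, partitions[cmb])
    }
  }
  profiles
}

#' Write an overlap profile to TSV
#'
#' @param profile An `OverlapProfile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "OverlapProfile"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# reference=%s others=%s", profile$reference_label,
                     paste(profile$other_labels, collapse = "+")), con)
  utils::write.table(profile$per_bin, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
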