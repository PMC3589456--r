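#' Configuration of the motif-implantation benchmark
#'
#' Defaults reproduce the standard sensitivity test: 6,000 random sequences
#' of 500 bp whose GC content matches the S. cerevisiae genome (0.38), each
#' receiving one implanted copy of the 8-mer ATGCCGTA.
#'
#' @param n_sequences Number of random sequences.
#' @param seq_length Length of each sequence (bp).
#' @param gc GC fraction in (0, 1).
#' @param motif DNA word to implant.
#' @param implants_per_sequence Implanted copies per sequence (0 gives a
#'   null run with no implants).
#' @param seed Integer RNG seed (mandatory).
#' @return Object of class `ImplantSimConfig`.
#' @export
implant_sim_config <- function(n_sequences = 6000L, seq_length = 500L,
                               gc = 0.38, motif = "ATGCCGTA",
                               implants_per_sequence = 1L, seed) {
  if (missing(seed) || is.null(seed))
    stop("seed is required", call. = FALSE)
  stopifnot(n_sequences >= 1, seq_length >= 1,
            is.character(motif), length(motif) == 1L)
  if (grepl("[^ACGT]", motif)) stop("motif must be over {A,C,G,T}",
                                    call. = FALSE)
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)", call. = FALSE)
  implants_per_sequence <- as.integer(implants_per_sequence)
  if (implants_per_sequence < 0L)
    stop("implants_per_sequence must be >= 0", call. = FALSE)
  if (implants_per_sequence * nchar(motif) > seq_length)
    stop("implants do not fit in the sequence length", call. = FALSE)
  structure(list(n_sequences = as.integer(n_sequences),
                 seq_length = as.integer(seq_length), gc = gc,
                 motif = motif,
                 implants_per_sequence = implants_per_sequence,
                 seed = as.integer(seed)),
            class = "ImplantSimConfig")
}

#' Generate GC-controlled random sequences
#'
#' Bases are iid with P(G) = P(C) = gc/2 and P(A) = P(T) = (1 - gc)/2.
#'
#' @param n Number of sequences.
#' @param length Length of each sequence.
#' @param gc GC fraction in (0, 1).
#' @param seed Integer RNG seed (mandatory; output is reproducible).
#' @param label Label of the resulting set.
#' @return A [sequence_set()] with records `seq_1`, ..., `seq_n`.
#' @export
random_sequences <- function(n, length, gc, seed, label = "random") {
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)", call. = FALSE)
  stopifnot(n >= 1, length >= 1)
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  draw <- sample(bases, n * length, replace = TRUE, prob = prob)
  mat <- matrix(draw, nrow = length, ncol = n)
  x <- apply(mat, 2L, paste0, collapse = "")
  names(x) <- paste0("seq_", seq_len(n))
  sequence_set(x, label = label)
}

#' Implant a motif into every sequence
#'
#' In each record, `implants_per_sequence` windows chosen uniformly at
#' random without overlap are overwritten by `motif` (lengths unchanged).
#' Every output sequence therefore contains at least that many occurrences.
#'
#' @param seqs A [sequence_set()].
#' @param motif DNA word over `{A,C,G,T}`.
#' @param implants_per_sequence Copies per sequence; 0 returns the input
#'   unchanged.
#' @param seed Integer RNG seed (mandatory).
#' @return A new `SequenceSet` with the same ids, lengths and label.
#' @export
implant_motif <- function(seqs, motif, implants_per_sequence = 1L, seed) {
  stopifnot(inherits(seqs, "SequenceSet"))
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  m <- as.integer(implants_per_sequence)
  if (m < 0L) stop("implants_per_sequence must be >= 0", call. = FALSE)
  if (m == 0L) return(seqs)
  if (grepl("[^ACGT]", motif)) stop("motif must be over {A,C,G,T}",
                                    call. = FALSE)
  k <- nchar(motif)
  set.seed(as.integer(seed))
  x <- as.character(seqs$seq)
  lens <- nchar(x)
  if (any(m * k > lens))
    stop("cannot place non-overlapping implants in every sequence",
         call. = FALSE)
  for (i in seq_along(x)) {
    n_off <- lens[i] - k + 1L
    offs <- NULL
    for (try in seq_len(1000L)) {
      cand <- sort(sample.int(n_off, m))
      if (m == 1L || all(diff(cand) >= k)) { offs <- cand; break }
    }
    if (is.null(offs))
      stop("cannot place non-overlapping implants in sequence ", i,
           call. = FALSE)
    for (o in offs) substr(x[i], o, o + k - 1L) <- motif
  }
  sequence_set(x, label = seqs$label)
}

#' Run the motif-implantation benchmark
#'
#' Generates the random sequence set, implants the motif, counts words of
#' the motif's length on both strands, scores every observed word under the
#' chosen background, and reports the motif's rank when the list is ordered
#' by decreasing Z-score and by decreasing fold enrichment.
#'
#' The generation and implantation stages consume seeds `seed` and
#' `seed + 1` respectively, so a single config seed fixes the whole run.
#'
#' @param config An [implant_sim_config()].
#' @param spec A [background_spec()].
#' @param ... Passed on to [enrich()] (e.g. `variance`, `normalization`).
#' @return Object of class `BenchmarkResult`: list with `rank_by_z`,
#'   `rank_by_fold`, `top10_by_z`, `top10_by_fold`, `motif_record` (the
#'   motif's enrichment record), `n_scored` (number of ranked words),
#'   `ranked` (the full Z-ranked list) and `config`.
#' @export
run_implant_benchmark <- function(config, spec = background_spec("ak1"),
                                  ...) {
  stopifnot(inherits(config, "ImplantSimConfig"),
            inherits(spec, "BackgroundSpec"))
  seqs <- random_sequences(config$n_sequences, config$seq_length, config$gc,
                           seed = config$seed, label = "implant_benchmark")
  seqs <- implant_motif(seqs, config$motif, config$implants_per_sequence,
                        seed = config$seed + 1L)
  k <- nchar(config$motif)
  ranked <- enrich(seqs, k, spec, ...)
  rec <- as.data.frame(ranked)
  rec <- rec[, setdiff(names(rec), "rank"), drop = FALSE]
  by_z <- rank_records(rec, "zscore")
  by_fold <- rank_records(rec, "fold")
  rank_of <- function(lst) {
    r <- lst$rank[match(config$motif, lst$kmer)]
    if (is.na(r)) stop("motif not present in the scored table",
                       call. = FALSE)
    r
  }
  structure(list(
    rank_by_z = rank_of(by_z),
    rank_by_fold = rank_of(by_fold),
    top10_by_z = top_n(by_z, 10L),
    top10_by_fold = top_n(by_fold, 10L),
    motif_record = by_z[by_z$kmer == config$motif, , drop = FALSE],
    n_scored = nrow(by_z),
    ranked = by_z,
    config = config
  ), class = "BenchmarkResult")
}

#' @export
print.BenchmarkResult <- function(x, ...) {
  cat(sprintf(
    "Implant benchmark: motif %s ranks %d by Z-score, %d by fold (of %d words)\n",
    x$config$motif, x$rank_by_z, x$rank_by_fold, x$n_scored))
  cat("  top 10 by Z:   ", paste(x$top10_by_z, collapse = " "), "\n")
  cat("  top 10 by fold:", paste(x$top10_by_fold, collapse = " "), "\n")
  invisible(x)
}

#' Simulate related species from a common ancestor
#'
#' One ancestral iid random genome is generated; each species is the
#' ancestor with iid per-base substitutions at `mutation_rate`, the mutated
#' base drawn uniformly from the three other bases. Expected pairwise
#' sequence identity between two species is (1-r)^2 + r^2/3.
#'
#' @param n_species Number of species to derive.
#' @param genome_length Length of the (single-record) genome.
#' @param gc Ancestral GC fraction in (0, 1).
#' @param mutation_rate Per-base substitution probability in \[0, 1).
#' @param seed Integer RNG seed (mandatory).
#' @return Named list of `SequenceSet` objects labeled `species_1`, ...
#' @export
synthetic_species <- function(n_species, genome_length, gc = 0.38,
                              mutation_rate = 0.01, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  stopifnot(n_species >= 1, genome_length >= 1)
  if (mutation_rate < 0 || mutation_rate >= 1)
    stop("mutation_rate must be in [0, 1)", call. = FALSE)
  anc <- random_sequences(1L, genome_length, gc, seed = seed,
                          label = "ancestor")
  anc_chars <- strsplit(as.character(anc$seq)[[1L]], "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  anc_idx <- match(anc_chars, bases)
  out <- vector("list", n_species)
  for (s in seq_len(n_species)) {
    hit <- stats::runif(genome_length) < mutation_rate
    chars <- anc_chars
    if (any(hit)) {
      shift <- sample.int(3L, sum(hit), replace = TRUE)
      chars[hit] <- bases[(anc_idx[hit] - 1L + shift) %% 4L + 1L]
    }
    label <- paste0("species_", s)
    genome <- paste0(chars, collapse = "")
    names(genome) <- "chr1"
    out[[s]] <- sequence_set(genome, label = label)
  }
  names(out) <- paste0("species_", seq_len(n_species))
  out
}
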