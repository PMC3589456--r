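#' Construct a sequence set
#'
#' A `SequenceSet` is the package's container for a labeled collection of DNA
#' sequences (a genome, a set of promoter regions, a simulated sequence set).
#' Residues are normalized to uppercase; IUPAC ambiguity codes other than N
#' are converted to N with a warning; `U` and non-nucleotide characters are
#' rejected.
#'
#' @param x A named character vector of sequences or a
#'   [Biostrings::DNAStringSet]. Names are the record identifiers and must be
#'   unique; unnamed input gets identifiers `seq_1`, `seq_2`, ...
#' @param label Single string naming the set (species or region tag); used to
#'   label downstream results.
#' @return An object of class `SequenceSet`: a list with elements `seq`
#'   (a `DNAStringSet`) and `label`.
#' @examples
#' ss <- sequence_set(c(s1 = "acgtACGT", s2 = "NNNN"), label = "demo")
#' sequence_length(ss)
#' @export
sequence_set <- function(x, label = "sequences") {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (methods::is(x, "DNAStringSet")) x <- as.character(x)
  if (!is.character(x) || length(x) == 0L)
    stop("no sequences", call. = FALSE)
  ids <- names(x)
  if (is.null(ids)) ids <- paste0("seq_", seq_along(x))
  if (anyDuplicated(ids)) stop("duplicate sequence ids", call. = FALSE)
  res <- toupper(x)
  if (any(grepl("U", res, fixed = TRUE)))
    stop("RNA residue 'U' is not accepted", call. = FALSE)
  bad <- grepl("[^ACGTNRYSWKMBDHV]", res)
  if (any(bad))
    stop("invalid residue in record(s): ", paste(ids[bad], collapse = ", "),
         call. = FALSE)
  amb <- grepl("[RYSWKMBDHV]", res)
  if (any(amb)) {
    warning(sum(amb), " record(s) contained IUPAC ambiguity codes; ",
            "converted to N", call. = FALSE)
    res <- chartr("RYSWKMBDHV", "NNNNNNNNNN", res)
  }
  if (sum(nchar(res)) == 0L) stop("no sequences", call. = FALSE)
  seq <- Biostrings::DNAStringSet(res)
  names(seq) <- ids
  structure(list(seq = seq, label = label), class = "SequenceSet")
}

#' @export
print.SequenceSet <- function(x, ...) {
  cat(sprintf("SequenceSet '%s': %d record(s), %d residues\n",
              x$label, length(x$seq), sequence_length(x)))
  invisible(x)
}

#' @export
length.SequenceSet <- function(x) length(x$seq)

#' @export
as.character.SequenceSet <- function(x, ...) as.character(x$seq)

#' Total residue count of a sequence set
#'
#' @param seqs A `SequenceSet`.
#' @return Integer total number of residues (N included) across all records.
#' @export
sequence_length <- function(seqs) {
  stopifnot(inherits(seqs, "SequenceSet"))
  sum(Biostrings::width(seqs$seq))
}

#' Read a multi-FASTA file into a SequenceSet
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @param label Label for the set; defaults to the file name without
#'   extension.
#' @return A [sequence_set()].
#' @export
read_fasta <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  # invalid residue codes (digits, punctuation) are fatal, not dropped
  dss <- withCallingHandlers(
    tryCatch(
      Biostrings::readDNAStringSet(path),
      error = function(e)
        stop("parse error in ", path, ": ", conditionMessage(e),
             call. = FALSE)
    ),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("parse error in ", path, ": ", conditionMessage(w),
             call. = FALSE)
      invokeRestart("muffleWarning")
    }
  )
  if (length(dss) == 0L) stop("no sequences in ", path, call. = FALSE)
  x <- as.character(dss)
  # FASTA descriptions: keep the first whitespace-delimited token as the id
  names(x) <- sub("\\s.*$", "", names(x))
  sequence_set(x, label = label)
}

#' Write a SequenceSet to a FASTA file
#'
#' @param seqs A `SequenceSet`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(inherits(seqs, "SequenceSet"))
  Biostrings::writeXStringSet(seqs$seq, filepath = path, width = width)
  invisible(path)
}

#' Reverse complement of DNA words
#'
#' Standard Watson-Crick complement, reversed; N maps to N. Vectorized.
#'
#' @param word Character vector of DNA words over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement(c("ACGT", "TAGTGTA"))
#' @export
reverse_complement <- function(word) {
  if (!is.character(word) || any(is.na(word)))
    stop("word must be a character vector", call. = FALSE)
  if (any(grepl("[^ACGTN]", word)))
    stop("non-DNA character in word", call. = FALSE)
  out <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(word)))
  names(out) <- NULL
  out
}

#' Read a plain-text k-mer list
#'
#' One word per line, with an optional leading integer rank separated by
#' whitespace. Blank lines and lines starting with `#` are skipped. A warning
#' is raised if the words are not all the same length.
#'
#' @param path Path to the list file.
#' @return Character vector of words, input order preserved.
#' @export
read_kmer_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(character(0))
  fields <- strsplit(lines, "\\s+")
  words <- vapply(fields, function(f) {
    if (length(f) >= 2L && grepl("^[0-9]+$", f[[1L]])) f[[2L]] else f[[1L]]
  }, character(1))
  words <- toupper(words)
  bad <- grepl("[^ACGT]", words)
  if (any(bad))
    stop("invalid characters in k-mer list at line(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  if (length(unique(nchar(words))) > 1L)
    warning("k-mer list mixes word lengths", call. = FALSE)
  words
}
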