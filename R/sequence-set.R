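#' Construct a sequence set
#'
#' A sequence set bundles `n >= 2` equal-length sequences over a declared
#' alphabet; it is the input container of every search driver. The first
#' sequence plays a distinguished role: candidate l-mers are drawn from it.
#'
#' @param sequences character vector of sequences, all the same length.
#' @param alphabet alphabet specification understood by [mss_alphabet()]
#'   (default `"auto"`).
#' @return An object of class `sequence_set` with fields `sequences`,
#'   `alphabet`, `n` (number of sequences) and `m` (common length).
#' @examples
#' ss <- sequence_set(c("ACGTACG", "ACGTACG"))
#' ss$n
#' ss$m
#' @export
sequence_set <- function(sequences, alphabet = "auto") {
  sequences <- as.character(sequences)
  nm <- names(sequences)
  if (is.null(nm)) nm <- paste0("seq", seq_along(sequences))
  if (length(sequences) < 2L) {
    stop("a sequence set needs at least 2 sequences", call. = FALSE)
  }
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1L])[1L]
    stop("sequences must all have the same length; record ", bad,
         " ('", nm[bad], "') has length ", lens[bad],
         " but record 1 has length ", lens[1L], call. = FALSE)
  }
  alphabet <- mss_alphabet(alphabet, sequences)
  for (i in seq_along(sequences)) {
    ch <- unique(.chars(sequences[i]))
    out <- setdiff(ch, alphabet)
    if (length(out) > 0L) {
      stop("record ", i, " ('", nm[i], "') contains character(s) outside ",
           "the alphabet: ", paste(out, collapse = " "), call. = FALSE)
    }
  }
  structure(
    list(sequences = unname(sequences), names = nm, alphabet = alphabet,
         n = length(sequences), m = lens[1L]),
    class = "sequence_set"
  )
}

#' @export
print.sequence_set <- function(x, ...) {
  cat("Sequence set: ", x$n, " sequences of length ", x$m,
      " over a ", length(x$alphabet), "-letter alphabet\n", sep = "")
  show <- utils::head(x$sequences, 3L)
  for (s in show) {
    cat("  ", if (nchar(s) > 60L) paste0(substr(s, 1L, 57L), "...") else s,
        "\n", sep = "")
  }
  if (x$n > 3L) cat("  ... and ", x$n - 3L, " more\n", sep = "")
  invisible(x)
}

# Encode every sequence of a set; returns list of integer vectors.
.encode_set <- function(x) lapply(x$sequences, .encode, alphabet = x$alphabet)

#' Read a sequence set from a FASTA file
#'
#' All records must have the same length and use only characters of the
#' declared alphabet; the first record becomes the candidate sequence from
#' which the search drivers draw their l-mers.
#'
#' @param path path to a FASTA file.
#' @param alphabet alphabet specification, see [mss_alphabet()].
#' @return A [sequence_set()].
#' @export
read_fasta <- function(path, alphabet = "auto") {
  xs <- Biostrings::readBStringSet(path)
  if (length(xs) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  seqs <- as.character(xs)
  sequence_set(seqs, alphabet)
}

#' Write a sequence set to a FASTA file
#'
#' @param x a [sequence_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "sequence_set"))
  xs <- Biostrings::BStringSet(x$sequences)
  names(xs) <- x$names
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' Write stems to a plain-text file
#'
#' One stem per line, wildcards rendered as `*`, lines sorted
#' lexicographically (byte order) so output is deterministic across runs and
#' locales.
#'
#' @param stems character vector of stems, or a [stem_result] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stems <- function(stems, path) {
  if (inherits(stems, "stem_result")) stems <- stems$stems
  stems <- as.character(stems)
  if (length(stems) > 0L && length(unique(nchar(stems))) != 1L) {
    stop("stems must all have the same length", call. = FALSE)
  }
  writeLines(.lex_sort(unique(stems)), path)
  invisible(path)
}
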