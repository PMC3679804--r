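#' Standard sequence alphabets
#'
#' Resolve an alphabet specification to an ordered character vector. The two
#' built-in alphabets are the four DNA bases and the twenty standard amino
#' acids. `"auto"` inspects a set of sequences and picks the smallest built-in
#' alphabet containing every observed character, falling back to the sorted set
#' of observed characters for non-standard inputs.
#'
#' The wildcard character `"*"` is reserved for stems and may never be a member
#' of a sequence alphabet.
#'
#' @param alphabet `"dna"`, `"protein"`, `"auto"`, or a character vector of
#'   single characters.
#' @param sequences character vector of sequences, consulted only when
#'   `alphabet = "auto"`.
#' @return Ordered character vector of single characters.
#' @examples
#' mss_alphabet("dna")
#' mss_alphabet("auto", c("MSSKW", "QQRHL"))
#' @export
mss_alphabet <- function(alphabet, sequences = NULL) {
  if (is.character(alphabet) && length(alphabet) == 1L && nchar(alphabet) > 1L) {
    alphabet <- match.arg(tolower(alphabet), c("dna", "protein", "auto"))
    if (alphabet == "dna") return(DNA_ALPHABET)
    if (alphabet == "protein") return(PROTEIN_ALPHABET)
    if (is.null(sequences)) {
      stop("alphabet = \"auto\" requires sequences to inspect", call. = FALSE)
    }
    seen <- unique(unlist(strsplit(toupper(sequences), "", fixed = TRUE)))
    if (all(seen %in% DNA_ALPHABET)) return(DNA_ALPHABET)
    if (all(seen %in% PROTEIN_ALPHABET)) return(PROTEIN_ALPHABET)
    return(sort(seen, method = "radix"))
  }
  alphabet <- as.character(alphabet)
  if (any(nchar(alphabet) != 1L)) {
    stop("alphabet members must be single characters", call. = FALSE)
  }
  if (anyDuplicated(alphabet)) {
    stop("alphabet members must be unique", call. = FALSE)
  }
  if (WILDCARD %in% alphabet) {
    stop("the wildcard character '", WILDCARD,
         "' cannot be a member of a sequence alphabet", call. = FALSE)
  }
  if (length(alphabet) < 2L) stop("alphabet must have at least 2 characters", call. = FALSE)
  alphabet
}

#' @rdname mss_alphabet
#' @format `DNA_ALPHABET`: the four DNA bases.
#' @export
DNA_ALPHABET <- c("A", "C", "G", "T")

#' @rdname mss_alphabet
#' @format `PROTEIN_ALPHABET`: the twenty standard amino acids, alphabetical.
#' @export
PROTEIN_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname mss_alphabet
#' @format `WILDCARD`: the wildcard character used in stems.
#' @export
WILDCARD <- "*"
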