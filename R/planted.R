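#' Generate a synthetic planted-motif instance
#'
#' Builds the standard planted (l,d)-motif benchmark: `n` IID-uniform random
#' sequences of length `m`; one motif of length `l` drawn uniformly; per
#' sequence, a mutated copy of the motif (a uniformly chosen number of
#' mismatch positions between 0 and `d`, each replaced by a different,
#' uniformly chosen character) overwrites a uniformly chosen window. By
#' construction the motif is an (l,d)-motif of the resulting set.
#'
#' The generator uses its own seeded random stream and leaves the session's
#' RNG state untouched, so the same arguments always yield the same instance.
#'
#' @param n number of sequences (benchmark default 20).
#' @param m sequence length (benchmark default 600).
#' @param l motif length.
#' @param d maximum number of substitutions per planted copy.
#' @param alphabet alphabet specification, see [mss_alphabet()]
#'   (default `"protein"`).
#' @param seed integer seed; required for reproducibility.
#' @return An object of class `planted_instance`: a list with the
#'   `sequence_set`, the ground-truth `motif`, 1-based `positions` of each
#'   planted copy, the mutated `instances`, and `l`, `d`, `seed`.
#' @examples
#' pi <- generate_planted_instance(n = 5, m = 50, l = 7, d = 1,
#'                                 alphabet = "dna", seed = 1)
#' pi$motif
#' substr(pi$sequence_set$sequences[1], pi$positions[1], pi$positions[1] + 6)
#' @export
generate_planted_instance <- function(n = 20, m = 600, l, d,
                                      alphabet = "protein", seed) {
  alphabet <- mss_alphabet(alphabet)
  sigma <- length(alphabet)
  n <- as.integer(n); m <- as.integer(m); l <- as.integer(l); d <- as.integer(d)
  if (n < 2L) stop("n must be at least 2", call. = FALSE)
  if (l > m) stop("motif length l = ", l, " exceeds sequence length m = ", m,
                  call. = FALSE)
  if (d > l) stop("d = ", d, " exceeds motif length l = ", l, call. = FALSE)
  if (d < 0L) stop("d must be non-negative", call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)

  .with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(alphabet, m, replace = TRUE), collapse = "")
    }, character(1))
    motif_ch <- sample(alphabet, l, replace = TRUE)
    positions <- integer(n)
    instances <- character(n)
    for (i in seq_len(n)) {
      inst <- motif_ch
      k <- sample.int(d + 1L, 1L) - 1L          # uniform on 0..d
      if (k > 0L) {
        pos <- sample.int(l, k)
        for (p in pos) {
          others <- setdiff(alphabet, inst[p])  # guarantee a true mismatch
          inst[p] <- others[sample.int(sigma - 1L, 1L)]
        }
      }
      start <- sample.int(m - l + 1L, 1L)
      substr(seqs[i], start, start + l - 1L) <- paste(inst, collapse = "")
      positions[i] <- start
      instances[i] <- paste(inst, collapse = "")
    }
    structure(
      list(sequence_set = sequence_set(seqs, alphabet),
           motif = paste(motif_ch, collapse = ""),
           positions = positions, instances = instances,
           l = l, d = d, seed = as.integer(seed)),
      class = "planted_instance"
    )
  })
}

#' @export
print.planted_instance <- function(x, ...) {
  cat("Planted (", x$l, ",", x$d, ")-motif instance, seed ", x$seed, "\n",
      sep = "")
  cat("  motif: ", x$motif, "\n", sep = "")
  cat("  ", x$sequence_set$n, " sequences of length ", x$sequence_set$m,
      ", sigma = ", length(x$sequence_set$alphabet), "\n", sep = "")
  invisible(x)
}

#' Write a planted instance to disk
#'
#' Writes the sequences as FASTA plus a sidecar key-value text file holding
#' the ground truth (motif, plant positions, mutated instances, parameters,
#' seed) so a benchmark run can be scored later.
#'
#' @param x a `planted_instance`.
#' @param fasta_path output FASTA path.
#' @param meta_path output metadata path (default: `fasta_path` + `.meta`).
#' @return `fasta_path`, invisibly.
#' @export
write_planted_instance <- function(x, fasta_path,
                                   meta_path = paste0(fasta_path, ".meta")) {
  stopifnot(inherits(x, "planted_instance"))
  write_fasta(x$sequence_set, fasta_path)
  writeLines(c(
    paste0("motif: ", x$motif),
    paste0("l: ", x$l),
    paste0("d: ", x$d),
    paste0("seed: ", x$seed),
    paste0("positions: ", paste(x$positions, collapse = ",")),
    paste0("instances: ", paste(x$instances, collapse = ","))
  ), meta_path)
  invisible(fasta_path)
}
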