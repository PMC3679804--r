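#' 2d-neighbours of an l-mer within a sequence
#'
#' Lists the (1-based) start positions of the windows of `s` whose Hamming
#' distance to `x` is at most `2d`. The doubled radius is what makes the
#' filter sound: two l-mers that both lie within distance `d` of some motif
#' are within distance `2d` of each other, so windows beyond `2d` can share
#' no d-neighbour with `x`.
#'
#' @param x an l-mer (string).
#' @param s a sequence (string).
#' @param d maximum mismatches of the motif model; the search radius is `2d`.
#' @return Increasing integer vector of window start positions.
#' @export
collect_2d_neighbors <- function(x, s, d) {
  a <- .chars(x); b <- .chars(s)
  l <- length(a); m <- length(b)
  if (l > m) stop("l-mer longer than sequence", call. = FALSE)
  R <- m - l + 1L
  dist <- integer(R)
  for (o in 0:(l - 1L)) dist <- dist + (b[seq_len(R) + o] != a[o + 1L])
  which(dist <= 2L * d)
}

#' Neighbour matrix of all candidate l-mers
#'
#' For every l-mer of the first sequence and every other sequence `s_i`
#' (`i = 2..n`), records the start offsets of the 2d-neighbours of the
#' candidate in `s_i`. Built from the diagonal-recurrence distance matrix
#' against each sequence, thresholded at `2d`; this is the O(m^2 n)
#' preprocessing that the fast search driver trades O(m^2) memory for.
#'
#' @param seqs a [sequence_set()].
#' @param l motif length.
#' @param d maximum mismatches.
#' @return An object of class `neighbor_matrix`: `entries[[k]][[i - 1]]` holds
#'   the offsets in sequence `i` for the candidate starting at `k` in
#'   sequence 1.
#' @export
build_neighbor_matrix <- function(seqs, l, d) {
  stopifnot(inherits(seqs, "sequence_set"))
  .check_params(seqs, l, d)
  R <- seqs$m - l + 1L
  entries <- lapply(seq_len(R), function(k) vector("list", seqs$n - 1L))
  for (i in 2:seqs$n) {
    D <- distance_matrix_diagonal(seqs$sequences[1L], seqs$sequences[i], l)
    hits <- D <= 2L * d
    for (k in seq_len(R)) entries[[k]][[i - 1L]] <- which(hits[k, ])
  }
  structure(list(entries = entries, l = as.integer(l), d = as.integer(d),
                 n = seqs$n, n_candidates = R),
            class = "neighbor_matrix")
}

#' @export
print.neighbor_matrix <- function(x, ...) {
  sizes <- vapply(x$entries, function(e) sum(lengths(e)), integer(1))
  cat("Neighbour matrix: ", x$n_candidates, " candidate l-mers x ",
      x$n - 1L, " sequences (l = ", x$l, ", d = ", x$d, ")\n", sep = "")
  cat("  total 2d-neighbour entries: ", sum(sizes), "\n", sep = "")
  invisible(x)
}

#' Select the minimal-neighbour sequence for a candidate l-mer
#'
#' Applies the skip rule and the minimal-list selection: a candidate is
#' skipped as soon as some sequence contains no 2d-neighbour of it (no
#' d-neighbour of the candidate can then be a motif); otherwise the sequence
#' with the fewest 2d-neighbours is chosen (ties broken toward the lowest
#' sequence index) and its neighbour list becomes the pairing set for stem
#' generation. Sequences are scanned in input order 2..n with early exit on
#' the first empty list.
#'
#' @param x_index candidate window start in sequence 1.
#' @param matrix a `neighbor_matrix`.
#' @return A list with `x_index`, `status` (`"viable"` or `"skipped"`),
#'   `min_seq_index` (the selected sequence, `NA` when skipped) and `i_min`
#'   (its neighbour offsets, empty when skipped).
#' @export
select_candidate <- function(x_index, matrix) {
  stopifnot(inherits(matrix, "neighbor_matrix"))
  if (x_index < 1L || x_index > matrix$n_candidates) {
    stop("x_index out of range", call. = FALSE)
  }
  lists <- matrix$entries[[x_index]]
  best_i <- NA_integer_
  best_size <- Inf
  for (i in seq_along(lists)) {           # i = 1 means sequence 2
    sz <- length(lists[[i]])
    if (sz == 0L) {
      return(list(x_index = x_index, status = "skipped",
                  min_seq_index = NA_integer_, i_min = integer(0)))
    }
    if (sz < best_size) {
      best_size <- sz
      best_i <- i
    }
  }
  list(x_index = x_index, status = "viable",
       min_seq_index = best_i + 1L, i_min = lists[[best_i]])
}

.check_params <- function(seqs, l, d) {
  if (l < 1L || l > seqs$m) {
    stop("l = ", l, " must be in [1, m = ", seqs$m, "]", call. = FALSE)
  }
  if (d < 0L || d > l) stop("d = ", d, " must be in [0, l = ", l, "]",
                            call. = FALSE)
  if (seqs$n < 2L) stop("need at least 2 sequences", call. = FALSE)
  invisible(TRUE)
}
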