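#' Hamming distance between two l-mers
#'
#' @param x,y strings of equal length.
#' @return Integer number of positions at which `x` and `y` differ.
#' @examples
#' hamming_lmer("gaaac", "gaaac")
#' hamming_lmer("ggaac", "gaaac")
#' @export
hamming_lmer <- function(x, y) {
  a <- .chars(x); b <- .chars(y)
  if (length(a) != length(b)) {
    stop("l-mers must have equal length (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  }
  sum(a != b)
}

#' Minimum Hamming distance from an l-mer to a sequence
#'
#' The distance from an l-mer `x` to a sequence `s` is the minimum Hamming
#' distance between `x` and any length-`l` window of `s`.
#'
#' @param x an l-mer (string).
#' @param s a sequence (string) with `nchar(s) >= nchar(x)`.
#' @return Integer minimum window distance.
#' @export
min_distance_to_sequence <- function(x, s) {
  a <- .chars(x); b <- .chars(s)
  l <- length(a); m <- length(b)
  if (l > m) stop("l-mer longer than sequence (", l, " > ", m, ")", call. = FALSE)
  R <- m - l + 1L
  d <- integer(R)
  for (o in 0:(l - 1L)) d <- d + (b[seq_len(R) + o] != a[o + 1L])
  min(d)
}

#' Pairwise l-mer distance matrix, naive computation
#'
#' Entry `[a, b]` is the Hamming distance between the window of `s1` starting
#' at `a` and the window of `si` starting at `b` (1-based starts). Costs
#' O(m^2 l) character comparisons; the reference against which the diagonal
#' recurrence is checked.
#'
#' @param s1,si sequences (strings) of equal length `m`.
#' @param l window length, `l <= m`.
#' @return An (m-l+1) x (m-l+1) integer matrix.
#' @seealso [distance_matrix_diagonal()] for the O(m^2) computation.
#' @export
distance_matrix_naive <- function(s1, si, l) {
  a <- .chars(s1); b <- .chars(si)
  .check_pair(a, b, l)
  R <- length(a) - l + 1L
  D <- matrix(0L, R, R)
  for (o in 0:(l - 1L)) {
    D <- D + outer(a[seq_len(R) + o], b[seq_len(R) + o], `!=`)
  }
  storage.mode(D) <- "integer"
  D
}

#' Pairwise l-mer distance matrix via the diagonal recurrence
#'
#' Produces exactly the matrix of [distance_matrix_naive()] in O(m^2) time.
#' Along a diagonal, consecutive cells pair windows that share an (l-1)-mer:
#' shifting both windows right by one drops the leading character pair and
#' gains a trailing one, so each cell follows from its predecessor with at
#' most a +/-1 update. One full O(l) Hamming evaluation seeds the top cell of
#' each of the m diagonals; diagonals on which the `si` window starts before
#' the `s1` window are handled by wrapping `si` with modular indexing
#' (conceptually, scanning against `si` appended to itself) and the wrapped
#' rows, which pair no real window, are discarded when the matrix is
#' assembled.
#'
#' @inheritParams distance_matrix_naive
#' @return An (m-l+1) x (m-l+1) integer matrix identical to the naive result.
#' @export
distance_matrix_diagonal <- function(s1, si, l) {
  a <- .chars(s1); b <- .chars(si)
  .check_pair(a, b, l)
  m <- length(a)
  R <- m - l + 1L
  g <- 0:(m - 1L)                       # diagonal = si start offset of row 1
  seed <- integer(m)
  for (o in 0:(l - 1L)) seed <- seed + (a[1L + o] != b[((g + o) %% m) + 1L])
  G <- matrix(0L, R, m)
  G[1L, ] <- seed
  if (R > 1L) {
    for (r in 2:R) {
      dropped <- a[r - 1L] != b[((g + r - 2L) %% m) + 1L]
      gained  <- a[r + l - 1L] != b[((g + r + l - 2L) %% m) + 1L]
      G[r, ] <- G[r - 1L, ] + (gained - dropped)
    }
  }
  # keep only cells whose si window does not wrap: cell (r, c) lives on
  # diagonal (c - r) mod m
  r_idx <- rep.int(seq_len(R), R)
  c_idx <- rep(seq_len(R), each = R)
  D <- matrix(G[cbind(r_idx, ((c_idx - r_idx) %% m) + 1L)], R, R)
  storage.mode(D) <- "integer"
  D
}

.check_pair <- function(a, b, l) {
  if (length(a) != length(b)) {
    stop("sequences must have equal length (", length(a), " vs ", length(b),
         ")", call. = FALSE)
  }
  if (l < 1L || l > length(a)) {
    stop("window length l = ", l, " must be in [1, ", length(a), "]",
         call. = FALSE)
  }
  invisible(TRUE)
}
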