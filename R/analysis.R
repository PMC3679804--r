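#' Probability that two random l-mers are within t mismatches
#'
#' Under an IID uniform background over a `sigma`-letter alphabet, each
#' position of two random l-mers mismatches independently with probability
#' `(sigma - 1) / sigma`, so the distance is Binomial(l, (sigma-1)/sigma) and
#' this function returns its lower tail
#' `sum_{i=0}^{t} choose(l, i) ((sigma-1)/sigma)^i (1/sigma)^(l-i)`.
#' Terms are accumulated in log space so extreme regimes (large alphabet,
#' long l-mers) do not underflow.
#'
#' With `t = 2d` this is the probability that a random window passes the
#' neighbour filter; with `t = d`, the probability that a random window is a
#' d-neighbour.
#'
#' @param l l-mer length.
#' @param t mismatch bound, `0 <= t <= l`.
#' @param sigma alphabet size, at least 2.
#' @return A probability.
#' @examples
#' p_at_most(7, 2, 4)    # ~1.29e-2
#' p_at_most(9, 4, 20)   # ~3.32e-5
#' @export
p_at_most <- function(l, t, sigma) {
  l <- as.integer(l); t <- as.integer(t)
  if (sigma < 2) stop("sigma must be at least 2", call. = FALSE)
  if (t < 0L || t > l) stop("t must be in [0, l]", call. = FALSE)
  i <- 0:t
  log_terms <- lchoose(l, i) + i * log(sigma - 1) - l * log(sigma)
  # summing smallest-first keeps the accumulation well conditioned;
  # clamp the rounding overshoot at full support
  min(1, sum(exp(sort(log_terms))))
}

#' Expected number of spurious (l,d)-motifs
#'
#' For `n` random sequences of length `m`, the chance that a fixed l-mer has
#' a d-neighbour in one sequence is `P = 1 - (1 - p)^(m - l + 1)` with
#' `p = p_at_most(l, d, sigma)`, so `sigma^l * P^n` l-mers are expected to
#' qualify as (l,d)-motifs by chance alone.
#'
#' @inheritParams p_at_most
#' @param d mismatch bound of the motif model.
#' @param n number of sequences.
#' @param m sequence length.
#' @return Expected count (may be astronomically small or large).
#' @export
expected_random_motifs <- function(l, d, sigma, n, m) {
  if (m < l) stop("m must be at least l", call. = FALSE)
  p <- p_at_most(l, d, sigma)
  # 1 - (1 - p)^(m-l+1), stable for tiny p
  P <- -expm1((m - l + 1) * log1p(-p))
  if (P <= 0) return(0)
  exp(l * log(sigma) + n * log(P))
}

#' Smallest d making random (l,d)-motifs expected
#'
#' The challenging-instance computation: for a given motif length `l`, the
#' smallest `d` at which [expected_random_motifs()] reaches 1 on a benchmark
#' of `n` sequences of length `m`. At that `d`, spurious motifs start
#' appearing by chance, which is what makes the instance hard.
#'
#' @inheritParams expected_random_motifs
#' @return The smallest such integer `d` (always exists: `d = l` gives
#'   expectation `sigma^l`).
#' @examples
#' challenging_d(9, 4, 20, 600)    # the classic DNA (9,2) instance
#' challenging_d(9, 20, 20, 600)   # proteins need d = 5
#' @export
challenging_d <- function(l, sigma, n = 20, m = 600) {
  for (d in 0:l) {
    if (expected_random_motifs(l, d, sigma, n, m) >= 1) return(as.integer(d))
  }
  as.integer(l)   # unreachable: d = l always satisfies
}

#' Order-of-magnitude bound on the expected stem count
#'
#' The expected number of window pairs passing the 2d filter between two
#' random sequences is `m^2 * p_at_most(l, 2d, sigma)`; multiplying by the
#' crude per-pair bound `2^l * l^d` on the stems one pair can generate gives
#' `m^2 p 2^l l^d`. This is a coarse upper envelope on the stems a search
#' run produces, not a prediction of the actual count.
#'
#' @inheritParams expected_random_motifs
#' @return Numeric bound.
#' @export
expected_stem_estimate <- function(l, d, sigma, m) {
  p <- p_at_most(l, min(2 * d, l), sigma)
  as.numeric(m)^2 * p * 2^l * as.numeric(l)^d
}
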