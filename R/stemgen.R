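#' Pair context for stem generation
#'
#' Splits the positions of an l-mer pair into the matching region (where the
#' two agree) and the non-matching region (where they differ, of size
#' `d_x = ` their Hamming distance). Wildcard placement is driven entirely by
#' this partition.
#'
#' @param x,x_prime l-mers (strings) of equal length.
#' @return An object of class `pair_context` with fields `x`, `x_prime`,
#'   `matching`, `nonmatching` (1-based position vectors) and `d_x`.
#' @export
pair_context <- function(x, x_prime) {
  a <- .chars(x); b <- .chars(x_prime)
  if (length(a) != length(b)) stop("pair members must have equal length",
                                   call. = FALSE)
  diff <- which(a != b)
  structure(list(x = x, x_prime = x_prime,
                 matching = setdiff(seq_along(a), diff),
                 nonmatching = diff, d_x = length(diff),
                 l = length(a)),
            class = "pair_context")
}

#' Wildcard placement budget for an l-mer pair
#'
#' For a pair at Hamming distance `d_x`, enumerates the admissible counts of
#' wildcards: `i` in the non-matching region and `k` in the matching region.
#' When `d_x <= d`, `i` ranges over `0..d_x`; when `d_x > d`, at least
#' `d_x - d` mismatches must be wiped out, so `i` ranges over `(d_x - d)..d`.
#' In both cases only the maximal matching-region count
#' `k = d - max(i, d_x - i)` is used: any placement with fewer matching-region
#' wildcards is covered by the maximal one, so enumerating it would only
#' inflate the output.
#'
#' @param d_x Hamming distance of the pair, must satisfy `0 <= d_x <= 2d`.
#' @param d maximum mismatches of the motif model.
#' @return A data frame with integer columns `i` and `k`.
#' @examples
#' wildcard_budget(0, 1)   # one wildcard, anywhere
#' wildcard_budget(2, 1)   # one non-matching position must be wiped out
#' @export
wildcard_budget <- function(d_x, d) {
  d_x <- as.integer(d_x); d <- as.integer(d)
  if (d < 0L) stop("d must be non-negative", call. = FALSE)
  if (d_x < 0L || d_x > 2L * d) {
    stop("d_x = ", d_x, " must be in [0, 2d = ", 2L * d, "]; pairs farther ",
         "than 2d apart share no d-neighbour", call. = FALSE)
  }
  i <- if (d_x <= d) 0:d_x else (d_x - d):d
  data.frame(i = as.integer(i), k = as.integer(d - pmax(i, d_x - i)))
}

#' Generate stems from an l-mer pair
#'
#' Overwrites positions of `x` with the wildcard character: for every
#' admissible `(i, k)` of [wildcard_budget()], every choice of `i`
#' non-matching and `k` matching positions yields one stem. Wildcards count
#' as mismatches against `x` wherever they are placed, and against `x_prime`
#' only in the matching region, so every generated stem stays within `d`
#' mismatches of both pair members.
#'
#' @param ctx a [pair_context()], or an l-mer (then `x_prime` must be given).
#' @param d maximum mismatches.
#' @param x_prime optional second l-mer when `ctx` is a plain string.
#' @return Character vector of distinct stems, sorted lexicographically.
#' @examples
#' place_wildcards("AAAA", 1, x_prime = "AAAA")
#' place_wildcards(pair_context("gaaac", "gcaac"), 1)
#' @export
place_wildcards <- function(ctx, d, x_prime = NULL) {
  if (!inherits(ctx, "pair_context")) {
    if (is.null(x_prime)) stop("need a pair_context or both l-mers",
                               call. = FALSE)
    ctx <- pair_context(ctx, x_prime)
  }
  budget <- wildcard_budget(ctx$d_x, d)
  xc <- .chars(ctx$x)
  out <- character(0)
  for (row in seq_len(nrow(budget))) {
    i <- budget$i[row]; k <- budget$k[row]
    non_sets <- .combs(ctx$nonmatching, i)
    mat_sets <- .combs(ctx$matching, k)
    for (ns in non_sets) {
      for (ms in mat_sets) {
        t <- xc
        t[c(ns, ms)] <- WILDCARD
        out[length(out) + 1L] <- paste(t, collapse = "")
      }
    }
  }
  .lex_sort(unique(out))
}

#' Exact stem count for an l-mer pair
#'
#' Number of distinct stems [place_wildcards()] generates for a pair of
#' length-`l` l-mers at Hamming distance `d_x`: the sum over the wildcard
#' budget of `choose(d_x, i) * choose(l - d_x, k)` (positions chosen within
#' the non-matching and matching regions respectively).
#'
#' @param l l-mer length.
#' @inheritParams wildcard_budget
#' @return Integer-valued count (as double, the values can be large).
#' @seealso [stem_count_bound()] for the looser closed-form bound.
#' @export
count_stems_exact <- function(l, d_x, d) {
  l <- as.integer(l)
  if (d_x > l || d > l) stop("d_x and d cannot exceed l", call. = FALSE)
  b <- wildcard_budget(d_x, d)
  sum(choose(d_x, b$i) * choose(l - d_x, b$k))
}

#' Closed-form upper bound on the per-pair stem count
#'
#' The bound `sum_i choose(l, i) * l^(d - max(i, d_x - i))` over the same
#' budget range, itself crudely bounded by `2^l * l^d`. Always at least
#' [count_stems_exact()] since `choose(d_x, i) <= choose(l, i)` and
#' `choose(l - d_x, k) <= l^k`.
#'
#' @inheritParams count_stems_exact
#' @return Numeric bound.
#' @export
stem_count_bound <- function(l, d_x, d) {
  l <- as.integer(l)
  if (d_x > l || d > l) stop("d_x and d cannot exceed l", call. = FALSE)
  b <- wildcard_budget(d_x, d)
  sum(choose(l, b$i) * as.numeric(l)^b$k)
}

#' Expand a stem into the l-mers it represents
#'
#' Substitutes every alphabet character at every wildcard position; a stem
#' with `w` wildcards over a `sigma`-letter alphabet represents `sigma^w`
#' distinct l-mers.
#'
#' @param stem a stem (string over alphabet plus `*`).
#' @param alphabet alphabet specification, see [mss_alphabet()].
#' @return Character vector of expanded l-mers, sorted lexicographically.
#' @examples
#' expand_stem("g*aac", c("a", "c", "g", "t"))
#' @export
expand_stem <- function(stem, alphabet) {
  alphabet <- mss_alphabet(alphabet)
  ch <- .chars(stem)
  wild <- which(ch == WILDCARD)
  if (length(wild) == 0L) return(stem)
  grid <- expand.grid(rep(list(alphabet), length(wild)),
                      stringsAsFactors = FALSE)
  out <- vapply(seq_len(nrow(grid)), function(r) {
    ch[wild] <- unlist(grid[r, ], use.names = FALSE)
    paste(ch, collapse = "")
  }, character(1))
  .lex_sort(out)
}

#' Distance from a stem to an l-mer
#'
#' Counts mismatches at non-wildcard positions only; wildcards match any
#' character. Equals the minimum Hamming distance between `y` and any member
#' of the stem's expansion. A distance of 0 means the stem covers `y`.
#'
#' @param stem a stem (string).
#' @param y an l-mer (string) of the same length.
#' @return Integer distance.
#' @examples
#' stem_distance("g*aac", "gtaac")
#' @export
stem_distance <- function(stem, y) {
  a <- .chars(stem); b <- .chars(y)
  if (length(a) != length(b)) stop("stem and l-mer must have equal length",
                                   call. = FALSE)
  sum(a != b & a != WILDCARD)
}
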