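# Search drivers: the two stem-search algorithms, the pairwise-stemming
# baseline, the post-process validation, and the brute-force planted-motif
# oracle used to certify them.

.new_stem_result <- function(stems, prov, l, d, alphabet, algorithm,
                             counters, post_processed = FALSE) {
  keep <- !duplicated(stems)                  # first provenance wins
  stems_u <- stems[keep]
  prov_u <- prov[keep, , drop = FALSE]
  ord <- order(stems_u, method = "radix")
  structure(
    list(stems = stems_u[ord],
         provenance = `rownames<-`(prov_u[ord, , drop = FALSE], NULL),
         l = as.integer(l), d = as.integer(d), alphabet = alphabet,
         algorithm = algorithm, counters = counters,
         post_processed = post_processed),
    class = "stem_result"
  )
}

#' @export
print.stem_result <- function(x, ...) {
  cat("Stem search result (", x$algorithm, "): ", length(x$stems),
      " stem(s), l = ", x$l, ", d = ", x$d,
      if (x$post_processed) ", post-processed" else "", "\n", sep = "")
  cat("  candidates examined: ", x$counters[["candidates_examined"]],
      ", skipped: ", x$counters[["candidates_skipped"]],
      ", pairs processed: ", x$counters[["pairs_processed"]], "\n", sep = "")
  if (length(x$stems) > 0L) {
    cat("  ", paste(utils::head(x$stems, 8L), collapse = " "),
        if (length(x$stems) > 8L) " ..." else "", "\n", sep = "")
  }
  invisible(x)
}

# Stem generation shared by both drivers: pair candidate k of s_1 with every
# member of the minimal neighbour list, so the two drivers can only differ in
# how they computed that list.
.stems_from_selection <- function(seqs, l, d, k, min_seq, offsets, acc) {
  x <- substr(seqs$sequences[1L], k, k + l - 1L)
  for (off in offsets) {
    xp <- substr(seqs$sequences[min_seq], off, off + l - 1L)
    st <- place_wildcards(pair_context(x, xp), d)
    m <- length(st)
    acc$stems[[length(acc$stems) + 1L]] <- st
    acc$x[[length(acc$x) + 1L]] <- rep.int(x, m)
    acc$xp[[length(acc$xp) + 1L]] <- rep.int(xp, m)
    acc$pairs <- acc$pairs + 1L
  }
  acc
}

.finish_driver <- function(seqs, l, d, acc, skipped, R, algorithm, validate) {
  stems <- unlist(acc$stems, use.names = FALSE)
  if (is.null(stems)) stems <- character(0)
  prov <- data.frame(x = unlist(acc$x, use.names = FALSE) %||% character(0),
                     x_prime = unlist(acc$xp, use.names = FALSE) %||% character(0),
                     stringsAsFactors = FALSE)
  res <- .new_stem_result(
    stems, prov, l, d, seqs$alphabet, algorithm,
    counters = c(candidates_examined = R, candidates_skipped = skipped,
                 pairs_processed = acc$pairs)
  )
  if (validate) res <- post_process(res, seqs) else res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Motif stem search, per-candidate driver
#'
#' For each l-mer of the first sequence, computes its 2d-neighbour list in
#' every other sequence on the fly (O(m^2 n l) character comparisons in
#' total), skips the candidate if any list is empty, and otherwise generates
#' stems by placing wildcards between the candidate and each member of the
#' smallest list. The union of stems over all candidates covers every
#' (l,d)-motif of the input.
#'
#' @param seqs a [sequence_set()].
#' @param l motif length.
#' @param d maximum mismatches.
#' @param validate run the [post_process()] phase on the result
#'   (default `FALSE`).
#' @return A `stem_result`: sorted unique stems, per-stem provenance (the
#'   generating pair), and search counters.
#' @seealso [mss2()] for the faster driver with identical output,
#'   [stemming_baseline()] for the pairwise baseline.
#' @export
mss1 <- function(seqs, l, d, validate = FALSE) {
  stopifnot(inherits(seqs, "sequence_set"))
  .check_params(seqs, l, d)
  l <- as.integer(l); d <- as.integer(d)
  enc <- .encode_set(seqs)
  W <- lapply(enc, .window_matrix, l = l)
  R <- seqs$m - l + 1L
  acc <- list(stems = list(), x = list(), xp = list(), pairs = 0L)
  skipped <- 0L
  for (k in seq_len(R)) {
    x_code <- enc[[1L]][k:(k + l - 1L)]
    lists <- vector("list", seqs$n - 1L)
    skip <- FALSE
    for (i in 2:seqs$n) {
      off <- which(.dist_to_windows(x_code, W[[i]]) <= 2L * d)
      if (length(off) == 0L) { skip <- TRUE; break }
      lists[[i - 1L]] <- off
    }
    if (skip) { skipped <- skipped + 1L; next }
    sizes <- lengths(lists)
    best <- which.min(sizes)                 # ties -> lowest sequence index
    acc <- .stems_from_selection(seqs, l, d, k, best + 1L, lists[[best]], acc)
  }
  .finish_driver(seqs, l, d, acc, skipped, R, "mss1", validate)
}

#' Motif stem search, neighbour-matrix driver
#'
#' Same output as [mss1()], computed faster: the full candidate-by-sequence
#' neighbour matrix is built first via the O(1) per-cell diagonal recurrence
#' ([distance_matrix_diagonal()]), dropping the per-candidate cost of the
#' neighbour scan from O(m n l) to O(m n) at the price of O(m^2) memory.
#'
#' @inheritParams mss1
#' @return A `stem_result` identical (stems, counters) to the [mss1()] result
#'   on the same input.
#' @export
mss2 <- function(seqs, l, d, validate = FALSE) {
  stopifnot(inherits(seqs, "sequence_set"))
  .check_params(seqs, l, d)
  l <- as.integer(l); d <- as.integer(d)
  nm <- build_neighbor_matrix(seqs, l, d)
  R <- nm$n_candidates
  acc <- list(stems = list(), x = list(), xp = list(), pairs = 0L)
  skipped <- 0L
  for (k in seq_len(R)) {
    sel <- select_candidate(k, nm)
    if (sel$status == "skipped") { skipped <- skipped + 1L; next }
    acc <- .stems_from_selection(seqs, l, d, k, sel$min_seq_index,
                                 sel$i_min, acc)
  }
  .finish_driver(seqs, l, d, acc, skipped, R, "mss2", validate)
}

#' Post-process validation of a stem set
#'
#' Retains a stem only if every input sequence contains a window within
#' distance `d` of it, wildcards matching freely ([stem_distance()]). A stem
#' covering a true (l,d)-motif always survives: the motif has an occurrence
#' within `d` in every sequence, and the stem can only be closer to that
#' occurrence than the motif is.
#'
#' @param result a `stem_result`.
#' @param seqs the [sequence_set()] the result was computed from.
#' @return The filtered `stem_result` with `post_processed = TRUE`.
#' @export
post_process <- function(result, seqs) {
  stopifnot(inherits(result, "stem_result"), inherits(seqs, "sequence_set"))
  if (result$l > seqs$m) stop("stem length exceeds sequence length",
                              call. = FALSE)
  stems <- result$stems
  out <- result
  out$post_processed <- TRUE
  if (length(stems) == 0L) return(out)
  P <- t(vapply(stems, .encode, integer(result$l), alphabet = seqs$alphabet))
  nonwild <- rowSums(P != 0L)
  keep <- rep(TRUE, length(stems))
  enc <- .encode_set(seqs)
  for (i in seq_len(seqs$n)) {
    Wl <- .window_matrix(enc[[i]], result$l)
    M <- matrix(0, nrow(P), nrow(Wl))
    for (a in seq_along(seqs$alphabet)) {
      Pa <- P == a
      if (!any(Pa)) next
      M <- M + Pa %*% t(Wl == a)
    }
    keep <- keep & (nonwild - .row_max(M) <= result$d)
  }
  out$stems <- stems[keep]
  out$provenance <- result$provenance[keep, , drop = FALSE]
  out$counters <- c(result$counters, stems_removed = sum(!keep))
  out
}

#' Pairwise-stemming baseline
#'
#' The algorithm the two stem-search drivers improve on. First builds the
#' candidate set `I`: every l-mer (of any input sequence) whose distance to
#' every sequence is at most `2d`. Then, for every ordered pair of distinct
#' `I` members within Hamming distance `2d` of each other (including a
#' member paired with itself), generates stems by wildcard placement. Because
#' candidates are paired all-against-all rather than against one minimal
#' neighbour list, the output is a superset of the driver output -- typically
#' a very large one.
#'
#' @inheritParams mss1
#' @return A `stem_result`.
#' @export
stemming_baseline <- function(seqs, l, d, validate = FALSE) {
  stopifnot(inherits(seqs, "sequence_set"))
  .check_params(seqs, l, d)
  l <- as.integer(l); d <- as.integer(d)
  enc <- .encode_set(seqs)
  R <- seqs$m - l + 1L
  # I: l-mer occurrences passing the 2d filter against every sequence
  members <- character(0)
  for (i in seq_len(seqs$n)) {
    pass <- rep(TRUE, R)
    for (j in seq_len(seqs$n)) {
      if (i == j) next    # an l-mer is at distance 0 from its own sequence
      D <- distance_matrix_diagonal(seqs$sequences[i], seqs$sequences[j], l)
      pass <- pass & (D[cbind(seq_len(R), max.col(-D, ties.method = "first"))]
                      <= 2L * d)
    }
    if (any(pass)) {
      members <- c(members, vapply(which(pass), function(k) {
        substr(seqs$sequences[i], k, k + l - 1L)
      }, character(1)))
    }
  }
  members <- unique(members)
  acc <- list(stems = list(), x = list(), xp = list(), pairs = 0L)
  if (length(members) > 0L) {
    Im <- t(vapply(members, .encode, integer(l), alphabet = seqs$alphabet))
    Mm <- matrix(0, nrow(Im), nrow(Im))
    for (a in seq_along(seqs$alphabet)) {
      Ia <- Im == a
      if (!any(Ia)) next
      Mm <- Mm + Ia %*% t(Ia)
    }
    HD <- l - Mm                              # pairwise Hamming distances
    for (xi in seq_along(members)) {
      mates <- which(HD[xi, ] <= 2L * d)
      for (yi in mates) {
        st <- place_wildcards(pair_context(members[xi], members[yi]), d)
        nst <- length(st)
        acc$stems[[length(acc$stems) + 1L]] <- st
        acc$x[[length(acc$x) + 1L]] <- rep.int(members[xi], nst)
        acc$xp[[length(acc$xp) + 1L]] <- rep.int(members[yi], nst)
        acc$pairs <- acc$pairs + 1L
      }
    }
  }
  stems <- unlist(acc$stems, use.names = FALSE) %||% character(0)
  prov <- data.frame(x = unlist(acc$x, use.names = FALSE) %||% character(0),
                     x_prime = unlist(acc$xp, use.names = FALSE) %||% character(0),
                     stringsAsFactors = FALSE)
  res <- .new_stem_result(
    stems, prov, l, d, seqs$alphabet, "stemming",
    counters = c(candidates_examined = length(members),
                 candidates_skipped = NA_integer_,
                 pairs_processed = acc$pairs)
  )
  if (validate) post_process(res, seqs) else res
}

#' Brute-force planted-motif oracle
#'
#' Enumerates the full d-neighbourhood of every l-mer of the first sequence
#' and keeps exactly those candidates whose distance to every sequence is at
#' most `d` -- the exact (l,d)-motif set. Exponential in `d`; intended for
#' validating the stem-search output on small instances, and guarded by an
#' explicit work limit.
#'
#' @inheritParams mss1
#' @param max_work refuse instances whose candidate enumeration would exceed
#'   this many l-mers (default `5e6`). The error thrown has condition class
#'   `mss_infeasible_error`.
#' @return Sorted character vector of all (l,d)-motifs.
#' @export
pms_oracle <- function(seqs, l, d, max_work = 5e6) {
  stopifnot(inherits(seqs, "sequence_set"))
  .check_params(seqs, l, d)
  l <- as.integer(l); d <- as.integer(d)
  sigma <- length(seqs$alphabet)
  R <- seqs$m - l + 1L
  per_lmer <- sum(choose(l, 0:d) * (sigma - 1)^(0:d))
  if (R * per_lmer > max_work) {
    stop(structure(
      class = c("mss_infeasible_error", "error", "condition"),
      list(message = sprintf(
        "oracle enumeration would need %.3g candidates (limit %.3g)",
        R * per_lmer, max_work), call = sys.call(-1L))))
  }
  enc <- .encode_set(seqs)
  seeds <- unique(lapply(seq_len(R), function(k) enc[[1L]][k:(k + l - 1L)]))
  cand <- do.call(rbind, lapply(seeds, .d_neighborhood, d = d, sigma = sigma))
  cand <- cand[!duplicated(cand), , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(seqs$n)) {
    Wl <- .window_matrix(enc[[i]], l)
    M <- matrix(0, nrow(cand), nrow(Wl))
    for (a in seq_len(sigma)) {
      Ca <- cand == a
      if (!any(Ca)) next
      M <- M + Ca %*% t(Wl == a)
    }
    keep <- keep & (l - .row_max(M) <= d)
  }
  hits <- cand[keep, , drop = FALSE]
  .lex_sort(vapply(seq_len(nrow(hits)), function(r) {
    .decode(hits[r, ], seqs$alphabet)
  }, character(1)))
}

# All l-mers within Hamming distance d of the encoded l-mer x (codes
# 1..sigma), returned as a matrix with one candidate per row.
.d_neighborhood <- function(x, d, sigma) {
  l <- length(x)
  rows <- list(matrix(x, nrow = 1L))
  for (j in seq_len(d)) {
    for (pos in .combs(seq_len(l), j)) {
      # each mutated position cycles through the sigma - 1 other codes
      shifts <- expand.grid(rep(list(seq_len(sigma - 1L)), j))
      block <- matrix(rep(x, each = nrow(shifts)), nrow = nrow(shifts))
      for (c_ in seq_len(j)) {
        p <- pos[c_]
        block[, p] <- ((x[p] - 1L + shifts[[c_]]) %% sigma) + 1L
      }
      rows[[length(rows) + 1L]] <- block
    }
  }
  do.call(rbind, rows)
}

#' One-call stem search
#'
#' Convenience wrapper dispatching to [mss1()], [mss2()] or
#' [stemming_baseline()], optionally followed by [post_process()].
#'
#' @inheritParams mss1
#' @param algorithm `"mss2"` (default), `"mss1"`, or `"stemming"`.
#' @return A `stem_result`.
#' @examples
#' pi <- generate_planted_instance(n = 4, m = 40, l = 5, d = 1,
#'                                 alphabet = "dna", seed = 3)
#' motif_stems(pi$sequence_set, l = 5, d = 1, validate = TRUE)
#' @export
motif_stems <- function(seqs, l, d,
                        algorithm = c("mss2", "mss1", "stemming"),
                        validate = TRUE) {
  algorithm <- match.arg(algorithm)
  fn <- switch(algorithm, mss1 = mss1, mss2 = mss2,
               stemming = stemming_baseline)
  fn(seqs, l, d, validate = validate)
}
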