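# Independent reference implementations used as oracles. Deliberately naive:
# each one recomputes its quantity by direct enumeration, never through the
# code path it is meant to certify.

# Per-position comparison loop.
ham_loop <- function(x, y) {
  a <- strsplit(x, "")[[1]]
  b <- strsplit(y, "")[[1]]
  n <- 0L
  for (i in seq_along(a)) if (a[i] != b[i]) n <- n + 1L
  n
}

# Explicit window scan.
min_dist_scan <- function(x, s) {
  l <- nchar(x)
  min(vapply(seq_len(nchar(s) - l + 1L), function(j) {
    ham_loop(x, substr(s, j, j + l - 1L))
  }, integer(1)))
}

# Element-wise recomputation of the pairwise window distance matrix.
dist_matrix_scan <- function(s1, si, l) {
  R <- nchar(s1) - l + 1L
  outer(seq_len(R), seq_len(R), Vectorize(function(a, b) {
    ham_loop(substr(s1, a, a + l - 1L), substr(si, b, b + l - 1L))
  }))
}

rand_seq <- function(m, alphabet) {
  paste(sample(alphabet, m, replace = TRUE), collapse = "")
}

# All strings of length l over `alphabet`.
all_strings <- function(l, alphabet) {
  apply(expand.grid(rep(list(alphabet), l), stringsAsFactors = FALSE),
        1, paste, collapse = "")
}

# Does any stem in `stems` cover the l-mer `y` (distance 0)?
covered <- function(stems, y) {
  for (s in stems) if (stem_distance(s, y) == 0L) return(TRUE)
  FALSE
}

# Random planted instance with parameters drawn inside the benchmark caps
# (n <= 10, m <= 100, l <= 11, d <= 3, sigma in {4, 20}); DNA instances stay
# small enough for the brute-force oracle and the baseline's pair enumeration.
rand_instance <- function(seed, sigma = c(4L, 20L)) {
  set.seed(seed)
  sigma <- sigma[sample.int(length(sigma), 1L)]
  if (sigma == 4L) {
    alphabet <- "dna"
    n <- sample(3:6, 1); m <- sample(30:60, 1)
    l <- sample(c(7L, 9L), 1); d <- sample(1:2, 1)
  } else {
    alphabet <- "protein"
    n <- sample(4:10, 1); m <- sample(40:100, 1)
    l <- sample(7:11, 1); d <- sample(1:3, 1)
  }
  generate_planted_instance(n = n, m = m, l = l, d = d,
                            alphabet = alphabet, seed = seed)
}

# For each l-mer, is it covered (stem_distance 0) by at least one stem?
# Groups stems by wildcard mask and hash-joins masked l-mers against each
# group, so it stays usable against the baseline's very large stem sets.
stems_cover_each <- function(stems, lmers) {
  if (length(lmers) == 0L) return(logical(0))
  if (length(stems) == 0L) return(rep(FALSE, length(lmers)))
  Sm <- strsplit(stems, "", fixed = TRUE)
  masks <- vapply(Sm, function(ch) paste(which(ch == "*"), collapse = ","),
                  character(1))
  Ym <- do.call(rbind, strsplit(lmers, "", fixed = TRUE))
  covered <- rep(FALSE, length(lmers))
  for (mk in unique(masks)) {
    sel <- stems[masks == mk]
    pos <- if (nzchar(mk)) as.integer(strsplit(mk, ",", fixed = TRUE)[[1]])
           else integer(0)
    Ymk <- Ym
    if (length(pos) > 0) Ymk[, pos] <- "*"
    ystr <- do.call(paste0, lapply(seq_len(ncol(Ymk)), function(j) Ymk[, j]))
    covered <- covered | (ystr %in% sel)
  }
  covered
}
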