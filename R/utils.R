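# Internal helpers shared across modules.

# Split a single string into its character vector.
.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

# Encode a string as integers over `alphabet` (wildcard -> 0L).
.encode <- function(s, alphabet) {
  ch <- .chars(s)
  code <- match(ch, alphabet)
  code[ch == WILDCARD] <- 0L
  if (anyNA(code)) {
    bad <- unique(ch[is.na(code)])
    stop("character(s) outside alphabet: ", paste(bad, collapse = " "),
         call. = FALSE)
  }
  code
}

.decode <- function(code, alphabet) {
  out <- character(length(code))
  wild <- code == 0L
  out[wild] <- WILDCARD
  out[!wild] <- alphabet[code[!wild]]
  paste(out, collapse = "")
}

# All l-windows of an encoded sequence as an (m - l + 1) x l integer matrix;
# row a holds the window starting at position a.
.window_matrix <- function(code, l) {
  m <- length(code)
  R <- m - l + 1L
  matrix(code[outer(seq_len(R), 0:(l - 1L), `+`)], nrow = R, ncol = l)
}

# Hamming distance of the l-mer `x` (integer vector) to every row of a
# window matrix.
.dist_to_windows <- function(x, W) {
  as.integer(rowSums(W != matrix(x, nrow(W), length(x), byrow = TRUE)))
}

# k-subsets of a position vector; no subsets when k exceeds the region size,
# and combn()'s length-1 numeric x (treated as 1:x) is guarded.
.combs <- function(positions, k) {
  if (k == 0L) return(list(integer(0)))
  if (length(positions) < k) return(list())
  if (length(positions) == 1L) return(list(positions))
  utils::combn(positions, k, simplify = FALSE)
}

# Row-wise maximum of a numeric matrix without apply() overhead.
.row_max <- function(M) M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]

# Evaluate `code` under a private RNG stream seeded with `seed`; the global
# .Random.seed is restored (or removed) afterwards.
.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic, locale-independent lexicographic sort.
.lex_sort <- function(x) sort(x, method = "radix")
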