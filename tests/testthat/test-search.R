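test_that("identical sequences yield one wildcard per position", {
  ss <- sequence_set(c("AAAAA", "AAAAA"), "dna")
  res <- mss1(ss, 3, 1)
  expect_equal(res$stems, c("*AA", "A*A", "AA*"))
  expect_equal(unname(res$counters[["candidates_skipped"]]), 0L)
})

test_that("d = 0 collapses the search to exact common l-mers", {
  set.seed(51)
  pi <- generate_planted_instance(n = 4, m = 40, l = 6, d = 0,
                                  alphabet = "dna", seed = 51)
  res <- mss1(pi$sequence_set, 6, 0)
  # expected: l-mers of s_1 present verbatim in every sequence
  s1 <- pi$sequence_set$sequences[1]
  lmers <- unique(vapply(1:(40 - 6 + 1), function(k) substr(s1, k, k + 5),
                         character(1)))
  common <- lmers[vapply(lmers, function(x) {
    all(vapply(pi$sequence_set$sequences, function(s) grepl(x, s, fixed = TRUE),
               logical(1)))
  }, logical(1))]
  expect_setequal(res$stems, common)
  expect_false(any(grepl("*", res$stems, fixed = TRUE)))
  # and the baseline agrees exactly at d = 0 on the s_1-candidate stems
  expect_true(all(res$stems %in% stemming_baseline(pi$sequence_set, 6, 0)$stems))
})

test_that("mss1 and mss2 produce identical results on random planted instances", {
  for (seed in 1:8) {
    pi <- rand_instance(500 + seed)
    r1 <- mss1(pi$sequence_set, pi$l, pi$d)
    r2 <- mss2(pi$sequence_set, pi$l, pi$d)
    expect_identical(r1$stems, r2$stems)
    expect_identical(r1$counters[["candidates_skipped"]],
                     r2$counters[["candidates_skipped"]])
    expect_identical(r1$counters[["pairs_processed"]],
                     r2$counters[["pairs_processed"]])
  }
})

test_that("post-process keeps exactly the stems with a <= d window everywhere", {
  set.seed(52)
  pi <- generate_planted_instance(n = 4, m = 30, l = 5, d = 1,
                                  alphabet = "dna", seed = 52)
  res <- mss2(pi$sequence_set, 5, 1)
  pp <- post_process(res, pi$sequence_set)
  # oracle: explicit window scan with wildcard-as-match semantics
  for (st in res$stems) {
    ok <- all(vapply(pi$sequence_set$sequences, function(s) {
      min(vapply(1:(nchar(s) - 4), function(j) {
        stem_distance(st, substr(s, j, j + 4))
      }, integer(1))) <= 1
    }, logical(1)))
    expect_equal(st %in% pp$stems, ok)
  }
  expect_true(pp$post_processed)
})

test_that("post-process is sound: stems covering a true motif survive", {
  for (seed in 1:5) {
    pi <- rand_instance(600 + seed, sigma = 4L)
    if (pi$d > 2 || pi$l > 9) next
    motifs <- pms_oracle(pi$sequence_set, pi$l, pi$d)
    res <- mss2(pi$sequence_set, pi$l, pi$d)
    pp <- post_process(res, pi$sequence_set)
    dropped <- setdiff(res$stems, pp$stems)
    for (st in dropped) {
      expect_false(any(vapply(motifs, function(y) stem_distance(st, y) == 0,
                              logical(1))))
    }
  }
})

test_that("a pathological all-wildcard stem survives post-processing", {
  ss <- sequence_set(c("ACGTA", "TTTTT"), "dna")
  res <- structure(list(stems = "***", provenance = data.frame(x = "ACG",
                        x_prime = "ACG"), l = 3L, d = 3L,
                        alphabet = DNA_ALPHABET, algorithm = "mss1",
                        counters = c(candidates_examined = 1L,
                                     candidates_skipped = 0L,
                                     pairs_processed = 1L),
                        post_processed = FALSE), class = "stem_result")
  expect_equal(post_process(res, ss)$stems, "***")
})

test_that("oracle motifs are covered by the stems of every driver", {
  for (seed in 1:3) {
    pi <- rand_instance(700 + seed, sigma = 4L)
    if (pi$l > 9 || pi$d > 2) next
    motifs <- pms_oracle(pi$sequence_set, pi$l, pi$d)
    expect_true(pi$motif %in% motifs)
    for (res in list(mss1(pi$sequence_set, pi$l, pi$d),
                     stemming_baseline(pi$sequence_set, pi$l, pi$d))) {
      pp <- post_process(res, pi$sequence_set)
      expect_true(all(stems_cover_each(res$stems, motifs)))
      expect_true(all(stems_cover_each(pp$stems, motifs)))
    }
  }
})

test_that("driver stems expand to a subset of the baseline stems", {
  for (seed in c(801, 802, 803)) {
    pi <- rand_instance(seed, sigma = 4L)
    ab <- pi$sequence_set$alphabet
    e_mss <- unique(unlist(lapply(mss1(pi$sequence_set, pi$l, pi$d)$stems,
                                  expand_stem, alphabet = ab)))
    base_stems <- stemming_baseline(pi$sequence_set, pi$l, pi$d)$stems
    expect_true(all(stems_cover_each(base_stems, e_mss)))
  }
})

test_that("skipped candidates have no motif among their d-neighbors", {
  for (seed in 1:4) {
    pi <- rand_instance(900 + seed, sigma = 4L)
    if (pi$l > 9 || pi$d > 2) next
    motifs <- pms_oracle(pi$sequence_set, pi$l, pi$d)
    if (length(motifs) == 0) next
    nm <- build_neighbor_matrix(pi$sequence_set, pi$l, pi$d)
    s1 <- pi$sequence_set$sequences[1]
    for (k in seq_len(nm$n_candidates)) {
      if (select_candidate(k, nm)$status == "skipped") {
        x <- substr(s1, k, k + pi$l - 1L)
        for (y in motifs) {
          expect_gt(ham_loop(x, y), pi$d)
        }
      }
    }
  }
})

test_that("the oracle is monotone in d and guards infeasible scales", {
  pi <- generate_planted_instance(n = 4, m = 30, l = 5, d = 1,
                                  alphabet = "dna", seed = 53)
  m0 <- pms_oracle(pi$sequence_set, 5, 0)
  m1 <- pms_oracle(pi$sequence_set, 5, 1)
  m2 <- pms_oracle(pi$sequence_set, 5, 2)
  expect_true(all(m0 %in% m1))
  expect_true(all(m1 %in% m2))
  # d = 0: motifs are exactly the l-mers verbatim-present in all sequences
  for (y in m0) {
    expect_true(all(vapply(pi$sequence_set$sequences, grepl, logical(1),
                           pattern = y, fixed = TRUE)))
  }
  err <- tryCatch(pms_oracle(pi$sequence_set, 5, 2, max_work = 10),
                  error = identity)
  expect_s3_class(err, "mss_infeasible_error")
})

test_that("motif_stems dispatches and validates", {
  pi <- generate_planted_instance(n = 4, m = 40, l = 5, d = 1,
                                  alphabet = "dna", seed = 3)
  r <- motif_stems(pi$sequence_set, 5, 1, algorithm = "mss2", validate = TRUE)
  expect_true(r$post_processed)
  expect_identical(r$stems,
                   post_process(mss1(pi$sequence_set, 5, 1),
                                pi$sequence_set)$stems)
})
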