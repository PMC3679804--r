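test_that("FASTA round trip preserves sequences, order and dimensions", {
  f <- withr::local_tempfile(fileext = ".fasta")
  ss <- sequence_set(c(a = "ACGTACG", b = "ACGTACG"), "dna")
  write_fasta(ss, f)
  back <- read_fasta(f, "dna")
  expect_equal(back$sequences, ss$sequences)
  expect_equal(back$n, 2L)
  expect_equal(back$m, 7L)

  set.seed(11)
  seqs <- vapply(1:20, function(i) rand_seq(600, PROTEIN_ALPHABET), character(1))
  write_fasta(sequence_set(seqs, "protein"), f)
  big <- read_fasta(f, "protein")
  expect_equal(big$sequences, seqs)
  expect_equal(c(big$n, big$m, length(big$alphabet)), c(20L, 600L, 20L))
})

test_that("malformed inputs are rejected with the offending record named", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r1", "ACGTACGTAC", ">r2", "ACGTACGTA"), f)
  expect_error(read_fasta(f, "dna"), "record 2")

  writeLines(c(">r1", "ACGT", ">r2", "ACXT"), f)
  expect_error(read_fasta(f, "dna"), "record 2.*X")

  writeLines("no fasta here", f)
  expect_error(read_fasta(f))

  expect_error(sequence_set("ACGT", "dna"), "at least 2")
})

test_that("stems files are lexicographically sorted, one stem per line", {
  f <- withr::local_tempfile(fileext = ".txt")
  write_stems(c("ab*", "a*c"), f)
  expect_equal(readLines(f), c("a*c", "ab*"))

  write_stems("g*aac", f)
  expect_equal(readLines(f), "g*aac")

  write_stems(character(0), f)
  expect_equal(readLines(f), character(0))

  expect_error(write_stems(c("ab*", "a*cd"), f), "same length")
})

test_that("planted instances respect the mutation and placement contract", {
  # d = 0 forces exact copies
  pi0 <- generate_planted_instance(n = 2, m = 10, l = 4, d = 0,
                                   alphabet = "dna", seed = 7)
  expect_true(all(pi0$instances == pi0$motif))

  pi <- generate_planted_instance(n = 20, m = 600, l = 9, d = 2,
                                  alphabet = "protein", seed = 1)
  expect_equal(nchar(pi$motif), 9L)
  for (i in 1:20) {
    expect_lte(ham_loop(pi$instances[i], pi$motif), 2L)
    expect_equal(substr(pi$sequence_set$sequences[i], pi$positions[i],
                        pi$positions[i] + 8L), pi$instances[i])
  }
  expect_true(all(pi$positions >= 1 & pi$positions <= 600 - 9 + 1))
})

test_that("generation is deterministic under a fixed seed and leaves the RNG alone", {
  a <- generate_planted_instance(n = 4, m = 30, l = 5, d = 1,
                                 alphabet = "dna", seed = 42)
  b <- generate_planted_instance(n = 4, m = 30, l = 5, d = 1,
                                 alphabet = "dna", seed = 42)
  expect_identical(a, b)

  set.seed(123)
  before <- .Random.seed
  generate_planted_instance(n = 3, m = 20, l = 4, d = 1,
                            alphabet = "dna", seed = 9)
  expect_identical(.Random.seed, before)
})

test_that("invalid generator parameters are rejected", {
  expect_error(generate_planted_instance(n = 3, m = 5, l = 9, d = 1,
                                         alphabet = "dna", seed = 1), "exceeds")
  expect_error(generate_planted_instance(n = 3, m = 20, l = 4, d = 5,
                                         alphabet = "dna", seed = 1), "exceeds")
})

test_that("the planted motif is always an (l,d)-motif of its instance", {
  for (seed in 1:5) {
    pi <- generate_planted_instance(n = 4, m = 40, l = 6, d = 1,
                                    alphabet = "dna", seed = seed)
    motifs <- pms_oracle(pi$sequence_set, pi$l, pi$d)
    expect_true(pi$motif %in% motifs)
  }
})

test_that("sidecar metadata records the ground truth", {
  f <- withr::local_tempfile(fileext = ".fasta")
  pi <- generate_planted_instance(n = 3, m = 25, l = 5, d = 1,
                                  alphabet = "dna", seed = 5)
  write_planted_instance(pi, f)
  meta <- readLines(paste0(f, ".meta"))
  expect_true(paste0("motif: ", pi$motif) %in% meta)
  expect_true(paste0("positions: ", paste(pi$positions, collapse = ",")) %in% meta)
  back <- read_fasta(f, "dna")
  expect_equal(back$sequences, pi$sequence_set$sequences)
})
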