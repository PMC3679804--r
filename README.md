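# motifstems

Exact motif *stem* search for planted (l,d)-motifs, built for large
alphabets such as proteins.

## The problem

An **(l,d)-motif** of `n` sequences (each of length `m`, over an alphabet
of size `σ`) is a length-`l` string whose Hamming distance to every
sequence — the minimum over all length-`l` windows — is at most `d`.
Exact planted-motif search algorithms enumerate `d`-mismatch
neighbourhoods and pay a `σ^d` factor, which is fine for DNA (`σ = 4`)
and hopeless for proteins (`σ = 20`).

A **motif stem** is an l-length pattern with wildcard positions (`*`); it
represents the `σ^w` l-mers obtained by substituting its `w` wildcards.
Stem search returns a set of stems whose expansions are guaranteed to
contain **every** (l,d)-motif, at a cost that does not grow with `σ`:

- candidates are the l-mers `x` of the first sequence; `x` is skipped if
  some sequence has no window within `2d` of it (two strings within `d`
  of a common motif are within `2d` of each other);
- a surviving `x` is paired only with its `2d`-neighbours in the sequence
  where it has fewest of them (`I_min`);
- for a pair `(x, x')` at distance `d_x`, stems are made by overwriting
  `i` non-matching positions (`0 ≤ i ≤ d_x` if `d_x ≤ d`, else
  `d_x − d ≤ i ≤ d`) and `k = d − max(i, d_x − i)` matching positions of
  `x` with wildcards; these stems cover every common d-neighbour of the
  pair.

Two drivers compute the identical stem set: `mss1()` scans neighbours per
candidate (O(m²nl)); `mss2()` first builds the full neighbour matrix with
an O(1)-per-cell diagonal recurrence on the window-distance matrix
(O(m²n) time, O(m²) space). `stemming_baseline()` is the pairwise
predecessor algorithm (all filtered l-mers against all), whose output the
drivers provably shrink; `post_process()` discards stems lacking a
`≤ d` window in some sequence; `pms_oracle()` is a work-guarded
brute-force reference that returns the exact motif set on small
instances. Closed-form analysis functions (`p_at_most()`,
`expected_random_motifs()`, `challenging_d()`, `expected_stem_estimate()`)
give the neighbour probabilities, the expected number of spurious motifs
`σ^l (1−(1−p)^{m−l+1})^n`, and the *challenging* `d` for a given `l`.

## Worked example

```r
library(motifstems)

pi <- generate_planted_instance(n = 5, m = 60, l = 7, d = 1,
                                alphabet = "dna", seed = 11)
pi$motif
#> [1] "CAAGTGC"

res <- motif_stems(pi$sequence_set, l = 7, d = 1, algorithm = "mss2",
                   validate = TRUE)
res
#> Stem search result (mss2): 18 stem(s), l = 7, d = 1, post-processed
#>   candidates examined: 54, skipped: 45, pairs processed: 9

head(res$stems)
#> [1] "*AAGTGC" "*CAAGTG" "*TAATCT" "A*AATCT" "AAGTGC*" "AAGTGCT"

min(vapply(res$stems, stem_distance, integer(1), y = pi$motif))
#> [1] 0
```

Of the 54 candidate 7-mers of sequence 1, the `2d` filter skipped 45; the
9 survivors were paired with their minimal neighbour lists, and the 18
stems that survive post-processing cover the planted motif exactly
(distance 0). On the analysis side:

```r
p_at_most(9, 4, 20)              # chance two random 9-mers are within 2d = 4
#> [1] 3.322221e-05
challenging_d(9, 20, 20, 600)    # smallest d with spurious (9,d)-motifs expected
#> [1] 5
expected_random_motifs(9, 5, 20, 20, 600)
#> [1] 52.08399
```

A command-line front end (subcommands `search`, `simulate`, `stats`,
`oracle`) is installed at
`system.file("scripts", "mss.R", package = "motifstems")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","mss.R",package="motifstems"))')" \
    search --input seqs.fasta --l 9 --d 2 --output stems.txt
```

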