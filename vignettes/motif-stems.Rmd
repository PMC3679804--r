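---
title: "Motif stems: searching planted (l,d)-motifs on large alphabets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif stems: searching planted (l,d)-motifs on large alphabets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifstems)
```

## The problem

Given `n` sequences of common length `m` over an alphabet of size `sigma`,
an *(l,d)-motif* is a length-`l` string whose Hamming distance to every
sequence (minimum over all length-`l` windows) is at most `d`. Exact
planted-motif search enumerates candidate l-mers together with their
`d`-mismatch neighbourhoods, and its cost therefore grows like
`sigma^d` — prohibitive for proteins (`sigma = 20`) at useful `d`.

Motif *stem* search sidesteps the alphabet blow-up. A stem is an l-length
pattern over the alphabet plus a wildcard `*`; it represents the
`sigma^w` l-mers obtained by substituting each of its `w` wildcards.
Instead of the motifs themselves, the search reports a set of stems whose
expansions form a superset of all (l,d)-motifs. The number of stems does not
depend on `sigma`, only the sizes of their expansions do.

## The search procedure

Candidates are the l-mers of the first sequence. Three facts drive the
search:

1. **2d filter.** If two l-mers are both within `d` of some motif, they are
   within `2d` of each other (triangle inequality). So if a candidate `x`
   has *no* window within `2d` in some sequence, no d-neighbour of `x` can
   be a motif and `x` is skipped.
2. **Minimal pairing set.** If `x` survives, every motif within `d` of `x`
   has an occurrence among `x`'s 2d-neighbours in *each* sequence. It
   suffices to pair `x` with its neighbours in the single sequence where it
   has fewest of them (`I_min`); ties go to the lowest sequence index.
3. **Wildcard placement.** For a pair `(x, x')` at Hamming distance `d_x`,
   positions split into a matching and a non-matching region. Placing `i`
   wildcards in the non-matching region (range `0..d_x` when `d_x <= d`,
   else `(d_x - d)..d`) and `k = d - max(i, d_x - i)` in the matching
   region yields stems within `d` mismatches of both pair members;
   wildcards count as mismatches against `x` everywhere and against `x'`
   only in the matching region. Only the maximal `k` is enumerated — any
   placement with fewer matching-region wildcards is covered by a maximal
   one, so emitting it would only inflate the output. Every common
   d-neighbour of the pair is covered by one of these stems, which is what
   makes the output a superset of the motifs.

`mss1()` computes the neighbour lists per candidate on the fly. `mss2()`
produces the identical stem set but first materialises the full
candidate-by-sequence neighbour matrix using a diagonal recurrence on the
pairwise window-distance matrix: along a diagonal, consecutive cells pair
windows sharing an (l-1)-mer, so each cell follows from its predecessor in
O(1) by comparing one dropped and one gained character pair. One O(l)
Hamming evaluation seeds each of the `m` diagonals; diagonals where the
second sequence's window starts before the first's are scanned with
modular (wrap-around) indexing and the wrapped cells, which pair no real
window, are discarded during assembly. This turns the O(m^2 n l) neighbour
computation into O(m^2 n) at a cost of O(m^2) memory. `distance_matrix_naive()`
retains the direct computation purely as the correctness reference.

The optional post-process (`post_process()`, or `validate = TRUE` in the
drivers) retains a stem only if every sequence has a window within `d` of
it, with wildcards matching freely. A stem covering a true motif always
survives this filter.

`stemming_baseline()` implements the pairwise predecessor of the drivers:
it collects *every* l-mer of *every* sequence passing the 2d filter and
places wildcards for all ordered pairs of them within `2d`. Its output
strictly contains (at the expansion level) the driver output and is
typically orders of magnitude larger; it is included both as a comparator
and because the superset relationship is itself a testable claim.

`pms_oracle()` is the brute-force ground truth: it enumerates the full
d-neighbourhood of every candidate l-mer and verifies each against all
sequences. Its work grows like `m * C(l,d) * (sigma-1)^d`, so it refuses
instances beyond an explicit work limit (`max_work`, default 5e6
candidates) with a catchable `mss_infeasible_error`.

## Probability machinery

Under an IID uniform background, each position of two random l-mers
mismatches with probability `(sigma-1)/sigma`, so their distance is
binomial and `p_at_most(l, t, sigma)` is its lower tail at `t`. Terms are
accumulated in log space, summed smallest-first, so the protein regime
(`sigma = 20`, `l` up to 21) does not underflow. From this follow:

* `expected_random_motifs(l, d, sigma, n, m)`: a random l-mer has a
  d-neighbour in one sequence with probability
  `P = 1 - (1-p)^(m-l+1)` (computed via `log1p`/`expm1`), so
  `sigma^l * P^n` motifs arise by chance.
* `challenging_d(l, sigma, n, m)`: the smallest `d` with expectation at
  least 1 — the point where an instance starts containing spurious motifs.
  On the standard benchmark (`n = 20`, `m = 600`) this yields the familiar
  DNA ladder (9,2), (11,3), (13,4), and for proteins (7,4) and (9,5).
* `expected_stem_estimate(l, d, sigma, m)`: the coarse envelope
  `m^2 * p_at_most(l, 2d, sigma) * 2^l * l^d` on the stems a run can
  produce — an order-of-magnitude bound, not a prediction.

The benchmark parameters `n` and `m` default to 20 and 600 throughout:
that is the configuration on which challenging instances are convention-
ally quoted, and the challenging-d values reported by this package assume
it.

## The synthetic benchmark generator

`generate_planted_instance()` reproduces the standard protocol: IID
uniform sequences, one uniformly drawn motif, and per sequence one mutated
copy planted at a uniform position. Two details the protocol leaves open
are fixed as follows:

* the number of mutated positions per copy is drawn uniformly from
  `{0, ..., d}` ("at most d" leaves the distribution open; uniform is the
  least informative choice);
* each mutated position receives a character drawn uniformly from the
  `sigma - 1` characters *different* from the motif character, so the
  chosen positions are genuine mismatches.

Plant positions are uniform over `1..(m-l+1)`, so instances never overhang
a sequence end. The generator runs on a private seeded stream and restores
the session RNG, making instances reproducible from their `(parameters,
seed)` pair alone; `write_planted_instance()` persists the ground truth in
a sidecar text file.

What the generator does *not* emulate: compositional bias, repeats,
homology between sequences, insertions/deletions, or multiple motif
occurrences per sequence. Tests passing on these instances certify the
combinatorics of the search, not its behaviour on biased biological
backgrounds — on real data the 2d filter simply becomes less selective and
the stem set larger, but the superset guarantee is distribution-free.

## Conventions and numerical choices

* Coordinates are 1-based and inclusive, the R/Bioconductor convention;
  window `k` of a sequence covers positions `k .. k+l-1`.
* The wildcard is `*` and is excluded from every sequence alphabet.
* Stem sets are deduplicated on the exact pattern string; stems whose
  expansions are nested are *not* merged (no merging rule is part of the
  model), and provenance keeps the first generating pair per stem.
* All stem and motif outputs are sorted byte-lexicographically
  (locale-independent radix order) so runs are reproducible.
* `p_at_most` clamps its sum at 1 to absorb float rounding at full
  support.
* Distance-matrix values are small integers stored as plain integer
  matrices; thresholding at `2d` happens in the neighbour module, never in
  the distance module.

## Problem sizes used by the test-suite

The suite validates equivalences at the scales their cost structure
affords, chosen once: diagonal-vs-naive matrix equality exhaustively over
all binary pairs up to `m = 8` (plus 200 random DNA/protein pairs up to
`m = 60`); driver equivalence on 50 random planted instances with
`n <= 10`, `m <= 100`, `l <= 11`, `d <= 3`; oracle-certified superset and
subset checks on the DNA subset of those instances (`l <= 9`, `d <= 2`,
`m <= 60`, where the brute-force oracle and the baseline's quadratic pair
enumeration are comfortable); the wildcard-coverage lemma exhaustively for
`l <= 6`, `sigma <= 4`, `d <= 2` (using the position-wise relabeling that
canonicalises one pair member to `aaa...a`); and one full-scale protein
benchmark (`n = 20`, `m = 600`, `l = 9`, `d = 2`) run end to end.

## A worked example

```{r example}
pi <- generate_planted_instance(n = 5, m = 60, l = 7, d = 1,
                                alphabet = "dna", seed = 11)
pi$motif

res <- motif_stems(pi$sequence_set, l = 7, d = 1, algorithm = "mss2",
                   validate = TRUE)
res

head(res$stems)

# the ground-truth motif is covered by the surviving stems
min(vapply(res$stems, stem_distance, integer(1), y = pi$motif))
```

## Known limitations

* The drivers draw candidates from the first sequence only; if the first
  sequence is unrepresentative (e.g. lacks a motif occurrence — impossible
  for planted instances, possible for arbitrary data where a "motif" need
  not occur verbatim anywhere), stems are still a superset of all motifs,
  because every motif is within `d` of *some* window of sequence 1 by
  definition.
* Runtime is dominated by `|stems|` at large `d`; the closed-form envelope
  `expected_stem_estimate()` indicates when an instance will flood.
* DNA at challenging `d` produces very large spurious-stem sets (the
  method is designed for large alphabets); classical PMS algorithms are
  the better tool there.
* No insertion/deletion model: distances are Hamming throughout.
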