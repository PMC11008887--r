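---
title: "Block-wise merging of alignment ensembles by sum-of-pairs score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block-wise merging of alignment ensembles by sum-of-pairs score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalign)
```

## The problem

Different multiple-sequence-alignment (MSA) programs make different
trade-offs, and no single aligner wins on every data set. A common remedy
is meta-alignment: run several aligners on the same unaligned nucleic-acid
sequences and combine their outputs into one alignment that is at least as
good as the best input. `metalign` implements such a combiner. Its
guarantee is stated in terms of the sum-of-pairs (SP) objective: the
merged alignment's SP score is provably greater than or equal to the SP
score of every input.

## The model

### The SP objective

For an alignment of $N$ sequences, each column contributes the sum of
pairwise character scores over all $\binom{N}{2}$ unordered row pairs:
$+1$ for two identical letters, $-1$ for two different letters, $-2$ for a
letter opposite a gap, and $0$ for two gaps. The alignment's SP score is
the sum over its columns, and the aSP score divides by $\binom{N}{2}$ to
make values comparable across sequence counts. Letter identity is
case-insensitive, and IUPAC ambiguity codes are ordinary letters: two
`N`s match, `N` against `A` mismatches. We sum each unordered pair once;
writing the column sum over ordered pairs merely doubles every score, so
every comparison and argmax in the pipeline is unaffected, and per-pair
normalisation of aSP is conventional. The implementation counts letters
per column (matches are $\sum_b \binom{c_b}{2}$ over letter counts
$c_b$) rather than enumerating pairs, and the test suite checks it
against a literal double-loop oracle.

Two properties of this objective carry the whole method:

* **Column additivity** — the SP score of an alignment is the sum of the
  SP scores of any partition of its columns.
* **Row-permutation invariance** — reordering sequences does not change
  the score.

### Validation

The inputs are the unaligned reference set $R$ and $n$ candidate
alignments. Each candidate is reordered to $R$'s sequence order (some
aligners emit guide-tree order instead), matched by identifier when the
identifiers correspond one-to-one and otherwise by ungapped content, with
duplicate sequences assigned stably in first-occurrence order. All
sequences are sanitized by deleting every character other than the 52
ASCII letters — some aligners silently drop such characters themselves,
so comparing raw strings would reject legitimate alignments. A candidate
is accepted when every row, after degapping and sanitizing, equals the
corresponding sanitized reference sequence up to letter case; the $m \le
n$ survivors proceed to merging. Comparison is case-insensitive because
aligners disagree on case conventions (e.g. soft-masking), while output
preserves the input's case.

### Partitioning two alignments into block pairs

Two validated alignments of the same sequences contain the same residues
in the same row order and differ only in gap placement. Recoding each as
a binary mask (gap $\to$ 0, anything else $\to$ 1) discards base identity
and keeps exactly that difference. A *pace* vector at a column position
is the per-sequence cumulative count of 1s scanned so far, i.e. how many
residues of each sequence lie at or before that column.

A *cutting site* is a pair of positions, one per alignment, where the two
pace vectors are equal: both prefixes contain exactly the same residues
of every sequence, so the alignments can be split there compatibly. The
scan that finds all cutting sites uses two pointers, one per mask. The
active pointer advances column by column; as soon as any component of its
pace strictly exceeds the other pointer's, it halts and the other pointer
becomes active ("greater" is component-wise: some index strictly larger).
Whenever the two pace vectors are exactly equal the current position pair
is recorded. Each pointer only ever moves forward and each column is
consumed exactly once, so the scan is linear in the total number of
columns — the pointer-advance count is asserted to equal
$\mathrm{width}_1 + \mathrm{width}_2$ in the tests. Because both masks
have the same per-sequence residue totals, the scan always ends with both
paces equal, so the final cutting site is the pair of full widths and at
least one block always exists.

Consecutive cutting sites delimit half-open column intervals — a *block
pair* — holding identical sequence fragments with possibly different gap
placements. Cut coordinates are stored as "columns consumed" (0-based
half-open interval ends), which lets intervals compose without off-by-one
adjustments.

### Merging

For each block pair the block with the higher SP score is kept, and the
winners are concatenated in cut order. By column additivity the result's
SP score is $\sum_b \max(\mathrm{sp}_1^{(b)}, \mathrm{sp}_2^{(b)})$,
which dominates both inputs. An ensemble of $m$ validated alignments is
merged by $m-1$ pairwise steps in descending order of whole-alignment SP
score: the two best first, then the running result against the next best.
By induction the final SP score dominates every input. The order is fixed
once from the initial SP scores rather than re-sorted after each step;
with ties broken by stable input order, this makes the pipeline fully
deterministic (same inputs, byte-identical output).

Tie-breaks: when a block pair ties on SP, the block of the first operand
— the alignment earlier in the descending-SP order — is kept. Merging an
alignment with itself therefore returns it unchanged, and while the
tie-broken *rows* of `merge_pair(a, b)` and `merge_pair(b, a)` may
differ, their SP scores are equal (asserted in the tests).

### Quality metrics

For benchmarking against a trusted reference alignment the package
provides, besides aSP:

* **Q** — the fraction of residue pairs aligned in the reference (two
  residues of different sequences sharing a column) that also share a
  column in the test alignment.
* **TC** — the fraction of reference columns whose complete
  residue-ordinal signature (which residue of each sequence, or a gap,
  occupies the column) recurs as a column of the test alignment.

We read "columns in the reference" as *all* reference columns, gapped or
not; external benchmark tools vary in this denominator convention, so the
choice is stated here to make comparisons reproducible. Both metrics are
invariant to inserting all-gap columns into the test alignment.

## Numerical and degenerate-input choices

* **All-gap columns** are stripped from every validated alignment before
  partitioning, and defensively from merged results. They score 0 under
  the objective and carry no information, but they create pace plateaus
  that make cutting-site positions non-unique; after stripping, every
  column increments at least one pace component, each prefix pace vector
  occurs at most once per mask, and the cut set is unique and
  order-invariant.
* **Which pointer scans first** is arbitrary for the resulting cut set
  (asserted against a brute-force enumeration oracle); the implementation
  always starts with the first alignment for determinism.
* **Scores are exact**: integer-valued arithmetic throughout the
  objective (stored in doubles, far below the 2^53 exact-integer limit),
  no floating-point accumulation; aSP and the metrics are exact ratios
  evaluated once.
* **Gap dialects**: `-` and `.` are both accepted on input; `-` is
  emitted on output. Output FASTA wraps at 60 columns.
* **A single surviving alignment** ($m = 1$) is returned unchanged with a
  warning; zero survivors is an error.

## The synthetic-data generator

Real ensembles come from running external aligners, which this package
deliberately does not do. The generator stands in for them structurally:
`generate_reference()` draws a random DNA ancestor (length uniform in a
range) and derives each sequence by independent per-site substitutions
and short (1–3 base) indels; `generate_ensemble()` lays the set out as
`k` alignments that all degap back to it — one left-flush layout plus
jittered and random-gap-placement variants. Defaults (10 sequences of
100–200 bases, substitution rate 0.05, indel rate 0.02, k = 5) are
typical of small rRNA-like test sets; the property tests span 5–20
sequences of 50–300 bases with 2–9 alignments per ensemble, sizes at
which every invariant can be cross-checked against brute-force oracles in
seconds. All randomness is driven by integer seeds through R's generator,
so fixtures are reproducible.

What the generator does **not** emulate: phylogenetic structure (all
sequences are siblings of one ancestor), realistic indel length
distributions, aligner-like gap placement (its random layouts are far
worse than any real aligner's output), or similarity-calibrated
divergence. Passing tests therefore demonstrate the method's structural
guarantees — validation round-trips, cut-site correctness, SP dominance,
metric identities — on arbitrary valid ensembles; they say nothing about
alignment *accuracy* on biological data, which depends on the quality of
the input alignments being merged.

## Known limitations

* The SP-dominance guarantee is relative to the inputs under the chosen
  scoring scheme; it does not imply biological optimality, and a merged
  alignment can equal the best input when no block swap helps.
* Merging is pairwise and sequential in a fixed order; no global search
  over merge orders, and no recombination at resolution finer than a
  block.
* Only FASTA I/O; ragged alignments are rejected, not repaired.
* Affine gap penalties and similarity matrices are out of scope for the
  objective.
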