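---
title: "Methods: a Boolean algebra over all minimal alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Boolean algebra over all minimal alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varalgebra)
```

## The problem and the model

Two descriptions of small genetic variants can relate to each other in ways
that no single normalised representation reveals. `varalgebra` classifies a
pair of variants over a shared reference sequence `R` as exactly one of
*equivalent*, *contains*, *is contained*, *overlap* or *disjoint*, defined
over the **set of all minimal alignments** between `R` and each observed
sequence.

The primitive operations are single-symbol deletions (at a 1-based
reference position) and single-symbol insertions (anchored in the gap after
a reference position; anchor 0 precedes the sequence). SNVs,
multi-nucleotide variants and delins forms are treated as compositions of
these primitives. A representation is *interpretable* if patching the
reference with it deterministically yields the observed sequence; it is
*minimal* if it has the fewest possible operations, which equals the simple
edit distance `d(R,O)` (Levenshtein without substitutions, unit costs).
Relations are functions of the sequences `(R, O, P)` only: a non-minimal
input representation is patched to its observed sequence and implicitly
re-minimised, so the same pair of variants always yields the same relation
no matter how it was written.

Assumptions worth stating explicitly:

* both variants are described against the *same* reference sequence (the
  algebra does not compare across references or reference builds);
* variants are sequence-level precise (non-exact structural-variant
  notation is out of scope);
* empty variants (observed = reference) are rejected with an error rather
  than silently classified — the relations are defined between non-empty
  variants, and a silent convention would corrupt database semantics;
* inversions are representable (as delins) but their deletion/insertion
  distance does not reflect their biological nature — a known limitation.

## Decision procedure

For observed sequences `O` and `P`, with `dO = d(R,O)`, `dP = d(R,P)`,
`dOP = d(O,P)`:

1. `O == P` → equivalent (string equality; no alignment needed).
2. `dO − dP == dOP` → contains; `dP − dO == dOP` → is contained. The
   distance test is exact: a minimal path from `R` to `O` passing through
   `P` exists if and only if the distances telescope.
3. `dO + dP == dOP` → disjoint (minimal paths on opposite "sides" of `R`).
4. Otherwise the element sets decide: `Ψ(R,O) ∩ Ψ(R,P) = ∅` → disjoint,
   else overlap. `Ψ` — the union of elements over all minimal
   representations — is at most quadratic in the sequence lengths even when
   the number of representations is exponential, and only the *emptiness*
   of the intersection is consumed, so repeated identical insertions can be
   collapsed safely.

Step 3 alone is not sufficient for disjointness: for `R = CT`, `O = TG`,
`P = GC` all three distances are 2, every distance test is inconclusive,
and only the empty Ψ-intersection shows the pair is disjoint.

### The sub-representation relation

The definition-level notion behind containment ("some minimal
representation of P is part of some minimal representation of O") needs
care when insertions repeat. We implement: deletions as a position subset,
and — per anchor — the smaller representation's inserted string must be a
**subsequence** of the larger's, with strictly fewer operations in total.
Plain element-set comparison is too coarse (two insertions of `T` at one
anchor collapse into one set element), and plain multiset comparison is too
lax, because the order of insertions sharing an anchor is part of the
representation: for `R = A`, `O = ACAAA`, `P = AAAAAAC`, the multiset of
`[1_2insC;1_2insA×3]` is contained in that of `[1_2insA×5;1_2insC]`, but
`CAAA` is not a subsequence of `AAAAAC` and indeed no minimal path from `R`
to `P` passes through `O`. With the subsequence reading, the
definition-based classification and the distance tests agree on every case
we enumerate — the central cross-check of the test suite.

## Computing all minimal alignments

The full dynamic-programming matrix is quadratic in space and infeasible
for long sequences, so the package expands the matrix with A\* search using
the admissible heuristic `h(i,j) = |(|R|−i) − (|O|−j)|` and total cost
`f = D + h`. Orthogonal steps towards the target diagonal leave `f`
unchanged, steps away cost +2, and diagonal match runs ("snakes") are
followed greedily, so cells are expanded in waves of constant `f` starting
at `||R|−|O||` and stepping by 2; the final wave's `f` is the distance.

The frontier needs only linear temporary space: for each diagonal
`k = j − i` the furthest expanded row is kept (along a diagonal the
`D`-values are non-decreasing with constant parity, so each wave extends
every diagonal by one contiguous, constant-`D` run). The equivalent
rows/cols arrays — right-most expanded column per row and bottom-most row
per column — are recorded per wave for inspection:

```{r waves}
g <- build_lcs_graph("CATATATCG", "CTTATAGCAT")
g$fs
g$waves[[1]][c("f", "rows", "cols")]
```

Expanded match cells become nodes of the **LCS-graph** at level
`⌊(i + j − D(i,j))/2⌋` (their position in a longest common subsequence);
edges connect level `ℓ` to level `ℓ+1` wherever both coordinates strictly
increase, labelled with the deleted run and inserted run of the gap.
Because any source→sink path through one node per level costs exactly
`d(R,O)`, *every* complete path is a minimal alignment; match cells that
sit on no complete path (they were expanded but are not co-optimal) are
removed by a reachability sweep from both ends. We prune after building
rather than constructing backwards from the sink — the output is the same
and the sweep is a single pass per direction.

From the graph:

* `enumerate_minimal()` materialises Φ — per path and per monotone
  interleaving of each gap's deletions and insertions (an inserted symbol
  may be anchored after any prefix of the gap's deletions, with
  non-decreasing anchors along the gap's insertion order). Enumeration is
  exponentially bounded, so a `cap` (default 10 000) turns blowup into a
  clean error of class `"varalg_cap_error"`; callers that only need the
  element set never enumerate.
* `element_set()` computes Ψ directly: a gap with deletions `a..b`
  contributes those deletions, and each gap insertion symbol contributes an
  insertion element at every anchor in `[a−1, b]`. This anchor-range rule
  is validated against the enumeration oracle rather than derived from
  first principles.

## Maximal influence intervals and the prefilter

The maximal influence interval is the hull of Ψ over reference positions:
a deletion at `i` spans `[i, i+1)`, an insertion anchor `p` the degenerate
point `[p, p)`. Pairs of variants whose intervals do not intersect are
guaranteed disjoint, which lets `run_all_pairs()` skip the alignment work
for most pairs of a large set; intersecting intervals still go through the
full comparison (the prefilter may have false positives, never false
negatives).

Two boundary conventions matter:

* A degenerate interval `[p, p)` intersects `[s, e)` when `s ≤ p ≤ e`,
  inclusive at both boundaries (a pure insertion at a boundary can share
  its anchor element with the neighbour).
* When the *end* of a non-degenerate interval is attained by an insertion
  anchor rather than a deletion, that anchor lies on the boundary itself.
  The interval records this (`end_closed`), and boundary-touching intervals
  with a closed end are reported as intersecting. Without this refinement a
  strict half-open test would wrongly reject, e.g., Ψ₁ = {del 1, ins(5,X)}
  (interval `[1,5)`) against Ψ₂ = {ins(5,X), del 8} (interval `[5,9)`),
  which share an element. The printed form stays `[start, end)`.

## Supremal representations

For indexing, a variant can be stored as a single delins whose deletion
spans its maximal influence interval and whose insertion repeats whatever
reference material it does not change: `supremal_variant("CACAT", "3C>T")`
is `2_3delinsAT`. Two end-cases are our own choices: for a degenerate
interval the supremal form stays a pure insertion at the single anchor, and
when the interval end is anchor-attained (`end_closed`) the deletion span
includes the end position, since insertions may follow it — in both cases
patching the reference with the supremal form reproduces the observed
sequence exactly, which the property suite asserts. We deliberately do
*not* use SPDI-style rolling extension, which does not in general cover all
minimal alignments; the construction here comes from the LCS-graph.

## Parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `cap` | `enumerate_minimal()`, `enumerate_paths()` | 10 000 / 100 000 | abort threshold for exponential enumeration |
| `size_guard` | `dp_full_matrix()` | 64 | maximum sequence length for the quadratic-space oracle |
| `use_prefilter` | `run_all_pairs()` | `TRUE` | interval prefilter on/off (results are identical either way) |
| `skip_invalid` | `read_variant_list()` | `FALSE` | skip unparseable lines with a warning instead of failing |
| `ref_length`, `alphabet`, `op_count`, `n_variants` | `random_case()` | 24, ACGT, 3, 4 | fixture generator regime |

The defaults of `random_case()` define the synthetic study conditions used
throughout the property suites: gene-fragment-scale references (24 bp)
built from homopolymer runs and short tandem repeats interleaved with
random stretches, and variants of up to three operations (deletion runs of
1–3, insertions of 1–3 symbols, SNVs). Repeats are the regime that
maximises co-optimal-alignment ambiguity — the hard case for this algebra —
so passing on these fixtures is informative about exactly the situations
where normalisation-based comparison fails. What the generator does *not*
emulate: realistic genome-scale sequence composition, sequencing error,
structural variants, or the empirical size/spacing distribution of variants
in real databases; conclusions about throughput or relation frequencies in
real data do not follow from these tests.

## HGVS subset and canonical formatting

The parser accepts the genomic-coordinate subset used for small variants —
`NdelS?`, `N_MdelS?`, `N_MinsSEQ`, `N_MdelinsSEQ`, `NX>Y` and bracketed
`;`-separated alleles — and errors loudly on everything else (dup, inv,
repeats, uncertainty) rather than misparse. A delins expands to deletions
`N..M` plus insertions anchored at `M`; the choice is immaterial because
relations are computed from patched sequences. Deletion symbol annotations
are validated when present and optional otherwise.

No canonical textual form for multi-operation representations is imposed by
the nomenclature, so `format_variant()` fixes one: operations sorted by
position, adjacent runs collapsed to `del`/`ins`/`delins` shorthand, a
single-position deletion–insertion with a known deleted symbol written as
an SNV, brackets only for multiple groups. The round-trip guarantee is
semantic, not syntactic: parsing a formatted representation patches to the
same observed sequence.

## Numerical and degenerate-input choices

* Sequences are uppercased; symbols are compared literally (no IUPAC
  ambiguity semantics). Empty sequences are valid everywhere except as the
  reference of a comparison.
* Matrix orientation: rows are indexed by the reference, columns by the
  observed sequence; the virtual source `(0,0)` sits at level 0 and the
  virtual sink at `(|R|+1, |O|+1)`, so leading/trailing gaps are ordinary
  edges.
* `O == P` short-circuits before any alignment; identical inputs never
  depend on tie-breaking.
* All counters use R integers except representation counts, which use
  doubles (they overflow 32-bit integers long before the cap is reached).
* The wave trace, frontier arrays and graph object are plain lists of
  integer vectors; no `|R|×|O|` matrix is ever allocated outside the
  deliberately quadratic oracle.

## Validation strategy and problem sizes

The package carries its own independent oracle: the full-matrix recurrence,
exhaustive backtrace enumeration, and literal evaluation of the relation
definitions. The test suite checks, among other properties:

* wave distance, graph enumeration and Ψ against the oracle for *every*
  pair of strings over {A,C,T} up to length 4 and for seeded random pairs
  up to length 12 over ACGT;
* the five-way classification against the definition-based oracle for the
  full domain of references over {A,C} up to length 4 against all observed
  sequences up to length 5 (≈10^5 ordered triples), driven through the
  package's own batch machinery;
* supremal patch-equivalence, prefilter soundness, the partition property
  and converse-symmetry on 500 seeded repeat-rich cases;
* prefilter-on/off equality of a 50-variant all-pairs run.

These sizes keep the whole suite at a couple of minutes on one CPU while
covering the exhaustive small domain completely; the algorithms themselves
have no small-size assumptions.

## Known limitations

* The composition of an overlap (which elements are shared, and how many)
  is not computed — only its existence; quantifying overlap would require
  enumerating an exponential set.
* Relations across different reference sequences are undefined here.
* The elements-per-edge reduction and bit-string Ψ encodings are not
  implemented (correctness-first); they are pure optimisations and do not
  change results.
* Very long references are limited by R-level performance of the wave loop,
  not by memory; the design keeps temporary space linear.
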