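# varalgebra

A Boolean algebra for genetic variants: classify every pair of variants
described against a shared reference sequence as exactly one of
**equivalent**, **contains**, **is contained**, **overlap** or
**disjoint**, by reasoning over *all* minimal alignments simultaneously.

## Why

Variant databases, diagnostic pipelines and annotation tools usually decide
whether two variant descriptions "are the same" by normalising each to a
canonical form (3'-rule in HGVS, left-alignment in VCF, SPDI rolling) and
comparing strings. Normalisation is sound for equivalence but for nothing
else: whether an SNV is contained in a larger deletion–insertion, or two
indels in a repeat share an element, depends on *which* co-optimal alignment
you look at, and in repetitive sequence the number of co-optimal alignments
grows exponentially. Questions like "is this suballele part of the observed
allele?" (star-allele calling, strain typing) or "which known variants does
this novel indel intersect?" need a relation defined over the whole set of
minimal alignments, not over one normalised representative.

This package is for people building or querying variant collections —
locus-specific databases, VCF annotation, pharmacogenomic allele matching —
and for anyone who needs a decision procedure for variant identity that is
independent of representation.

## The model

A variant is a pair (R, φ): a reference string R and a set of atomic
operations (single-symbol deletions at reference positions, single-symbol
insertions anchored after a reference position) that deterministically
patches R into the observed string O. Distance between strings is the
**simple edit distance** — Levenshtein without substitutions, deletions and
insertions at unit cost — computed by the recurrence

    D(i,0) = i,  D(0,j) = j
    D(i,j) = D(i-1,j-1)                      if R_i = O_j
           = min(D(i-1,j), D(i,j-1)) + 1     otherwise

which relates to the longest common subsequence by
`D(i,j) = i + j - 2·|LCS(R_1..i, O_1..j)|`. Φ(R,O) is the set of all
*minimal* representations (monotone paths through the matrix); Ψ(R,O) is
the set of all elements occurring in any member of Φ — at most quadratic in
size even when Φ is exponential.

For two variants over the same R with observed sequences O and P:

* **equivalent** iff O = P;
* **contains** iff `d(R,O) − d(R,P) = d(O,P)` (a minimal path from R to O
  passes through P); *is contained* is the converse;
* **disjoint** if `d(R,O) + d(R,P) = d(O,P)`, and otherwise decided by
  whether Ψ(R,O) ∩ Ψ(R,P) is empty;
* **overlap** in the remaining case (some minimal representations share an
  element but neither containment holds).

Exactly one relation holds for every pair of non-empty variants.

The engine underneath is a wave-based A\* expansion of the distance matrix
with the admissible heuristic `h(i,j) = |(|R|−i) − (|O|−j)|`: cells are
expanded in waves of constant `f = D + h` starting at `||R|−|O||` and
stepping by 2, with the frontier held in linear-space arrays. The expanded
match cells form the **LCS-graph**, a DAG whose source→sink paths spell
exactly the minimal alignments; Ψ, the **maximal influence interval** (an
interval prefilter that lets an all-pairs run skip almost all distant
pairs), and the **supremal** delins representation (a database-indexable
single deletion–insertion spanning the whole influence interval) all fall
out of this graph.

## Worked example

```r
library(varalgebra)

compare_variants("TTTTTT", "2_5delinsGGG", "3T>G")
#> [1] "contains"

g <- build_lcs_graph("ATTTA", "ATTA")
sapply(enumerate_minimal(g), format_variant, reference = "ATTTA")
#> [1] "4delT" "3delT" "2delT"
element_set(g)
#> # A tibble: 3 × 3
#>   op      pos symbol
#>   <chr> <int> <chr>
#> 1 del       2 T
#> 2 del       3 T
#> 3 del       4 T
```

Deleting one T from the run `TTT` in `ATTTA` can be aligned three ways;
`enumerate_minimal()` lists all three minimal representations and
`element_set()` their union Ψ. The all-pairs driver with the interval
prefilter:

```r
records <- run_all_pairs("TCCCTTTA",
  c(O = "3C>A", P = "6T>G", P1 = "[4del;5_6insC]", P2 = "2_3insT"))
records
#> # A tibble: 6 × 7
#>   lhs_id rhs_id relation lhs_interval_start lhs_interval_end rhs_interval_start
#> 1 O      P      disjoint                  2                5                  5
#> 2 O      P1     overlap                   2                5                  2
#> 3 O      P2     disjoint                  2                5                  2
#> 4 P      P1     overlap                   5                8                  2
#> 5 P      P2     disjoint                  5                8                  2
#> 6 P1     P2     disjoint                  2                8                  2
glance(records)
#> # A tibble: 1 × 7
#>   n_variants n_pairs equivalent contains is_contained overlap disjoint
#> 1          4       6          0        0            0       2        4
```

`O` and `P` are disjoint on their influence intervals `[2,5)` and `[5,8)`
alone — no alignment work is done for that pair. `O` and the pure insertion
`P2` have intersecting intervals but turn out disjoint after the full
comparison: the prefilter is conservative, never wrong. Finally, the
supremal (indexable) form of an SNV in an ambiguous context:

```r
supremal_variant("CACAT", "3C>T")
#> <supremal variant> 2_3delinsAT (deletion span [2, 4))
```

A command-line interface wrapping the same functions is installed as
`exec/varalgebra` (subcommands `distance`, `compare`, `all-pairs`,
`supremal`, `influence`, `graph`).

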