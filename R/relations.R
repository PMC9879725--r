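relation_levels <- c("equivalent", "contains", "is_contained", "overlap", "disjoint")

# Resolve a variant given as a representation, an observed() sequence, a
# "seq:"-prefixed string, or an HGVS-subset description, to its observed
# sequence with respect to `reference`.
resolve_observed <- function(reference, x, arg = "variant") {
  if (is_variant_rep(x)) return(patch(reference, x))
  if (inherits(x, "observed_seq")) return(unclass(x))
  if (is.character(x) && length(x) == 1L && !is.na(x)) {
    if (startsWith(x, "seq:")) return(check_sequence(substring(x, 5L), arg))
    return(patch(reference, parse_variant(x, nchar(reference))))
  }
  abort_varalg(
    sprintf("`%s` must be a variant_rep, observed() sequence, or description string.", arg),
    "varalg_type_error"
  )
}

# Core five-way classification on observed sequences. `psi` is a function
# O -> Psi key set, injectable so batch drivers can cache per variant.
compare_observed <- function(R, O, P, psi = NULL) {
  if (O == R || P == R) {
    abort_varalg(
      "relations are defined for non-empty variants only (observed equals reference).",
      "varalg_empty_variant_error"
    )
  }
  if (O == P) return("equivalent")
  dO <- wave_core(R, O)$distance
  dP <- wave_core(R, P)$distance
  dOP <- wave_core(O, P)$distance
  if (dO - dP == dOP) return("contains")
  if (dP - dO == dOP) return("is_contained")
  if (dO + dP == dOP) return("disjoint")
  if (is.null(psi)) psi <- function(obs) psi_keys(build_lcs_graph(R, obs))
  if (any(psi(O) %in% psi(P))) "overlap" else "disjoint"
}

#' Boolean relation between two variants
#'
#' Classifies a pair of variants over a shared reference as exactly one of
#' `"equivalent"`, `"contains"`, `"is_contained"`, `"overlap"` or
#' `"disjoint"`, reasoning over *all* minimal alignments. Non-minimal input
#' representations are admissible: variants are patched to their observed
#' sequences and implicitly re-minimised, so the relation is a function of
#' the three sequences only. The decision uses distance-only fast paths
#' (equivalence by string equality; containment when
#' `d(R,O) - d(R,P) = d(O,P)`; disjointness when `d(R,O) + d(R,P) = d(O,P)`)
#' and falls back to intersecting the element sets Psi(R,O) and Psi(R,P)
#' only to separate overlap from disjoint.
#'
#' @param reference Reference sequence (non-empty string).
#' @param lhs,rhs Variants: a [variant_rep], an [observed()] sequence, a
#'   `"seq:"`-prefixed sequence string, or an HGVS-subset description.
#' @return One of the five relation names. Empty variants (observed sequence
#'   equal to the reference) raise an error of class
#'   `"varalg_empty_variant_error"`: the relations are defined between
#'   non-empty variants only.
#' @examples
#' compare_variants("TTTTTT", "1delT", "6delT")          # equivalent
#' compare_variants("TTTTTT", "2_5delinsGGG", "3T>G")    # contains
#' compare_variants("CT", observed("TG"), observed("GC")) # disjoint
#' @export
compare_variants <- function(reference, lhs, rhs) {
  reference <- check_sequence(reference, "reference", allow_empty = FALSE)
  O <- resolve_observed(reference, lhs, "lhs")
  P <- resolve_observed(reference, rhs, "rhs")
  compare_observed(reference, O, P)
}

#' Algebraic properties of the Boolean relations
#'
#' Symmetry, reflexivity and transitivity of each relation: equivalence is
#' an equivalence relation; containment (either direction) is a strict
#' partial-order-like relation (asymmetric, irreflexive, transitive);
#' overlap and disjoint are symmetric, irreflexive and intransitive. The
#' converse of `"contains"` is `"is_contained"` and vice versa.
#'
#' @param relation Optionally, a single relation name to select one row.
#' @return A tibble with columns `relation`, `symmetry`, `reflexivity`,
#'   `transitivity` (and `converse`).
#' @examples
#' relation_properties("overlap")
#' @export
relation_properties <- function(relation = NULL) {
  tbl <- tibble::tibble(
    relation = relation_levels,
    symmetry = c("symmetric", "asymmetric", "asymmetric", "symmetric", "symmetric"),
    reflexivity = c("reflexive", "irreflexive", "irreflexive", "irreflexive", "irreflexive"),
    transitivity = c("transitive", "transitive", "transitive", "intransitive", "intransitive"),
    converse = c("equivalent", "is_contained", "contains", "overlap", "disjoint")
  )
  if (is.null(relation)) return(tbl)
  if (!relation %in% relation_levels) {
    abort_varalg(sprintf("unknown relation \"%s\"", relation), "varalg_type_error")
  }
  tbl[tbl$relation == relation, ]
}
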