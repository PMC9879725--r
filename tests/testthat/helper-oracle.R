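# Shared helpers: canonical representation keys, exhaustive string sets,
# and a cached definition-based pair classifier for the big oracle sweeps.

# Canonical key for comparing representations as sets: deletions sorted by
# position (annotations ignored), insertions in row order (both enumerators
# emit insertions with non-decreasing anchors, preserving per-anchor symbol
# order).
canonical_rep_key <- function(r) {
  del <- r$op == "del"
  paste(c(sort(paste0("d", r$pos[del])),
          paste0("i", r$pos[!del], ":", r$symbol[!del])),
        collapse = "|")
}

rep_key_set <- function(reps) sort(vapply(reps, canonical_rep_key, character(1)))

# All strings over `alphabet` with length min_len..max_len.
all_strings <- function(max_len, alphabet, min_len = 0L) {
  out <- if (min_len == 0L) "" else character(0)
  for (l in seq_len(max_len)) {
    if (l < min_len) next
    grid <- do.call(expand.grid, c(rep(list(alphabet), l), stringsAsFactors = FALSE))
    out <- c(out, apply(grid, 1L, paste, collapse = ""))
  }
  out
}

# Per-variant oracle cache entry for a fixed reference: full enumeration,
# structural views and element keys.
oracle_variant_cache <- function(reference, observed_seq, cap = 100000L) {
  reps <- enumerate_paths(dp_full_matrix(reference, observed_seq), cap = cap)
  list(
    observed = observed_seq,
    reps = reps,
    structs = lapply(reps, varalgebra:::rep_structure),
    keys = unique(unlist(lapply(reps, varalgebra:::rep_element_keys)))
  )
}

# Relation records as a bare data frame (attributes and class dropped) for
# whole-table comparisons.
records_frame <- function(x) {
  df <- data.frame(lapply(unclass(x)[names(x)], unname), stringsAsFactors = FALSE)
  attr(df, "row.names") <- seq_len(nrow(df))
  df
}

# Definition-based relation from two cache entries (same decision procedure
# as relation_by_definition, over precomputed enumerations).
oracle_relation_cached <- function(co, cp) {
  if (co$observed == cp$observed) return("equivalent")
  contains <- function(big, small) {
    if (small[[1]]$size >= big[[1]]$size) return(FALSE)
    for (sm in small) {
      for (bg in big) {
        if (varalgebra:::is_proper_subrep(sm, bg)) return(TRUE)
      }
    }
    FALSE
  }
  if (contains(co$structs, cp$structs)) return("contains")
  if (contains(cp$structs, co$structs)) return("is_contained")
  if (any(co$keys %in% cp$keys)) return("overlap")
  "disjoint"
}
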