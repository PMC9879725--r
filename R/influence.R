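#' Maximal influence interval of a variant
#'
#' The extreme bounds, as positions in the reference sequence, of the
#' changes a variant can make under *any* minimal alignment: the hull of
#' the element set Psi, where a deletion at reference position `i` spans
#' `[i, i+1)` and an insertion anchored after position `p` spans the
#' degenerate point interval `[p, p)`. A pair of variants can only be
#' non-disjoint when their maximal influence intervals intersect, which
#' makes the interval a cheap per-variant prefilter for all-pairs
#' comparison (see [prefilter_pairs()]).
#'
#' Intervals are half-open and printed `[start, end)`. When the end bound is
#' attained by an insertion anchor (rather than a deletion), that anchor
#' lies *on* the boundary; the interval records this (`end_closed`) so that
#' boundary-touching intervals are still reported as intersecting and the
#' prefilter never produces false negatives.
#'
#' @param reference Reference sequence, or an `lcs_graph` built for the
#'   variant (in which case `variant` is ignored).
#' @param variant The variant (see [compare_variants()] for accepted forms).
#' @return An `influence_interval` with fields `start`, `end`, `end_closed`.
#' @examples
#' influence_interval("TCCCTTTA", "3C>A")           # [2, 5)
#' influence_interval("TCCCTTTA", "2_3insT")        # [2, 2)
#' @export
influence_interval <- function(reference, variant = NULL) {
  graph <- if (inherits(reference, "lcs_graph")) {
    reference
  } else {
    build_lcs_graph(check_sequence(reference, "reference", allow_empty = FALSE),
                    resolve_observed(reference, variant))
  }
  s <- Inf
  e_del <- -Inf
  e_anch <- -Inf
  for (e in seq_along(graph$edges$from)) {
    gap <- edge_gap(graph, e)
    if (length(gap$dels)) {
      s <- min(s, gap$dels[1L])
      e_del <- max(e_del, gap$dels[length(gap$dels)] + 1L)
    }
    if (length(gap$ins)) {
      s <- min(s, gap$anchors[1L])
      e_anch <- max(e_anch, gap$anchors[length(gap$anchors)])
    }
  }
  if (!is.finite(s)) {
    abort_varalg("the empty variant has no influence interval.",
                 "varalg_empty_variant_error")
  }
  new_influence_interval(
    start = as.integer(s),
    end = as.integer(max(e_del, e_anch)),
    end_closed = e_anch >= e_del
  )
}

new_influence_interval <- function(start, end, end_closed = FALSE) {
  structure(list(start = as.integer(start), end = as.integer(end),
                 end_closed = isTRUE(end_closed)),
            class = "influence_interval")
}

#' @export
format.influence_interval <- function(x, ...) sprintf("[%d, %d)", x$start, x$end)

#' @export
print.influence_interval <- function(x, ...) {
  cat("<maximal influence interval>", format(x), "\n")
  invisible(x)
}

#' Do two maximal influence intervals intersect?
#'
#' Conservative intersection test over intervals from the same reference:
#' a `FALSE` guarantees the pair of variants is disjoint. Two non-degenerate
#' intervals intersect when `max(start) < min(end)`, or when they touch at a
#' boundary that an insertion anchor lies on (`end_closed`). A degenerate
#' point interval `[p, p)` (insertion-only variant) intersects `[s, e)` when
#' `s <= p <= e`, inclusive at both boundaries; two degenerate intervals
#' intersect only when equal.
#'
#' @param a,b `influence_interval` objects (or lists with `start`, `end`,
#'   and optionally `end_closed`).
#' @return `TRUE` or `FALSE`.
#' @examples
#' intervals_intersect(influence_interval("TCCCTTTA", "3C>A"),
#'                     influence_interval("TCCCTTTA", "6T>G"))  # FALSE
#' @export
intervals_intersect <- function(a, b) {
  deg_a <- a$start == a$end
  deg_b <- b$start == b$end
  if (deg_a && deg_b) return(a$start == b$start)
  if (deg_a) return(b$start <= a$start && a$start <= b$end)
  if (deg_b) return(a$start <= b$start && b$start <= a$end)
  ms <- max(a$start, b$start)
  me <- min(a$end, b$end)
  if (ms < me) return(TRUE)
  if (ms > me) return(FALSE)
  # boundary touch: intersects only if the meeting end is an anchor
  (a$end == me && isTRUE(a$end_closed)) || (b$end == me && isTRUE(b$end_closed))
}

#' Candidate variant pairs by interval sweep
#'
#' Given per-variant maximal influence intervals, returns exactly the pairs
#' whose intervals intersect per [intervals_intersect()], by a sort-and-sweep
#' over interval starts (O(n log n + k) for k candidate pairs). Every pair
#' *not* returned is guaranteed disjoint; returned pairs still need
#' [compare_variants()] (intervals may intersect for ultimately disjoint
#' variants).
#'
#' @param intervals A named list of `influence_interval`s (names are ids).
#' @return A tibble with columns `lhs_id`, `rhs_id`, one row per unordered
#'   candidate pair, ids in input order within each pair.
#' @export
prefilter_pairs <- function(intervals) {
  n <- length(intervals)
  ids <- names(intervals)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n < 2L) {
    return(tibble::tibble(lhs_id = character(0), rhs_id = character(0)))
  }
  starts <- vapply(intervals, `[[`, integer(1), "start")
  ends <- vapply(intervals, `[[`, integer(1), "end")
  ord <- order(starts, ends, method = "radix")
  lhs <- character(0); rhs <- character(0)
  for (x in seq_len(n - 1L)) {
    ax <- ord[x]
    for (y in (x + 1L):n) {
      ay <- ord[y]
      if (starts[ay] > ends[ax]) break # sorted by start: no later y can touch
      if (intervals_intersect(intervals[[ax]], intervals[[ay]])) {
        first <- min(ax, ay); second <- max(ax, ay)
        lhs <- c(lhs, ids[first]); rhs <- c(rhs, ids[second])
      }
    }
  }
  tibble::tibble(lhs_id = lhs, rhs_id = rhs)
}

#' Supremal (delins) representation of a variant
#'
#' A normalised single deletion-insertion whose deletion spans the entire
#' maximal influence interval and whose insertion may re-include reference
#' symbols. Supremal representations contain all information needed to
#' relate the variant to others and can be ordered and indexed on their
#' deleted interval, which makes them convenient database keys. For a
#' degenerate interval `[p, p)` the supremal form is the pure insertion of
#' the combined inserted string at anchor `p`.
#'
#' @param reference Reference sequence.
#' @param variant The variant (see [compare_variants()] for accepted forms).
#' @return A `supremal_variant` with fields `interval` (the maximal
#'   influence interval, equal to the deletion span), `inserted` (the
#'   observed span between the matched prefix and suffix) and `description`
#'   (HGVS-subset delins/ins form). `as_variant_rep()` converts it to an
#'   ordinary representation; patching with it reproduces the observed
#'   sequence.
#' @examples
#' supremal_variant("CACAT", "3C>T")$description # "2_3delinsAT"
#' @export
supremal_variant <- function(reference, variant) {
  reference <- check_sequence(reference, "reference", allow_empty = FALSE)
  O <- resolve_observed(reference, variant)
  graph <- build_lcs_graph(reference, O)
  iv <- influence_interval(graph)
  nR <- nchar(reference)
  nO <- nchar(O)
  s <- iv$start; e <- iv$end
  # when the end bound is an insertion anchor, insertions may follow R_e, so
  # the matched suffix only starts at e + 1 and the deletion span includes e
  a <- max(s, 1L); b <- if (iv$end_closed) e else e - 1L
  if (s == e || b < a) {
    # no deleted reference position: pure insertion at anchor s
    inserted <- substr(O, s + 1L, nO - (nR - s))
    desc <- sprintf("%d_%dins%s", s, s + 1L, inserted)
  } else {
    inserted <- substr(O, a, nO - (nR - b))
    span <- if (a == b) sprintf("%d", a) else sprintf("%d_%d", a, b)
    desc <- if (nzchar(inserted)) paste0(span, "delins", inserted) else paste0(span, "del")
  }
  structure(
    list(interval = iv, inserted = inserted, description = desc,
         reference_length = nR),
    class = "supremal_variant"
  )
}

#' @export
print.supremal_variant <- function(x, ...) {
  cat("<supremal variant>", x$description,
      sprintf("(deletion span %s)", format(x$interval)), "\n")
  invisible(x)
}

#' @export
format.supremal_variant <- function(x, ...) x$description

#' Convert a supremal variant to an ordinary representation
#'
#' @param x A `supremal_variant`.
#' @return A [variant_rep] (deletions over the interval plus per-symbol
#'   insertions anchored at its end).
#' @export
as_variant_rep <- function(x) {
  UseMethod("as_variant_rep")
}

#' @export
as_variant_rep.supremal_variant <- function(x) {
  s <- x$interval$start; e <- x$interval$end
  a <- max(s, 1L); b <- if (x$interval$end_closed) e else e - 1L
  sym <- if (nzchar(x$inserted)) strsplit(x$inserted, "")[[1]] else character(0)
  if (s == e || b < a) {
    return(new_variant_rep(rep.int("ins", length(sym)), rep.int(s, length(sym)), sym))
  }
  dels <- seq.int(a, b)
  new_variant_rep(
    c(rep.int("del", length(dels)), rep.int("ins", length(sym))),
    c(dels, rep.int(b, length(sym))),
    c(rep.int(NA_character_, length(dels)), sym)
  )
}

#' @export
as_variant_rep.variant_rep <- function(x) x
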