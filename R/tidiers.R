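#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an LCS-graph into node or edge tibbles
#'
#' @param x An `lcs_graph`.
#' @param what `"edges"` (default) or `"nodes"`.
#' @param ... Unused.
#' @return For nodes: `node`, `i`, `j`, `level`, `kind`. For edges: the two
#'   node indices and coordinates, plus the gap label (`deleted` run and
#'   `inserted` string).
#' @export
tidy.lcs_graph <- function(x, what = c("edges", "nodes"), ...) {
  what <- match.arg(what)
  n <- length(x$nodes$i)
  if (what == "nodes") {
    return(tibble::tibble(
      node = seq_len(n), i = x$nodes$i, j = x$nodes$j, level = x$nodes$level,
      kind = c("source", rep("match", max(n - 2L, 0L)), "sink")[seq_len(n)]
    ))
  }
  ne <- length(x$edges$from)
  deleted <- character(ne)
  inserted <- character(ne)
  for (e in seq_len(ne)) {
    gap <- edge_gap(x, e)
    deleted[e] <- if (length(gap$dels)) {
      paste0(gap$dels[1L], if (length(gap$dels) > 1L) paste0("_", gap$dels[length(gap$dels)]))
    } else ""
    inserted[e] <- paste(gap$ins, collapse = "")
  }
  tibble::tibble(
    from = x$edges$from, to = x$edges$to,
    from_i = x$nodes$i[x$edges$from], from_j = x$nodes$j[x$edges$from],
    to_i = x$nodes$i[x$edges$to], to_j = x$nodes$j[x$edges$to],
    level = x$nodes$level[x$edges$from],
    deleted = deleted, inserted = inserted
  )
}

#' One-row summary of an LCS-graph
#'
#' @param x An `lcs_graph`.
#' @param ... Unused.
#' @return A tibble with the simple edit distance, LCS length, node, edge
#'   and minimal-representation counts, and the first/final wave f-values.
#' @export
glance.lcs_graph <- function(x, ...) {
  tibble::tibble(
    reference = x$reference, observed = x$observed,
    distance = x$distance, lcs_length = x$lcs_length,
    n_nodes = length(x$nodes$i), n_edges = length(x$edges$from),
    n_representations = count_representations(x),
    first_f = x$first_f, n_waves = length(x$fs)
  )
}

#' Plot an LCS-graph on the alignment matrix
#'
#' Match nodes are drawn at their (observed index, reference index)
#' coordinates with the reference running downwards, edges as segments;
#' node labels give `(i,j)/level`.
#'
#' @param object An `lcs_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lcs_graph <- function(object, ...) {
  nodes <- tidy(object, "nodes")
  edges <- tidy(object, "edges")
  lab <- ifelse(nodes$kind == "match",
                sprintf("(%d,%d)/%d", nodes$i, nodes$j, nodes$level),
                nodes$kind)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$from_j, y = .data$from_i,
                   xend = .data$to_j, yend = .data$to_i),
      colour = "grey55",
      arrow = grid::arrow(length = grid::unit(2, "mm"), type = "closed")
    ) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(x = .data$j, y = .data$i),
                        size = 2.5) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$j, y = .data$i, label = lab),
                       vjust = -0.9, size = 3) +
    ggplot2::scale_y_reverse(breaks = unique(nodes$i)) +
    ggplot2::scale_x_continuous(breaks = unique(nodes$j)) +
    ggplot2::labs(
      x = sprintf("observed: %s", object$observed),
      y = sprintf("reference: %s", object$reference),
      title = sprintf("LCS-graph (distance %d, LCS length %d)",
                      object$distance, object$lcs_length)
    ) +
    ggplot2::theme_minimal()
}

#' Summarise relation records
#'
#' @param x A `relation_records` tibble from [run_all_pairs()].
#' @param ... Unused.
#' @return A one-row tibble: variant and pair counts and the per-relation
#'   counts over the upper triangle.
#' @export
glance.relation_records <- function(x, ...) {
  counts <- table(factor(x$relation, levels = relation_levels))
  ids <- attr(x, "variant_ids")
  tibble::tibble(
    n_variants = if (is.null(ids)) NA_integer_ else length(ids),
    n_pairs = nrow(x),
    equivalent = as.integer(counts[["equivalent"]]),
    contains = as.integer(counts[["contains"]]),
    is_contained = as.integer(counts[["is_contained"]]),
    overlap = as.integer(counts[["overlap"]]),
    disjoint = as.integer(counts[["disjoint"]])
  )
}

#' Plot per-relation counts of an all-pairs run
#'
#' @param object A `relation_records` tibble.
#' @param ... Unused.
#' @return A ggplot bar chart of pair counts by relation.
#' @export
autoplot.relation_records <- function(object, ...) {
  df <- tibble::tibble(relation = factor(object$relation, levels = relation_levels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$relation)) +
    ggplot2::geom_bar() +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::labs(x = "relation", y = "pairs (upper triangle)",
                  title = "Boolean relations over all variant pairs") +
    ggplot2::theme_minimal()
}
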