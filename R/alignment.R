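# Wave-based A* expansion of the simple edit distance matrix.
#
# Cells are expanded in waves of constant total cost f = D(i,j) + h(i,j),
# with the admissible heuristic h = |(|R|-i) - (|O|-j)|. The frontier is kept
# per diagonal k = j - i as the furthest expanded row (linear temporary
# space); along a diagonal the D-values are non-decreasing and of constant
# parity, so the cells newly expanded in a wave all carry D = f - |delta - k|.
# Orthogonal steps towards the target diagonal delta = |O| - |R| leave f
# unchanged (processed within the wave, sweeping outside-in), steps away
# from it cost +2 (picked up by the next wave); diagonal match "snakes" are
# followed greedily and leave f unchanged.
wave_core <- function(R, O, record = FALSE) {
  ra <- charToRaw(R)
  oa <- charToRaw(O)
  nR <- length(ra)
  nO <- length(oa)
  delta <- nO - nR
  noff <- nR + 1L
  ndiag <- nR + nO + 1L
  V <- rep.int(-1L, ndiag) # furthest expanded row i per diagonal
  f <- abs(delta)
  fs <- integer(0)
  mi <- integer(0); mj <- integer(0); md <- integer(0)
  waves <- list()

  repeat {
    p <- (f - abs(delta)) %/% 2L
    kmin <- min(0L, delta) - p
    kmax <- max(0L, delta) + p
    ks <- c(
      if (kmin <= delta - 1L) seq.int(kmin, delta - 1L) else integer(0),
      if (kmax >= delta + 1L) seq.int(kmax, delta + 1L, by = -1L) else integer(0),
      delta
    )
    for (m in ks) {
      im <- m + noff
      imax <- min(nR, nO - m)
      istart <- max(0L, -m)
      cand <- V[im]
      # insertion entry from diagonal m-1 (free towards delta, else previous wave)
      v <- if (im > 1L) V[im - 1L] else -1L
      if (v >= 0L) {
        v <- min(v, imax)
        if (v >= istart) cand <- max(cand, v)
      }
      # deletion entry from diagonal m+1
      v <- if (im < ndiag) V[im + 1L] else -1L
      if (v >= 0L) {
        v2 <- min(v + 1L, imax)
        if (v2 >= istart) cand <- max(cand, v2)
      }
      if (f == abs(delta) && m == 0L) cand <- max(cand, 0L)
      if (cand < istart) next
      old <- V[im]
      i <- cand
      if (i < imax) { # slide the match snake
        len <- imax - i
        mis <- which(ra[(i + 1L):(i + len)] != oa[(i + m + 1L):(i + m + len)])
        i <- if (length(mis)) i + mis[1L] - 1L else imax
      }
      if (i > old) {
        V[im] <- i
        if (record) {
          lo <- if (old < 0L) istart else old + 1L
          ii <- seq.int(lo, i)
          ii <- ii[ii >= 1L & ii + m >= 1L]
          if (length(ii)) {
            mm <- ii[ra[ii] == oa[ii + m]]
            if (length(mm)) {
              mi <- c(mi, mm)
              mj <- c(mj, mm + m)
              md <- c(md, rep.int(f - abs(delta - m), length(mm)))
            }
          }
        }
      }
    }
    fs <- c(fs, f)
    if (record) {
      act <- which(V >= 0L)
      ka <- act - noff
      va <- V[act]
      rows <- vapply(0:max(va), function(r) {
        ok <- va >= r & r + ka >= 0L
        if (any(ok)) r + max(ka[ok]) else NA_integer_
      }, integer(1))
      maxcol <- max(va + ka)
      cols <- vapply(0:maxcol, function(cl) {
        ii <- cl - ka
        ok <- ii >= 0L & va >= ii
        if (any(ok)) max(ii[ok]) else NA_integer_
      }, integer(1))
      waves[[length(waves) + 1L]] <- list(f = f, rows = rows, cols = cols)
    }
    if (V[delta + noff] >= nR) break
    if (f > nR + nO) {
      abort_varalg("wave expansion failed to reach the target element.",
                   "varalg_internal_error") # nocov
    }
    f <- f + 2L
  }

  list(distance = f, fs = fs, mi = mi, mj = mj, md = md, waves = waves,
       frontier_cells = ndiag)
}

#' Simple edit distance (deletions and insertions only)
#'
#' The Levenshtein distance without substitutions, weighing deletions and
#' insertions as 1 each. Computed by wave-based A* expansion (the f-value of
#' the target element), not by filling the full dynamic-programming matrix;
#' temporary space is linear in `nchar(a) + nchar(b)`.
#'
#' @param a,b Sequences (single strings; may be empty).
#' @return A non-negative integer; symmetric in its arguments and equal to
#'   `nchar(a) + nchar(b) - 2 * lcs_length(a, b)`.
#' @examples
#' edit_distance("CATATATCG", "CTTATAGCAT") # 7
#' edit_distance("CT", "TG")                # 2
#' @export
edit_distance <- function(a, b) {
  a <- check_sequence(a, "a")
  b <- check_sequence(b, "b")
  wave_core(a, b, record = FALSE)$distance
}

#' @rdname edit_distance
#' @export
lcs_length <- function(a, b) {
  a <- check_sequence(a, "a")
  b <- check_sequence(b, "b")
  (nchar(a) + nchar(b) - wave_core(a, b, record = FALSE)$distance) %/% 2L
}

#' Level of a match element in the LCS-graph
#'
#' The position in a longest common subsequence of the match at matrix
#' element `(i, j)` with simple-edit-distance value `d_ij`:
#' `floor((i + j - d_ij) / 2)`.
#'
#' @param i Reference index of the match (1-based; 0 for the virtual source).
#' @param j Observed index of the match.
#' @param d_ij Distance value of the element.
#' @return Integer level; the virtual source is level 0.
#' @export
node_level <- function(i, j, d_ij) {
  (as.integer(i) + as.integer(j) - as.integer(d_ij)) %/% 2L
}

#' Build the LCS-graph of all minimal alignments
#'
#' Constructs the directed acyclic graph whose nodes are the single-symbol
#' matches occurring in some longest common subsequence of `reference` and
#' `observed` (plus a virtual source and sink), and whose source-to-sink
#' paths spell exactly the minimal alignments. Matches are collected by
#' wave-based A* expansion with a per-diagonal frontier (temporary space
#' linear in the sequence lengths), levelled with [node_level()], connected
#' level-to-next-level where both coordinates strictly increase, and pruned
#' by a reachability sweep from source and sink so that every retained node
#' lies on at least one minimal alignment.
#'
#' @param reference,observed Sequences (single strings).
#' @return An `lcs_graph` object with components `distance`, `lcs_length`,
#'   `nodes` (coordinates and levels; source first, sink last), `edges`
#'   (node index pairs with gap labels), and `waves` (per-wave f-values with
#'   the rows/cols frontier arrays). See [tidy.lcs_graph()], [autoplot.lcs_graph()],
#'   [enumerate_minimal()] and [element_set()] for consumers.
#' @examples
#' g <- build_lcs_graph("ATTTA", "ATTA")
#' glance(g)
#' @export
build_lcs_graph <- function(reference, observed) {
  reference <- check_sequence(reference, "reference")
  observed <- check_sequence(observed, "observed")
  w <- wave_core(reference, observed, record = TRUE)
  nR <- nchar(reference)
  nO <- nchar(observed)
  d <- w$distance
  L <- (nR + nO - d) %/% 2L

  lev <- (w$mi + w$mj - w$md) %/% 2L
  ord <- order(lev, w$mi, w$mj, method = "radix")
  ni <- c(0L, w$mi[ord], nR + 1L)
  nj <- c(0L, w$mj[ord], nO + 1L)
  nl <- c(0L, lev[ord], L + 1L)
  nn <- length(ni)

  # edges between consecutive levels with strictly increasing coordinates
  by_level <- split(seq_len(nn), nl)
  ef <- integer(0); et <- integer(0)
  for (l in 0:L) {
    us <- by_level[[as.character(l)]]
    vs <- by_level[[as.character(l + 1L)]]
    if (is.null(us) || is.null(vs)) next
    for (u in us) {
      hit <- vs[ni[vs] > ni[u] & nj[vs] > nj[u]]
      if (length(hit)) {
        ef <- c(ef, rep.int(u, length(hit)))
        et <- c(et, hit)
      }
    }
  }

  # prune nodes not on any source-to-sink path
  fwd <- logical(nn); fwd[1L] <- TRUE
  for (l in 0:L) { # edges only go level l -> l+1, so one ascending pass
    sel <- nl[ef] == l & fwd[ef]
    fwd[et[sel]] <- TRUE
  }
  bwd <- logical(nn); bwd[nn] <- TRUE
  for (l in (L + 1L):1L) {
    sel <- nl[et] == l & bwd[et]
    bwd[ef[sel]] <- TRUE
  }
  keep <- fwd & bwd
  sel <- keep[ef] & keep[et]
  idx <- cumsum(keep)
  nodes <- list(i = ni[keep], j = nj[keep], level = nl[keep])
  edges <- list(from = idx[ef[sel]], to = idx[et[sel]])

  structure(
    list(
      reference = reference, observed = observed,
      distance = d, lcs_length = L,
      nodes = nodes, edges = edges,
      waves = w$waves, first_f = w$fs[1L], fs = w$fs,
      frontier_cells = w$frontier_cells
    ),
    class = "lcs_graph"
  )
}

#' @export
print.lcs_graph <- function(x, ...) {
  cat(sprintf(
    "<LCS-graph %s -> %s: distance %d, LCS length %d, %d nodes, %d edges>\n",
    x$reference, x$observed, x$distance, x$lcs_length,
    length(x$nodes$i), length(x$edges$from)
  ))
  invisible(x)
}

# Gap between two graph nodes: deleted reference run and inserted observed
# run, with the admissible insertion anchors i_u .. i_v - 1.
edge_gap <- function(graph, e) {
  u <- graph$edges$from[e]; v <- graph$edges$to[e]
  iu <- graph$nodes$i[u]; iv <- graph$nodes$i[v]
  ju <- graph$nodes$j[u]; jv <- graph$nodes$j[v]
  dels <- if (iv - iu > 1L) seq.int(iu + 1L, iv - 1L) else integer(0)
  ins <- if (jv - ju > 1L) {
    strsplit(substr(graph$observed, ju + 1L, jv - 1L), "")[[1]]
  } else character(0)
  list(dels = dels, ins = ins, anchors = seq.int(iu, iv - 1L))
}

# All non-decreasing anchor assignments of length m over `values`.
nondecreasing_tuples <- function(values, m) {
  if (m == 0L) return(list(integer(0)))
  out <- list()
  recurse <- function(prefix, start) {
    if (length(prefix) == m) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (t in start:length(values)) recurse(c(prefix, values[t]), t)
  }
  recurse(integer(0), 1L)
  out
}

count_representations <- function(graph) {
  nn <- length(graph$nodes$i)
  cnt <- numeric(nn)
  cnt[nn] <- 1
  ec <- vapply(seq_along(graph$edges$from), function(e) {
    u <- graph$edges$from[e]; v <- graph$edges$to[e]
    m <- graph$nodes$j[v] - graph$nodes$j[u] - 1L
    k <- graph$nodes$i[v] - graph$nodes$i[u] # number of admissible anchors
    if (m == 0L) 1 else choose(m + k - 1, m)
  }, numeric(1))
  for (u in order(graph$nodes$level, decreasing = TRUE)) {
    if (u == nn) next
    sel <- which(graph$edges$from == u)
    if (length(sel)) cnt[u] <- sum(ec[sel] * cnt[graph$edges$to[sel]])
  }
  cnt[1L]
}

#' Enumerate all minimal representations
#'
#' Materialises the full set of minimal representations transforming the
#' graph's reference into its observed sequence: one representation per
#' source-to-sink path and per monotone interleaving of each gap's deletions
#' and insertions (an inserted symbol may be anchored after any prefix of
#' the gap's deletions; anchors are non-decreasing across a gap's insertion
#' order). The number of representations is exponentially bounded, so a cap
#' guards against blowup — use [element_set()] when only the element set is
#' needed.
#'
#' @param graph An `lcs_graph` from [build_lcs_graph()].
#' @param cap Abort (with class `"varalg_cap_error"`) if the number of
#'   representations would exceed this.
#' @return A list of [variant_rep] tibbles; every one patches the reference
#'   to the observed sequence using the same number of deletions and of
#'   insertions.
#' @examples
#' length(enumerate_minimal(build_lcs_graph("ATTTA", "ATTA"))) # 3
#' @export
enumerate_minimal <- function(graph, cap = 10000L) {
  stopifnot(inherits(graph, "lcs_graph"))
  total <- count_representations(graph)
  if (total > cap) {
    abort_varalg(
      sprintf("number of minimal representations (%.0f) exceeds cap (%d)", total, cap),
      "varalg_cap_error"
    )
  }
  nn <- length(graph$nodes$i)
  out_edges <- split(seq_along(graph$edges$from), graph$edges$from)
  # gap options per edge: list of op tables (op, pos, symbol)
  gap_options <- lapply(seq_along(graph$edges$from), function(e) {
    gap <- edge_gap(graph, e)
    m <- length(gap$ins)
    lapply(nondecreasing_tuples(gap$anchors, m), function(anch) {
      list(
        op = c(rep.int("del", length(gap$dels)), rep.int("ins", m)),
        pos = c(gap$dels, anch),
        symbol = c(rep.int(NA_character_, length(gap$dels)), gap$ins)
      )
    })
  })
  suffix <- vector("list", nn)
  suffix_for <- function(u) {
    if (!is.null(suffix[[u]])) return(suffix[[u]])
    if (u == nn) {
      res <- list(list(op = character(0), pos = integer(0), symbol = character(0)))
    } else {
      res <- list()
      for (e in out_edges[[as.character(u)]]) {
        tails <- suffix_for(graph$edges$to[e])
        for (g in gap_options[[e]]) {
          for (tl in tails) {
            res[[length(res) + 1L]] <- list(
              op = c(g$op, tl$op), pos = c(g$pos, tl$pos),
              symbol = c(g$symbol, tl$symbol)
            )
          }
        }
      }
    }
    suffix[[u]] <<- res
    res
  }
  reps <- lapply(suffix_for(1L), function(r) new_variant_rep(r$op, r$pos, r$symbol))
  keys <- vapply(reps, function(r) paste(r$op, r$pos, r$symbol, collapse = "|"),
                 character(1))
  reps[!duplicated(keys)]
}

# Psi(R, O) as a character key multiset-free vector, straight from the
# pruned graph edges (no enumeration).
psi_keys <- function(graph) {
  keys <- character(0)
  for (e in seq_along(graph$edges$from)) {
    gap <- edge_gap(graph, e)
    if (length(gap$dels)) keys <- c(keys, paste0("d", gap$dels))
    if (length(gap$ins)) {
      syms <- unique(gap$ins)
      keys <- c(keys, paste0("i", rep(gap$anchors, each = length(syms)), ":", syms))
    }
  }
  unique(keys)
}

#' Element set of all minimal representations
#'
#' Computes the set of atomic-operation elements occurring in any
#' minimal representation, without enumerating the (exponentially many)
#' representations: each graph edge with gap deletions `a..b` and gap
#' insertions contributes deletion elements `a..b` and, for every gap
#' insertion symbol, insertion elements anchored anywhere in `[a-1, b]`.
#' The set size is at most quadratic in the sequence lengths.
#'
#' @param graph An `lcs_graph` from [build_lcs_graph()].
#' @return An `element_set` tibble with columns `op`, `pos`, `symbol`
#'   (deleted symbols annotated from the reference), one row per distinct
#'   element, sorted by position.
#' @examples
#' element_set(build_lcs_graph("CT", "TG"))
#' @export
element_set <- function(graph) {
  stopifnot(inherits(graph, "lcs_graph"))
  keys <- psi_keys(graph)
  del <- grepl("^d", keys)
  pos <- integer(length(keys))
  sym <- character(length(keys))
  pos[del] <- as.integer(sub("^d", "", keys[del]))
  refc <- strsplit(graph$reference, "")[[1]]
  sym[del] <- refc[pos[del]]
  insm <- regmatches(keys[!del], regexec("^i([0-9]+):(.)$", keys[!del]))
  pos[!del] <- vapply(insm, function(mm) as.integer(mm[2]), integer(1))
  sym[!del] <- vapply(insm, function(mm) mm[3], character(1))
  op <- ifelse(del, "del", "ins")
  ord <- order(pos, op == "ins", sym, method = "radix")
  structure(
    list(op = op[ord], pos = pos[ord], symbol = sym[ord]),
    class = c("element_set", "tbl_df", "tbl", "data.frame"),
    row.names = c(NA_integer_, -length(keys))
  )
}

#' Export an LCS-graph in Graphviz DOT format
#'
#' Nodes are labelled `(i,j)/level`; edges carry their gap description
#' (empty for consecutive matches).
#'
#' @param graph An `lcs_graph`.
#' @param path File to write; use `""` for stdout.
#' @return `path`, invisibly.
#' @export
write_dot <- function(graph, path = "") {
  stopifnot(inherits(graph, "lcs_graph"))
  n <- length(graph$nodes$i)
  lab <- sprintf("(%d,%d)/%d", graph$nodes$i, graph$nodes$j, graph$nodes$level)
  lab[1] <- "source"
  lab[n] <- "sink"
  elab <- vapply(seq_along(graph$edges$from), function(e) {
    gap <- edge_gap(graph, e)
    if (length(gap$dels) == 0L && length(gap$ins) == 0L) return("")
    rep <- new_variant_rep(
      c(rep.int("del", length(gap$dels)), rep.int("ins", length(gap$ins))),
      c(gap$dels, rep.int(max(c(gap$dels, gap$anchors[1])), length(gap$ins))),
      c(rep.int(NA_character_, length(gap$dels)), gap$ins)
    )
    format_variant(rep, reference = graph$reference)
  }, character(1))
  lines <- c(
    "digraph lcs_graph {",
    "  rankdir=LR;",
    sprintf("  n%d [label=\"%s\"];", seq_len(n), lab),
    sprintf("  n%d -> n%d [label=\"%s\"];",
            graph$edges$from, graph$edges$to, elab),
    "}"
  )
  if (identical(path, "")) cat(lines, sep = "\n") else writeLines(lines, path)
  invisible(path)
}
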