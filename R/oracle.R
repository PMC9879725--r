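# Brute-force oracle: full dynamic-programming matrix, exhaustive path
# enumeration, and literal evaluation of the relation definitions. Used as
# the independent validation surface for the wave/LCS-graph algorithms; the
# oracle is deliberately naive (quadratic space, exponential enumeration
# behind explicit guards).

#' Full simple-edit-distance matrix
#'
#' Fills the complete (quadratic-space) dynamic-programming matrix of the
#' simple edit distance recurrence: `D(i,0) = i`, `D(0,j) = j`,
#' `D(i,j) = D(i-1,j-1)` on a match and
#' `min(D(i-1,j), D(i,j-1)) + 1` otherwise. Intended for small inputs as an
#' independent check of [edit_distance()] and [build_lcs_graph()].
#'
#' @param a,b Sequences (single strings).
#' @param size_guard Refuse inputs longer than this (quadratic space by design).
#' @return A `dp_matrix`: list with `D` (the `(nchar(a)+1) x (nchar(b)+1)`
#'   matrix) and the two sequences.
#' @examples
#' m <- dp_full_matrix("CATATATCG", "CTTATAGCAT")
#' m$D[10, 11] # bottom-right element: 7
#' @export
dp_full_matrix <- function(a, b, size_guard = 64L) {
  a <- check_sequence(a, "a")
  b <- check_sequence(b, "b")
  n <- nchar(a)
  m <- nchar(b)
  if (n > size_guard || m > size_guard) {
    abort_varalg(sprintf("sequence longer than size guard (%d)", size_guard),
                 "varalg_cap_error")
  }
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0:n
  D[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- if (ac[i] == bc[j]) D[i, j] else
        min(D[i, j + 1L], D[i + 1L, j]) + 1L
    }
  }
  structure(list(D = D, a = a, b = b), class = "dp_matrix")
}

#' Exhaustively enumerate minimal representations from the full matrix
#'
#' Backtraces every minimal path from the bottom-right to the top-left
#' element of a [dp_full_matrix()]: vertical steps are deletions, horizontal
#' steps insertions (anchored at the current reference position), diagonal
#' steps are matches. The complete set of minimal representations is
#' returned; the interleaving of each gap's deletions and insertions is
#' enumerated by construction.
#'
#' @param matrix A `dp_matrix`.
#' @param cap Abort (class `"varalg_cap_error"`) if the number of backtrace
#'   paths exceeds this.
#' @return A list of [variant_rep] tibbles.
#' @examples
#' length(enumerate_paths(dp_full_matrix("ATTTA", "ATTA"))) # 3
#' @export
enumerate_paths <- function(matrix, cap = 100000L) {
  stopifnot(inherits(matrix, "dp_matrix"))
  D <- matrix$D
  n <- nchar(matrix$a)
  m <- nchar(matrix$b)
  ac <- strsplit(matrix$a, "")[[1]]
  bc <- strsplit(matrix$b, "")[[1]]
  # path-count guard
  C <- base::matrix(0, n + 1L, m + 1L)
  C[1L, 1L] <- 1
  for (i in 0:n) {
    for (j in 0:m) {
      if (i == 0L && j == 0L) next
      tot <- 0
      if (i > 0L && j > 0L && ac[i] == bc[j]) tot <- tot + C[i, j]
      if (i > 0L && D[i, j + 1L] + 1L == D[i + 1L, j + 1L]) tot <- tot + C[i, j + 1L]
      if (j > 0L && D[i + 1L, j] + 1L == D[i + 1L, j + 1L]) tot <- tot + C[i + 1L, j]
      C[i + 1L, j + 1L] <- tot
    }
  }
  if (C[n + 1L, m + 1L] > cap) {
    abort_varalg(sprintf("number of backtrace paths (%.0f) exceeds cap (%d)",
                         C[n + 1L, m + 1L], cap), "varalg_cap_error")
  }
  memo <- vector("list", (n + 1L) * (m + 1L))
  prefix_for <- function(i, j) {
    id <- i * (m + 1L) + j + 1L
    if (!is.null(memo[[id]])) return(memo[[id]])
    res <- if (i == 0L && j == 0L) {
      list(list(op = character(0), pos = integer(0), symbol = character(0)))
    } else {
      acc <- list()
      if (i > 0L && j > 0L && ac[i] == bc[j]) {
        acc <- c(acc, prefix_for(i - 1L, j - 1L))
      }
      if (i > 0L && D[i, j + 1L] + 1L == D[i + 1L, j + 1L]) {
        acc <- c(acc, lapply(prefix_for(i - 1L, j), function(pp) {
          list(op = c(pp$op, "del"), pos = c(pp$pos, i),
               symbol = c(pp$symbol, ac[i]))
        }))
      }
      if (j > 0L && D[i + 1L, j] + 1L == D[i + 1L, j + 1L]) {
        acc <- c(acc, lapply(prefix_for(i, j - 1L), function(pp) {
          list(op = c(pp$op, "ins"), pos = c(pp$pos, i),
               symbol = c(pp$symbol, bc[j]))
        }))
      }
      acc
    }
    memo[[id]] <<- res
    res
  }
  reps <- lapply(prefix_for(n, m), function(r) new_variant_rep(r$op, r$pos, r$symbol))
  keys <- vapply(reps, function(r) paste(r$op, r$pos, r$symbol, collapse = "|"),
                 character(1))
  reps[!duplicated(keys)]
}

#' Relation between two variants by literal evaluation of the definitions
#'
#' Evaluates the five-way classification directly from the definitions, by
#' exhaustive enumeration of both variants' minimal representations:
#' equivalent iff the observed sequences are equal; one variant contains the
#' other iff some minimal representation of the one is a proper
#' sub-multiset of some minimal representation of the other; overlap iff
#' some pair of minimal representations shares at least one element and
#' neither containment holds; disjoint otherwise. Intended for small inputs
#' as the independent oracle for [compare_variants()].
#'
#' @param reference Reference sequence (non-empty).
#' @param o,p Observed sequences of the two variants.
#' @param cap Backtrace path cap, passed to [enumerate_paths()].
#' @return One of the five relation names.
#' @examples
#' relation_by_definition("CT", "TG", "GC") # disjoint
#' @export
relation_by_definition <- function(reference, o, p, cap = 100000L) {
  reference <- check_sequence(reference, "reference", allow_empty = FALSE)
  o <- check_sequence(o, "o")
  p <- check_sequence(p, "p")
  if (o == reference || p == reference) {
    abort_varalg(
      "relations are defined for non-empty variants only (observed equals reference).",
      "varalg_empty_variant_error"
    )
  }
  if (o == p) return("equivalent")
  reps_o <- enumerate_paths(dp_full_matrix(reference, o), cap)
  reps_p <- enumerate_paths(dp_full_matrix(reference, p), cap)
  phi_o <- lapply(reps_o, rep_structure)
  phi_p <- lapply(reps_p, rep_structure)
  contains <- function(big_set, small_set) {
    # sizes within each Phi are constant, so a proper sub-representation
    # needs strictly fewer elements
    if (small_set[[1]]$size >= big_set[[1]]$size) return(FALSE)
    for (sm in small_set) {
      for (bg in big_set) {
        if (is_proper_subrep(sm, bg)) return(TRUE)
      }
    }
    FALSE
  }
  if (contains(phi_o, phi_p)) return("contains")
  if (contains(phi_p, phi_o)) return("is_contained")
  # an element shared by the unions is shared by some representation pair
  keys_o <- unique(unlist(lapply(reps_o, rep_element_keys)))
  keys_p <- unique(unlist(lapply(reps_p, rep_element_keys)))
  if (any(keys_o %in% keys_p)) return("overlap")
  "disjoint"
}

random_reference <- function(ref_length, alphabet) {
  out <- character(0)
  total <- 0L
  while (total < ref_length) {
    unit <- switch(sample(c("homopolymer", "str", "random"), 1L,
                          prob = c(0.35, 0.35, 0.3)),
      homopolymer = rep(sample(alphabet, 1L), sample(2:6, 1L)),
      str = rep(sample(alphabet, sample(1:3, 1L), replace = TRUE), sample(2:4, 1L)),
      random = sample(alphabet, sample(1:4, 1L), replace = TRUE)
    )
    out <- c(out, unit)
    total <- length(out)
  }
  paste(out[seq_len(ref_length)], collapse = "")
}

random_rep_ops <- function(n, op_count, alphabet) {
  pool <- seq_len(n) # reference positions still available for deletion
  op <- character(0); pos <- integer(0); sym <- character(0)
  for (t in seq_len(op_count)) {
    kind <- if (length(pool) == 0L) "ins" else sample(c("del", "ins", "snv"), 1L)
    if (kind == "ins") {
      k <- sample(1:3, 1L)
      anchor <- sample(0:n, 1L)
      op <- c(op, rep.int("ins", k))
      pos <- c(pos, rep.int(anchor, k))
      sym <- c(sym, sample(alphabet, k, replace = TRUE))
    } else if (kind == "snv") {
      at <- pool[sample.int(length(pool), 1L)]
      pool <- setdiff(pool, at)
      op <- c(op, "del", "ins")
      pos <- c(pos, at, at)
      sym <- c(sym, NA_character_, sample(alphabet, 1L))
    } else {
      at <- pool[sample.int(length(pool), 1L)]
      run <- at
      len <- sample(1:3, 1L)
      while (length(run) < len && (run[length(run)] + 1L) %in% pool) {
        run <- c(run, run[length(run)] + 1L)
      }
      pool <- setdiff(pool, run)
      op <- c(op, rep.int("del", length(run)))
      pos <- c(pos, run)
      sym <- c(sym, rep.int(NA_character_, length(run)))
    }
  }
  new_variant_rep(op, pos, sym)
}

#' Seeded random comparison cases
#'
#' Deterministic fixture generator for property testing: builds a
#' repeat-rich reference (homopolymer runs and short tandem repeats
#' interleaved with random stretches — the structures that maximise
#' co-optimal alignment ambiguity) and random variants composed of deletion
#' runs, insertions and SNVs on it. Every generated variant patches cleanly
#' and, for `op_count > 0`, changes the reference.
#'
#' @param seed Integer seed; the same seed reproduces the same case.
#' @param ref_length Reference length (default 24).
#' @param alphabet Symbol set (default DNA).
#' @param op_count Operations per variant (0 gives empty variants, useful
#'   for empty-variant error tests).
#' @param n_variants Number of variants to generate (default 4).
#' @return A list with `reference` (string), `variants` (list of
#'   [variant_rep]) and `seed`.
#' @examples
#' case <- random_case(1, ref_length = 10, alphabet = c("A", "T"), op_count = 2)
#' patch(case$reference, case$variants[[1]])
#' @export
random_case <- function(seed, ref_length = 24L, alphabet = c("A", "C", "G", "T"),
                        op_count = 3L, n_variants = 4L) {
  stopifnot(ref_length > 0L, length(alphabet) > 0L, op_count >= 0L, n_variants >= 1L)
  withr::with_seed(as.integer(seed), {
    reference <- random_reference(as.integer(ref_length), toupper(alphabet))
    n <- nchar(reference)
    variants <- vector("list", n_variants)
    for (v in seq_len(n_variants)) {
      if (op_count == 0L) {
        variants[[v]] <- new_variant_rep()
        next
      }
      for (try in 1:25) {
        cand <- random_rep_ops(n, as.integer(op_count), toupper(alphabet))
        if (patch(reference, cand) != reference) break
        cand <- NULL
      }
      if (is.null(cand)) { # nocov start
        abort_varalg("failed to generate a non-empty variant.", "varalg_internal_error")
      } # nocov end
      variants[[v]] <- cand
    }
    list(reference = reference, variants = variants, seed = as.integer(seed))
  })
}
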