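test_that("edit_distance matches the worked examples and boundaries", {
  expect_identical(edit_distance("CATATATCG", "CTTATAGCAT"), 7L)
  expect_identical(edit_distance("CT", "TG"), 2L)
  expect_identical(edit_distance("ATTTA", "ATTA"), 1L)
  expect_identical(edit_distance("ACGTACGT", "ACGTACGT"), 0L)
  expect_identical(edit_distance("", "ACGT"), 4L)
  expect_identical(edit_distance("ACGT", ""), 4L)
  expect_identical(edit_distance("", ""), 0L)
})

test_that("lcs_length satisfies the distance/LCS duality", {
  expect_identical(lcs_length("CATATATCG", "CTTATAGCAT"), 6L)
  expect_identical(lcs_length("ACGTT", "ACGTT"), 5L)
  expect_identical(lcs_length("AAA", "TTT"), 0L)
})

test_that("node_level places matches in the LCS", {
  expect_identical(node_level(1, 1, 0), 1L)
  expect_identical(node_level(7, 10, 5), 6L) # final T match of the 9x10 example
  expect_identical(node_level(0, 0, 0), 0L)
})

test_that("LCS-graph captures single-path, multi-path and identity cases", {
  g <- build_lcs_graph("CT", "TG")
  expect_identical(g$distance, 2L)
  nodes <- tidy(g, "nodes")
  expect_identical(nrow(nodes), 3L) # source, the shared T, sink
  expect_identical(nodes$i[nodes$kind == "match"], 2L)
  expect_identical(nodes$j[nodes$kind == "match"], 1L)
  reps <- enumerate_minimal(g)
  expect_length(reps, 1L)
  expect_identical(format_variant(reps[[1]], reference = "CT"), "[1delC;2_3insG]")

  expect_length(enumerate_minimal(build_lcs_graph("ATTTA", "ATTA")), 3L)

  g <- build_lcs_graph("ACGT", "ACGT")
  expect_identical(g$distance, 0L)
  expect_identical(length(g$nodes$i), 6L) # chain of 4 matches plus source/sink
  reps <- enumerate_minimal(g)
  expect_length(reps, 1L)
  expect_identical(nrow(reps[[1]]), 0L)
})

test_that("wave f-values start at the length difference and step by 2", {
  g <- build_lcs_graph("CATATATCG", "CTTATAGCAT")
  expect_identical(g$first_f, 1L)
  expect_identical(g$fs, c(1L, 3L, 5L, 7L))
  expect_identical(g$fs[length(g$fs)], g$distance)
  # frontier arrays after the first wave
  expect_identical(g$waves[[1]]$rows, c(1L, 2L))
  expect_identical(g$waves[[1]]$cols, c(0L, 1L, 1L))
  for (seed in 1:20) {
    case <- random_case(seed, ref_length = 12, op_count = 3, n_variants = 1)
    o <- patch(case$reference, case$variants[[1]])
    g <- build_lcs_graph(case$reference, o)
    expect_identical(g$first_f, abs(nchar(o) - nchar(case$reference)))
    expect_true(all(diff(g$fs) == 2L))
    expect_identical(g$fs[length(g$fs)], g$distance)
  }
})

test_that("enumerated representations reproduce the published sets", {
  reps <- enumerate_minimal(build_lcs_graph("GCTTT", "AGCTT"))
  expect_setequal(
    vapply(reps, format_variant, character(1)),
    c("[0_1insA;3del]", "[0_1insA;4del]", "[0_1insA;5del]")
  )
  expect_length(enumerate_minimal(build_lcs_graph("TTTTTT", "TTTTT")), 6L)
})

test_that("enumeration cap converts blowup into a clean error", {
  g <- build_lcs_graph("AAAAAAAAAA", "AAAAA") # choose(10, 5) = 252 representations
  expect_error(enumerate_minimal(g, cap = 100L), class = "varalg_cap_error")
  expect_length(enumerate_minimal(g, cap = 300L), 252L)
})

test_that("element sets match the published Psi sets", {
  es <- element_set(build_lcs_graph("CT", "TG"))
  expect_equal(es$op, c("del", "ins"))
  expect_equal(es$pos, c(1L, 2L))
  expect_equal(es$symbol, c("C", "G"))

  es <- element_set(build_lcs_graph("CT", "GC"))
  expect_equal(es$op, c("ins", "del"))
  expect_equal(es$pos, c(0L, 2L))
  expect_equal(es$symbol, c("G", "T"))

  expect_identical(nrow(element_set(build_lcs_graph("ACGT", "ACGT"))), 0L)

  es <- element_set(build_lcs_graph("GCTTT", "AGCTT"))
  expect_equal(paste(es$op, es$pos), c("ins 0", "del 3", "del 4", "del 5"))
})

test_that("wave algorithm agrees with the full-matrix oracle (exhaustive small + random)", {
  strs <- all_strings(4, c("A", "C", "T"))
  for (a in strs) {
    for (b in strs) {
      expect_identical(edit_distance(a, b), dp_full_matrix(a, b)$D[nchar(a) + 1L, nchar(b) + 1L],
                       label = sprintf("d(%s,%s)", a, b))
    }
  }
  set.seed(20240901)
  alpha <- c("A", "C", "G", "T")
  for (t in 1:120) {
    a <- paste(sample(alpha, sample(0:12, 1), TRUE), collapse = "")
    b <- paste(sample(alpha, sample(0:12, 1), TRUE), collapse = "")
    m <- dp_full_matrix(a, b)
    g <- build_lcs_graph(a, b)
    expect_identical(g$distance, m$D[nchar(a) + 1L, nchar(b) + 1L])
    expect_identical(rep_key_set(enumerate_minimal(g, cap = 1e5)),
                     rep_key_set(enumerate_paths(m, cap = 1e5)),
                     label = sprintf("Phi(%s,%s)", a, b))
    expect_setequal(
      varalgebra:::psi_keys(g),
      unique(unlist(lapply(enumerate_paths(m, cap = 1e5),
                           varalgebra:::rep_element_keys)))
    )
  }
})

test_that("every enumerated representation patches R to O with |rep| = d(R,O)", {
  set.seed(7)
  alpha <- c("A", "C", "G")
  for (t in 1:40) {
    a <- paste(sample(alpha, sample(1:9, 1), TRUE), collapse = "")
    b <- paste(sample(alpha, sample(0:9, 1), TRUE), collapse = "")
    g <- build_lcs_graph(a, b)
    reps <- enumerate_minimal(g, cap = 1e5)
    dels <- unique(vapply(reps, function(r) sum(r$op == "del"), integer(1)))
    inss <- unique(vapply(reps, function(r) sum(r$op == "ins"), integer(1)))
    expect_length(dels, 1L) # same deletion count in every minimal representation
    expect_length(inss, 1L)
    for (r in reps) {
      expect_identical(patch(a, r), b)
      expect_identical(nrow(r), g$distance)
    }
  }
})

test_that("graph is sound: all nodes on source-sink paths, gaps reconstruct O", {
  set.seed(99)
  for (t in 1:30) {
    a <- paste(sample(c("A", "T"), sample(1:8, 1), TRUE), collapse = "")
    b <- paste(sample(c("A", "T"), sample(1:8, 1), TRUE), collapse = "")
    g <- build_lcs_graph(a, b)
    nn <- length(g$nodes$i)
    # recompute reachability independently over the stored edges
    fwd <- logical(nn); fwd[1] <- TRUE
    for (l in sort(unique(g$nodes$level))) {
      sel <- g$nodes$level[g$edges$from] == l & fwd[g$edges$from]
      fwd[g$edges$to[sel]] <- TRUE
    }
    bwd <- logical(nn); bwd[nn] <- TRUE
    for (l in sort(unique(g$nodes$level), decreasing = TRUE)) {
      sel <- g$nodes$level[g$edges$to] == l & bwd[g$edges$to]
      bwd[g$edges$from[sel]] <- TRUE
    }
    expect_true(all(fwd & bwd))
    # every retained match node is a real match
    mid <- setdiff(seq_len(nn), c(1L, nn))
    expect_true(all(substr(a, g$nodes$i[mid], g$nodes$i[mid]) ==
                      substr(b, g$nodes$j[mid], g$nodes$j[mid])))
    # walking any path: matched symbols plus gap insertions spell O
    edges <- tidy(g, "edges")
    path <- 1L
    spelled <- ""
    while (path != nn) {
      e <- which(g$edges$from == path)[1]
      gap <- varalgebra:::edge_gap(g, e)
      nxt <- g$edges$to[e]
      spelled <- paste0(spelled, paste(gap$ins, collapse = ""),
                        if (nxt != nn) substr(b, g$nodes$j[nxt], g$nodes$j[nxt]) else "")
      path <- nxt
    }
    expect_identical(spelled, b)
  }
})

test_that("construction keeps only linear frontier storage", {
  g <- build_lcs_graph("CATATATCG", "CTTATAGCAT")
  n <- nchar(g$reference) + nchar(g$observed)
  expect_lte(g$frontier_cells, n + 1L)
  for (w in g$waves) {
    expect_lte(length(w$rows), nchar(g$reference) + 1L)
    expect_lte(length(w$cols), nchar(g$observed) + 1L)
  }
})
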