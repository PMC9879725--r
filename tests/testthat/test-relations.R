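test_that("the five relations reproduce the published examples", {
  expect_identical(compare_variants("TTTTTT", "1delT", "6delT"), "equivalent")
  expect_identical(compare_variants("TTTTTT", "2_5delinsGGG", "3T>G"), "contains")
  expect_identical(compare_variants("TTTTTT", "3T>G", "2_5delinsGGG"), "is_contained")
  expect_identical(compare_variants("TTTTTT", "2_4delinsGG", "3T>A"), "overlap")
  expect_identical(compare_variants("TTTTTT", "2_3insA", "4_5insA"), "disjoint")
  # disjoint despite all pairwise distances being equal: needs the Psi fallback
  expect_identical(compare_variants("CT", observed("TG"), observed("GC")), "disjoint")
  # non-minimal representations are minimised as part of the procedure
  expect_identical(
    compare_variants("GCTTT", "[1G>A;2C>G;3T>C]", "[1G>A;2C>G]"),
    "overlap"
  )
  expect_identical(compare_variants("CACAT", "3C>T", "2_3insT"), "contains")
  expect_identical(compare_variants("CACAT", "3C>T", "3_4insT"), "contains")
})

test_that("variants may be given as representations, descriptions or sequences", {
  rep <- parse_variant("2_5delinsGGG", 6)
  expect_identical(compare_variants("TTTTTT", rep, "3T>G"), "contains")
  expect_identical(compare_variants("TTTTTT", "seq:TGGGT", "3T>G"), "contains")
  expect_identical(compare_variants("TTTTTT", observed("TGGGT"), "3T>G"), "contains")
  expect_error(compare_variants("TTTTTT", 42, "3T>G"), class = "varalg_type_error")
})

test_that("empty variants are rejected rather than silently classified", {
  expect_error(compare_variants("TTTTTT", variant_rep(), "3T>G"),
               class = "varalg_empty_variant_error")
  # deletion + reinsertion of the same symbol patches back to the reference
  expect_error(compare_variants("TTTTTT", "3T>T", "2_3insA"),
               class = "varalg_empty_variant_error")
  expect_error(relation_by_definition("TTTTTT", "TTTTTT", "TTATTT"),
               class = "varalg_empty_variant_error")
})

test_that("relation properties follow the published table", {
  tbl <- relation_properties()
  expect_identical(nrow(tbl), 5L)
  eq <- relation_properties("equivalent")
  expect_identical(unlist(eq[, c("symmetry", "reflexivity", "transitivity")],
                          use.names = FALSE),
                   c("symmetric", "reflexive", "transitive"))
  co <- relation_properties("contains")
  expect_identical(unlist(co[, c("symmetry", "reflexivity", "transitivity")],
                          use.names = FALSE),
                   c("asymmetric", "irreflexive", "transitive"))
  expect_identical(co$converse, "is_contained")
  ov <- relation_properties("overlap")
  expect_identical(unlist(ov[, c("symmetry", "reflexivity", "transitivity")],
                          use.names = FALSE),
                   c("symmetric", "irreflexive", "intransitive"))
  expect_error(relation_properties("touches"), class = "varalg_type_error")
})

test_that("argument swap maps each relation onto its converse", {
  conv <- c(equivalent = "equivalent", contains = "is_contained",
            is_contained = "contains", overlap = "overlap", disjoint = "disjoint")
  seen <- character(0)
  for (seed in 1:40) {
    case <- random_case(seed, ref_length = 14, op_count = 2, n_variants = 2)
    o <- lapply(case$variants, function(v) observed(patch(case$reference, v)))
    r <- compare_variants(case$reference, o[[1]], o[[2]])
    expect_identical(compare_variants(case$reference, o[[2]], o[[1]]),
                     unname(conv[r]))
    seen <- union(seen, r)
  }
  # plus one deterministic pair per relation
  fixed <- list(
    list("TTTTTT", "1delT", "6delT"),
    list("TTTTTT", "2_5delinsGGG", "3T>G"),
    list("TTTTTT", "3T>G", "2_5delinsGGG"),
    list("TTTTTT", "2_4delinsGG", "3T>A"),
    list("TTTTTT", "2_3insA", "4_5insA")
  )
  for (fx in fixed) {
    r <- compare_variants(fx[[1]], fx[[2]], fx[[3]])
    expect_identical(compare_variants(fx[[1]], fx[[3]], fx[[2]]), unname(conv[r]))
    seen <- union(seen, r)
  }
  expect_setequal(seen, names(conv)) # all five relations exercised
})

test_that("compare agrees with the definition-based oracle on an exhaustive mini-domain", {
  refs <- all_strings(3, c("A", "C"), min_len = 1L)
  obs_all <- all_strings(4, c("A", "C"))
  mismatches <- 0L
  fastpath_checked <- 0L
  for (R in refs) {
    ov <- setdiff(obs_all, R)
    cache <- lapply(ov, function(o) oracle_variant_cache(R, o))
    dR <- vapply(ov, function(o) edit_distance(R, o), integer(1))
    for (x in seq_along(ov)) {
      for (y in seq_len(x)) {
        got <- compare_variants(R, observed(ov[x]), observed(ov[y]))
        want <- oracle_relation_cached(cache[[x]], cache[[y]])
        if (!identical(got, want)) mismatches <- mismatches + 1L
        # whenever a distance fast path fires, the oracle must agree
        dOP <- edit_distance(ov[x], ov[y])
        if (dR[x] - dR[y] == dOP || dR[y] - dR[x] == dOP || dR[x] + dR[y] == dOP) {
          fastpath_checked <- fastpath_checked + 1L
        }
      }
    }
  }
  expect_identical(mismatches, 0L)
  expect_gt(fastpath_checked, 1000L)
})

test_that("containment is transitive and equivalence is an equivalence relation", {
  set.seed(5)
  for (t in 1:30) {
    case <- random_case(t + 500L, ref_length = 20, op_count = 1, n_variants = 1)
    R <- case$reference
    n <- nchar(R)
    # nested deletion spans give a containment chain big > mid > small
    s <- sample(2:(n - 7), 1)
    big <- observed(patch(R, parse_variant(sprintf("%d_%ddel", s, s + 5), n)))
    mid <- observed(patch(R, parse_variant(sprintf("%d_%ddel", s + 1, s + 4), n)))
    small <- observed(patch(R, parse_variant(sprintf("%d_%ddel", s + 2, s + 3), n)))
    if (unclass(big) == R || unclass(mid) == R || unclass(small) == R) next
    r1 <- compare_variants(R, big, mid)
    r2 <- compare_variants(R, mid, small)
    if (r1 == "contains" && r2 == "contains") {
      expect_identical(compare_variants(R, big, small), "contains")
    }
    expect_identical(compare_variants(R, big, big), "equivalent")
  }
})
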