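test_that("method 1 splits top-down by concept probability", {
  bin <- generate_taxonomy(fixture_spec(seed = 1, n_concepts = 15,
                                        branching = c(2, 2)))
  fs <- method1_static(bin, max_features = 4)
  expect_equal(n_features(fs), 4L)
  expect_equal(unname(fs$features$depth), rep(2, 4))   # the four depth-2 nodes

  expect_equal(method1_static(bin, max_features = 1)$features$id, bin$root)

  # on chains a split never enlarges the frontier: descend to the leaf
  chain <- load_obo(obo_fixture(c("GO:0000001",
                                  "GO:0000002 is_a GO:0000001",
                                  "GO:0000003 is_a GO:0000002")), "GO")
  expect_equal(method1_static(chain, max_features = 2)$features$id,
               "GO:0000003")
})

test_that("method 2 only visits concepts with positive entity frequency", {
  bin <- generate_taxonomy(fixture_spec(seed = 1, n_concepts = 15,
                                        branching = c(2, 2)))
  left <- bin$children[[bin$root]][1]
  leaves_left <- intersect(descendants(bin, left), bin$ids[bin$depth == 3])
  idx <- idx_from_counts(bin, setNames(rep(1L, 4), leaves_left))
  fs <- method2_topdown(bin, idx, max_features = 6)
  expect_true(all(fs$features$id %in% descendants(bin, left)))
  expect_true(all(fs$features$ef > 0))

  # a single annotated concept is the only possible feature
  one <- idx_from_counts(bin, c(setNames(3L, leaves_left[1])))
  expect_equal(method2_topdown(bin, one, max_features = 15)$features$id,
               leaves_left[1])

  # uniform annotations on all four leaves of a depth-2 perfect tree
  small <- generate_taxonomy(fixture_spec(seed = 1, n_concepts = 7,
                                          branching = c(2, 2)))
  leaves <- small$ids[small$depth == 2]
  uni <- idx_from_counts(small, setNames(rep(2L, 4), leaves))
  expect_setequal(method2_topdown(small, uni, max_features = 4)$features$id,
                  leaves)
})

test_that("method 3 merges bottom-up and matches the spec examples", {
  tax <- tiny_tax()
  sib <- idx_from_counts(tax, c("GO:0000003" = 1L, "GO:0000004" = 1L))
  # identity when the annotated concepts fit the budget
  expect_setequal(method3_bottomup(tax, sib, max_features = 5)$features$id,
                  c("GO:0000003", "GO:0000004"))
  # two annotated siblings merge into their parent under budget 1
  expect_equal(method3_bottomup(tax, sib, max_features = 1)$features$id,
               "GO:0000002")
})

test_that("score_T multiplies information content and aggregated EF", {
  tax <- tiny_tax()   # N = 4: ic(GO:2) = -log2(3/4), ic(leaf) = 2
  idx <- idx_from_counts(tax, c("GO:0000003" = 5L, "GO:0000004" = 1L))
  expect_equal(score_T(tax, idx, tax$root), 0)           # IC(root) = 0
  expect_equal(score_T(tax, idx, "GO:0000003"), 2 * 5)
  expect_equal(score_T(tax, idx, "GO:0000004"), 2 * 1)
  none <- idx_from_counts(tax, c("GO:0000003" = 1L))
  expect_equal(score_T(tax, none, "GO:0000004"), 0)      # EF = 0
})

test_that("method 4 groups by score: heavy concepts stay, light ones merge up", {
  tax <- tiny_tax()
  idx <- idx_from_counts(tax, c("GO:0000003" = 5L, "GO:0000004" = 1L))
  fs <- method4_scored(tax, idx, max_features = 15)
  # score(GO:3) = 10 beats its parent (2.49); for GO:4 the parent wins
  expect_setequal(fs$features$id, c("GO:0000003", "GO:0000002"))

  # a single deeply annotated concept represents itself: EF is constant up
  # the chain while IC strictly decreases
  chain <- load_obo(obo_fixture(c("GO:0000001",
                                  "GO:0000002 is_a GO:0000001",
                                  "GO:0000003 is_a GO:0000002")), "GO")
  cidx <- idx_from_counts(chain, c("GO:0000003" = 4L))
  expect_equal(method4_scored(chain, cidx)$features$id, "GO:0000003")
})

test_that("empty corpora yield empty feature sets with a warning", {
  tax <- tiny_tax()
  empty <- idx_from_counts(tax, integer())
  for (m in 2:4) {
    expect_warning(fs <- extract_features(tax, empty, method = m),
                   "no resolved annotations")
    expect_equal(n_features(fs), 0L)
  }
})

test_that("extraction respects the budget and is deterministic", {
  spec <- fixture_spec(seed = 31, n_concepts = 120, n_models = 8)
  tax <- generate_taxonomy(spec)
  idx <- build_corpus_index(generate_corpus(spec, tax), tax)
  for (m in 1:4) {
    for (budget in c(1, 5, 15)) {
      a <- extract_features(tax, idx, m, budget)
      b <- extract_features(tax, idx, m, budget)
      expect_lte(n_features(a), budget)
      expect_identical(a$features, b$features)
      if (m > 1) expect_true(all(a$features$ef > 0))
    }
  }
  expect_error(extract_features(tax, idx, method = 5), "method")
  expect_error(extract_features(tax, idx, 2, max_features = 0), "max_features")
  expect_error(extract_features(tax, NULL, 2), "require a corpus index")
})

test_that("method 1 is corpus-independent, methods 2-4 depend on the corpus", {
  tax <- generate_taxonomy(fixture_spec(seed = 8, n_concepts = 60))
  f1 <- method1_static(tax, 8)
  idx_a <- idx_from_counts(tax, setNames(2L, tax$ids[tax$depth == 2][1]))
  idx_b <- idx_from_counts(tax, setNames(2L, rev(tax$ids[tax$depth == 2])[1]))
  expect_identical(method1_static(tax, 8)$features, f1$features)
  expect_false(identical(method2_topdown(tax, idx_a, 8)$features$id,
                         method2_topdown(tax, idx_b, 8)$features$id))
})

test_that("top-down and bottom-up extraction coincide on seeded corpora", {
  same <- tied <- logical(30)
  for (s in 1:30) {
    spec <- fixture_spec(seed = s, n_concepts = 100, n_models = 8)
    tax <- generate_taxonomy(spec)
    idx <- build_corpus_index(generate_corpus(spec, tax), tax)
    f2 <- method2_topdown(tax, idx)
    f3 <- method3_bottomup(tax, idx)
    tied[s] <- f2$tie_detected || f3$tie_detected
    same[s] <- identical(f2$features$id, f3$features$id)
  }
  # tie-free corpora must coincide exactly; divergence may only occur on
  # corpora where an ep tie was flagged
  expect_true(all(same[!tied]))
  expect_true(all(tied[!same]))
  expect_gt(sum(same), 25)
})

test_that("every annotated concept descends from a feature (coverage)", {
  for (s in c(2, 9, 17)) {
    spec <- fixture_spec(seed = s, n_concepts = 150, n_models = 10)
    tax <- generate_taxonomy(spec)
    idx <- build_corpus_index(generate_corpus(spec, tax), tax)
    annotated <- names(idx$direct)[idx$direct > 0]
    for (m in 2:4) {
      fs <- extract_features(tax, idx, m, max_features = 15)
      if (m == 4 && fs$truncated) next   # coverage asserted pre-truncation
      covered <- unique(unlist(lapply(fs$features$id, descendants, t = tax)))
      expect_true(all(annotated %in% covered),
                  label = sprintf("seed %d method %d coverage", s, m))
    }
  }
})
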