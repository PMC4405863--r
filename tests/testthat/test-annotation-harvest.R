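test_that("normalize_identifier handles both URI dialects and odd input", {
  x <- normalize_identifier(c(
    "http://identifiers.org/chebi/CHEBI:4167",
    "urn:miriam:obo.go:GO%3A0051234",
    "http://identifiers.org/uniprot/P04637",
    "https://identifiers.org/CHEBI:17234",
    "urn:miriam:biomodels.sbo:SBO%3A0000252",
    "not a uri at all"))
  expect_equal(x$ontology, c("CHEBI", "GO", "other", "CHEBI", "SBO", "other"))
  expect_equal(x$concept_id[1:2], c("CHEBI:4167", "GO:0051234"))
  expect_equal(x$concept_id[3], "P04637")
  expect_equal(x$concept_id[4:5], c("CHEBI:17234", "SBO:0000252"))
  expect_equal(x$ok, c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
})

test_that("parse_sbml_annotations emits one record per resource occurrence", {
  path <- sbml_fixture(
    model_id = "mod1",
    species = list(c("urn:miriam:obo.go:GO%3A0006402",
                     "urn:miriam:obo.go:GO%3A0006402"),   # duplicate counts twice
                   "http://identifiers.org/chebi/CHEBI:4167"),
    sbo = "SBO:0000252",
    model_ann = "http://identifiers.org/pubmed/123")
  recs <- parse_sbml_annotations(path)
  expect_equal(nrow(recs), 5L)
  expect_equal(sum(recs$concept_id == "GO:0006402"), 2L)
  expect_equal(recs$qualifier[recs$ontology == "SBO"], "sboTerm")
  expect_equal(sum(recs$qualifier == "bqbiol:is"), 3L)
  expect_equal(recs$qualifier[recs$level == "model"], "bqmodel:isDescribedBy")
  expect_equal(unique(recs$model_id), "mod1")
  # element ids resolve to the annotated elements
  expect_true(all(c("mod1_s1", "mod1_s2", "mod1_r1", "mod1") %in%
                    recs$element_id))
})

test_that("models without annotations yield an empty record set", {
  recs <- parse_sbml_annotations(sbml_fixture(model_id = "bare"))
  expect_s3_class(recs, "data.frame")
  expect_equal(nrow(recs), 0L)
})

test_that("malformed and non-SBML input is rejected", {
  bad <- tempfile(fileext = ".xml")
  writeLines("<sbml><unclosed>", bad)
  expect_error(parse_sbml_annotations(bad), "malformed XML")
  notsbml <- tempfile(fileext = ".xml")
  writeLines("<foo><bar/></foo>", notsbml)
  expect_error(parse_sbml_annotations(notsbml), "not an SBML document")
})

test_that("corpus index aggregates EF over descendant sets", {
  tax <- tiny_tax()   # GO:1 -> GO:2 -> {GO:3, GO:4}
  f1 <- sbml_fixture("m1", species = list(
    rep("http://identifiers.org/go/GO:0000003", 2),
    rep("http://identifiers.org/go/GO:0000004", 3)))
  idx <- build_corpus_index(f1, tax)
  expect_equal(unname(idx$direct[c("GO:0000003", "GO:0000004")]), c(2L, 3L))
  expect_equal(unname(idx$ef["GO:0000002"]), 5)
  expect_equal(unname(idx$ef["GO:0000001"]), 5)
  expect_equal(unname(idx$ep["GO:0000002"]), 1)
  expect_equal(idx$n_records, 5L)

  # chain r -> x -> y with direct x:1, y:3
  chain <- load_obo(obo_fixture(c("GO:0000001",
                                  "GO:0000002 is_a GO:0000001",
                                  "GO:0000003 is_a GO:0000002")), "GO")
  cidx <- idx_from_counts(chain, c("GO:0000002" = 1L, "GO:0000003" = 3L))
  expect_equal(unname(cidx$ef["GO:0000002"]), 4)
  expect_equal(unname(cidx$ep["GO:0000003"]), 0.75)
})

test_that("document frequency counts models and propagates to ancestors", {
  tax <- tiny_tax()
  f1 <- sbml_fixture("m1", species = list("http://identifiers.org/go/GO:0000003"))
  f2 <- sbml_fixture("m2", species = list("http://identifiers.org/go/GO:0000003"))
  idx <- build_corpus_index(c(f1, f2), tax)
  expect_equal(unname(idx$direct["GO:0000003"]), 2L)
  expect_equal(unname(idx$doc_freq["GO:0000003"]), 2L)
  expect_equal(unname(idx$doc_freq["GO:0000002"]), 2L)   # aggregated upward
  expect_equal(unname(idx$doc_freq["GO:0000004"]), 0L)
  # monotone along every is_a edge
  for (id in tax$ids) {
    for (k in tax$children[[id]]) {
      expect_gte(idx$doc_freq[id], idx$doc_freq[k])
    }
  }
})

test_that("unknown ids and foreign ontologies never enter the counts", {
  tax <- tiny_tax()
  f <- sbml_fixture("m1", species = list(
    "http://identifiers.org/go/GO:0000003",
    "http://identifiers.org/go/GO:7777777",        # unknown in taxonomy
    "http://identifiers.org/chebi/CHEBI:4167",     # foreign ontology
    "http://identifiers.org/uniprot/P04637"))      # out-of-scope namespace
  idx <- build_corpus_index(f, tax)
  expect_equal(idx$n_records, 1L)
  expect_equal(nrow(idx$unresolved), 1L)
  expect_equal(idx$unresolved$concept_id, "GO:7777777")
  expect_equal(idx$n_foreign, 2L)
  expect_equal(sum(idx$direct), 1L)
})

test_that("the index is invariant to model ordering and conserves records", {
  spec <- fixture_spec(seed = 21, n_concepts = 60, n_models = 5)
  tax <- generate_taxonomy(spec)
  paths <- generate_corpus(spec, tax)
  a <- build_corpus_index(paths, tax)
  b <- build_corpus_index(rev(paths), tax)
  expect_identical(a$direct, b$direct)
  expect_identical(a$ef, b$ef)
  expect_identical(a$doc_freq, b$doc_freq)
  expect_identical(a$models, b$models)
  # conservation on trees: EF(root) equals the resolved record count
  expect_equal(unname(a$ef[tax$root]), a$n_records)
  expect_equal(sum(a$direct), a$n_records)
})

test_that("df_filter removes rare concepts and recomputes the index", {
  tax <- tiny_tax()
  f1 <- sbml_fixture("m1", species = list(
    "http://identifiers.org/go/GO:0000003",
    "http://identifiers.org/go/GO:0000004"))
  f2 <- sbml_fixture("m2", species = list("http://identifiers.org/go/GO:0000003"))
  idx <- build_corpus_index(c(f1, f2), tax)
  expect_identical(df_filter(idx, tax, 0), idx)
  expect_identical(df_filter(idx, tax, 1), idx)
  flt <- df_filter(idx, tax, 2)
  expect_equal(unname(flt$direct["GO:0000004"]), 0L)   # in 1 of 2 models
  expect_equal(unname(flt$direct["GO:0000003"]), 2L)
  expect_equal(unname(flt$ef[tax$root]), 2)
  expect_equal(flt$n_records, 2L)
  expect_error(df_filter(idx, tax, -1), "non-negative")
})

test_that("filtering everything leaves an empty index and empty features", {
  tax <- tiny_tax()
  f1 <- sbml_fixture("m1", species = list("http://identifiers.org/go/GO:0000003"))
  idx <- build_corpus_index(f1, tax)
  flt <- df_filter(idx, tax, 5)
  expect_equal(unname(flt$ef[tax$root]), 0)
  expect_warning(fs <- method2_topdown(tax, flt), "no resolved annotations")
  expect_equal(n_features(fs), 0L)
})

test_that("empty model lists are refused", {
  expect_error(build_corpus_index(character(), tiny_tax()), "empty model list")
})
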