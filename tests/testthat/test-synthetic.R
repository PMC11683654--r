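test_that("ontology fixtures are deterministic per seed and respect counts", {
  spec <- fixture_spec(n_rare_diseases = 3, n_diseases = 2, n_phenotypes = 4,
                       seed = 21)
  d1 <- tempfile(); d2 <- tempfile()
  o1 <- generate_ontology_fixture(spec, dir = d1)
  o2 <- generate_ontology_fixture(spec, dir = d2)
  expect_identical(o1$rare_names, o2$rare_names)
  for (f in names(o1$files)) {
    expect_identical(readLines(o1$files[[f]]), readLines(o2$files[[f]]))
  }
  tsv <- utils::read.delim(o1$files[["rare_tsv"]], stringsAsFactors = FALSE)
  expect_equal(nrow(tsv), 3L)
  # both dialects compile to the same lexicon
  from_obo <- compile_rare_disease_lexicon(o1$files[["rare_obo"]])
  from_tsv <- compile_rare_disease_lexicon(o1$files[["rare_tsv"]])
  expect_setequal(lexicon_keys(from_obo), lexicon_keys(from_tsv))
  # zero counts still give valid (empty) files
  z <- generate_ontology_fixture(
    fixture_spec(n_rare_diseases = 0, n_diseases = 0, n_phenotypes = 0,
                 seed = 1), dir = tempfile())
  expect_equal(lexicon_size(compile_rare_disease_lexicon(z$files[["rare_tsv"]])),
               0L)
})

test_that("association fixtures link each rare disease to 1-5 phenotypes", {
  onto <- generate_ontology_fixture(fixture_spec(seed = 5))
  counts <- table(onto$associations$rare_disease)
  expect_setequal(names(counts), onto$rare_names)
  expect_true(all(counts >= 1 & counts <= 5))
  expect_true(all(onto$associations$phenotype %in% onto$phenotype_names))
})

test_that("generated corpora obey their spec's structural guarantees", {
  spec <- fixture_spec(n_docs = 15, cross_boundary_rate = 0.2, seed = 13)
  onto <- generate_ontology_fixture(spec)
  corpus <- generate_corpus(spec, onto)
  expect_length(corpus, 15L)
  c2 <- generate_corpus(spec, onto)
  expect_identical(vapply(corpus, `[[`, "", "text"),
                   vapply(c2, `[[`, "", "text"))  # deterministic per seed
  for (doc in corpus) {
    # spans are exact (enforced by the constructor, re-checked here)
    expect_equal(substring(doc$text, doc$entities$start + 1, doc$entities$end),
                 doc$entities$surface)
    # every mention participates in at least one relation
    refs <- c(doc$relations$subject_ref, doc$relations$object_ref)
    expect_true(all(doc$entities$mention_id %in% refs))
    # name-level relation triples are unique within a document
    surf <- setNames(doc$entities$surface, doc$entities$mention_id)
    key <- paste(normalize_name(surf[doc$relations$subject_ref]),
                 doc$relations$relation_type,
                 normalize_name(surf[doc$relations$object_ref]))
    expect_false(any(duplicated(key)))
    # anaphora antecedents are rare diseases
    ana <- doc$relations$relation_type == "anaphora"
    types <- setNames(doc$entities$entity_type, doc$entities$mention_id)
    expect_true(all(types[doc$relations$object_ref[ana]] == "rare_disease"))
  }
})

test_that("rate dials shut off their features completely", {
  onto <- generate_ontology_fixture(fixture_spec(seed = 3))
  no_ana <- generate_corpus(fixture_spec(n_docs = 5, anaphor_rate = 0,
                                         seed = 3), onto)
  for (doc in no_ana) {
    expect_false(any(doc$entities$entity_type == "anaphor"))
    expect_false(any(doc$relations$relation_type == "anaphora"))
  }
  only_produces <- generate_corpus(
    fixture_spec(n_docs = 5, seed = 3,
                 relation_mix = c(produces = 1, increases_risk_of = 0,
                                  is_a = 0, is_acron = 0, is_synon = 0,
                                  anaphora = 0)), onto)
  for (doc in only_produces) {
    expect_true(all(doc$relations$relation_type == "produces"))
  }
})

test_that("gold volumes and type proportions land near their targets", {
  spec <- fixture_spec(n_docs = 100, seed = 31)
  onto <- generate_ontology_fixture(spec)
  corpus <- generate_corpus(spec, onto)
  ents <- do.call(rbind, lapply(corpus, function(d) d$entities))
  # 100 docs at 5-10 mentions apiece
  expect_gte(nrow(ents), 500L)
  expect_lte(nrow(ents), 1000L)
  props <- prop.table(table(ents$entity_type))
  # emulated corpus shape: ~34% rare_disease, ~40% symptom_and_sign,
  # ~15% disease, ~11% anaphor (wide tolerances; binomial + event bundling)
  expect_gt(props[["rare_disease"]], 0.22)
  expect_lt(props[["rare_disease"]], 0.47)
  expect_gt(props[["symptom_and_sign"]], 0.28)
  expect_lt(props[["symptom_and_sign"]], 0.52)
  expect_gt(props[["disease"]], 0.05)
  expect_lt(props[["disease"]], 0.28)
  expect_gt(props[["anaphor"]], 0.03)
  expect_lt(props[["anaphor"]], 0.20)
})

test_that("oracle corruption parameters are validated", {
  setup <- study_setup(n_docs = 2)
  expect_error(build_oracle(setup$corpus, list(bogus = 1)), "unknown")
  expect_error(build_oracle(setup$corpus, list(entity_drop_p = 1.5)))
  o <- build_oracle(setup$corpus, list(entity_drop_p = 0.3,
                                       relation_drop_p = 0.1))
  expect_equal(o$corruption$entity_drop_p, 0.3)
  expect_equal(o$corruption$spurious_rate, 0)
})
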