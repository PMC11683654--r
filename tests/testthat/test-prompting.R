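test_that("exemplar selection is a seeded sample without replacement", {
  docs <- generate_corpus(fixture_spec(n_docs = 12, seed = 2),
                          generate_ontology_fixture(fixture_spec(seed = 2)))
  e1 <- select_exemplars(docs, k = 5, seed = 10)
  e2 <- select_exemplars(docs, k = 5, seed = 10)
  expect_identical(vapply(e1, `[[`, "", "source_doc_id"),
                   vapply(e2, `[[`, "", "source_doc_id"))
  expect_length(select_exemplars(docs, k = 0), 0L)
  all_of_them <- select_exemplars(docs, k = 12, seed = 1)
  expect_setequal(vapply(all_of_them, `[[`, "", "source_doc_id"),
                  vapply(docs, `[[`, "", "doc_id"))
  expect_error(select_exemplars(docs, k = 13), "exceeds")
  # gold outputs parse under the stage schema
  for (ex in e1[1:2]) {
    expect_silent(parse_json_payload(ex$gold_output_json, "entities"))
  }
  rel_ex <- select_exemplars(docs, k = 2, seed = 1, stage = "extract_relations")
  expect_silent(parse_json_payload(rel_ex[[1]]$gold_output_json, "relations"))
})

test_that("prompts embed a recoverable stage marker", {
  seg <- as_segment("Fryns syndrome produces fatigue.", "docX")
  prompt <- render_extract_more_terms(seg, match_terms(seg$text,
                                                       tiny_kb()$concept_lexicon))
  mk <- raremine:::parse_stage_marker(prompt)
  expect_equal(mk$stage, "extract_more_terms")
  expect_equal(mk$doc, "docX")
  expect_equal(mk$span_start, 0L)
  expect_equal(mk$kind, "segment")
})

test_that("toggles add or remove whole sections, leaving the rest byte-identical", {
  seg <- as_segment("Fryns syndrome produces fatigue.", "docX")
  kb <- tiny_kb()
  m <- annotate_negation(match_terms(seg$text, kb$concept_lexicon), seg$text)
  on <- render_extract_more_terms(seg, m, ablation_toggles())
  off <- render_extract_more_terms(seg, m,
                                   ablation_toggles(use_notice = FALSE))
  expect_match(on, "Notice:", fixed = TRUE)
  expect_no_match(off, "Notice:", fixed = TRUE)
  # removing the notice section leaves everything else untouched
  notice_block <- paste0("\n\n", raremine:::template_text("notice"))
  expect_identical(sub(notice_block, "", on, fixed = TRUE), off)
  # rendering is deterministic
  expect_identical(on, render_extract_more_terms(seg, m, ablation_toggles()))
})

test_that("the entity prompt carries candidates, anaphors and rare-disease knowledge", {
  seg <- as_segment("Fryns syndrome produces fatigue.", "docX")
  rdk <- data.frame(name = "Fryns syndrome",
                    definition = "A rare congenital disorder.",
                    stringsAsFactors = FALSE)
  p <- render_entity_prompt(seg, c("Fryns syndrome", "fatigue"),
                            "this disease", rd_knowledge = rdk)
  expect_match(p, "- Fryns syndrome is a rare disease. A rare congenital disorder.",
               fixed = TRUE)
  expect_match(p, "- this disease", fixed = TRUE)
  off <- render_entity_prompt(seg, c("Fryns syndrome", "fatigue"),
                              "this disease", rd_knowledge = rdk,
                              toggles = ablation_toggles(use_knowledge = FALSE))
  expect_no_match(off, "Rare disease knowledge", fixed = TRUE)
  empty <- render_entity_prompt(seg, character(0), character(0))
  expect_match(empty, "none found", fixed = TRUE)
})

test_that("the relation prompt lists entities, all six relation types and associations", {
  seg <- as_segment("Fryns syndrome produces fatigue.", "docX")
  ents <- data.frame(surface = c("Fryns syndrome", "fatigue"),
                     entity_type = c("rare_disease", "symptom_and_sign"),
                     stringsAsFactors = FALSE)
  assoc <- lookup_associations(tiny_kb(), "Fryns syndrome")
  p <- render_relation_prompt(seg, ents, assoc)
  for (tp in c("produces", "increases_risk_of", "is_a", "is_acron",
               "is_synon", "anaphora")) {
    expect_match(p, tp, fixed = TRUE)
  }
  expect_match(p, "- Fryns syndrome | rare_disease", fixed = TRUE)
  expect_match(p, "Fryns syndrome has the phenotype fatigue (Very frequent).",
               fixed = TRUE)
  expect_match(p, "has the phenotype rash", fixed = TRUE)  # both triples
  none <- render_relation_prompt(seg, ents[2, , drop = FALSE], NULL)
  expect_match(none, "## Known rare-disease associations\nnone", fixed = TRUE)
})

test_that("exemplars render in sample order and are dropped under budget pressure", {
  docs <- generate_corpus(fixture_spec(n_docs = 8, seed = 4),
                          generate_ontology_fixture(fixture_spec(seed = 4)))
  ex <- select_exemplars(docs, k = 5, seed = 1)
  seg <- as_segment("Fryns syndrome produces fatigue.", "docX")
  p <- render_entity_prompt(seg, "fatigue", character(0), exemplars = ex)
  for (i in 1:5) expect_match(p, sprintf("Example %d", i), fixed = TRUE)
  # order of appearance equals sample order
  starts <- vapply(seq_along(ex), function(i) {
    regexpr(ex[[i]]$input_text, p, fixed = TRUE)[[1]]
  }, numeric(1))
  expect_true(all(diff(starts) > 0))
  # tight budget drops exemplars (from the end) but never the passage
  expect_warning(
    small <- render_entity_prompt(seg, "fatigue", character(0),
                                  exemplars = ex, budget_tokens = 60),
    "dropping an exemplar")
  expect_match(small, seg$text, fixed = TRUE)
  expect_lt(count_tokens(small), count_tokens(p))
})

test_that("the calibration prompt reports per-entity relation counts", {
  ents <- data.frame(surface = c("Fryns syndrome", "fatigue", "disorder"),
                     entity_type = c("rare_disease", "symptom_and_sign",
                                     "disease"), stringsAsFactors = FALSE)
  rels <- data.frame(subject = "Fryns syndrome", relation_type = "produces",
                     object = "fatigue", stringsAsFactors = FALSE)
  p <- render_calibration_prompt(ents, rels, "docY")
  expect_match(p, "- Fryns syndrome | rare_disease | relations=1", fixed = TRUE)
  expect_match(p, "- disorder | disease | relations=0", fixed = TRUE)
  expect_identical(p, render_calibration_prompt(ents, rels, "docY"))
  empty <- render_calibration_prompt(ents[0, ], rels[0, ], "docY")
  expect_match(empty, "## Entities\nnone", fixed = TRUE)
})
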