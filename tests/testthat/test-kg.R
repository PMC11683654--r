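extraction_fixture <- function() {
  ents <- data.frame(
    surface = c("Fryns syndrome", "this disease", "fatigue"),
    entity_type = c("rare_disease", "anaphor", "symptom_and_sign"),
    start = c(0L, 40L, 60L), end = c(14L, 52L, 67L),
    provenance = NA_character_, stringsAsFactors = FALSE)
  rels <- data.frame(
    subject = c("this disease", "this disease"),
    relation_type = c("anaphora", "produces"),
    object = c("Fryns syndrome", "fatigue"),
    provenance = NA_character_, stringsAsFactors = FALSE)
  raremine:::new_extraction("d1", ents, rels)
}

test_that("name normalization case-folds, trims and collapses whitespace idempotently", {
  expect_equal(normalize_name("Fryns Syndrome"), "fryns syndrome")
  expect_equal(normalize_name("  giant  cell myocarditis "),
               "giant cell myocarditis")
  x <- c("A  b", " c ", "already normalized")
  expect_identical(normalize_name(normalize_name(x)), normalize_name(x))
})

test_that("anaphoric relations are rewritten to their antecedents", {
  out <- resolve_anaphora(extraction_fixture())
  expect_equal(nrow(out$relations), 1L)
  expect_equal(out$relations$subject, "Fryns syndrome")
  expect_equal(out$relations$object, "fatigue")
  expect_false(any(out$entities$entity_type == "anaphor"))
  # a result without anaphors is untouched
  plain <- raremine:::new_extraction("d2", data.frame(
    surface = "fatigue", entity_type = "symptom_and_sign",
    start = NA_integer_, end = NA_integer_, provenance = NA_character_,
    stringsAsFactors = FALSE), raremine:::empty_pred_relations())
  expect_identical(resolve_anaphora(plain), plain)
})

test_that("multi-link anaphors resolve to the nearest preceding antecedent", {
  ents <- data.frame(
    surface = c("Alpha syndrome", "Beta syndrome", "this disease", "fatigue"),
    entity_type = c("rare_disease", "rare_disease", "anaphor",
                    "symptom_and_sign"),
    start = c(0L, 30L, 60L, 90L), end = c(14L, 44L, 72L, 97L),
    provenance = NA_character_, stringsAsFactors = FALSE)
  rels <- data.frame(
    subject = c("this disease", "this disease", "this disease"),
    relation_type = c("anaphora", "anaphora", "produces"),
    object = c("Alpha syndrome", "Beta syndrome", "fatigue"),
    provenance = NA_character_, stringsAsFactors = FALSE)
  expect_warning(out <- resolve_anaphora(raremine:::new_extraction("d", ents, rels)),
                 "nearest antecedent")
  expect_equal(out$relations$subject, "Beta syndrome")
  # an unlinked anaphor loses its relations with a warning
  rels2 <- rels[3, , drop = FALSE]
  expect_warning(out2 <- resolve_anaphora(raremine:::new_extraction("d", ents, rels2)),
                 "no anaphora link")
  expect_equal(nrow(out2$relations), 0L)
})

test_that("graphs merge duplicate triples, align case and exclude isolated nodes", {
  mk <- function(doc, subj) raremine:::new_extraction(doc, data.frame(
    surface = c(subj, "fatigue", "lonely term"),
    entity_type = c("rare_disease", "symptom_and_sign", "disease"),
    start = NA_integer_, end = NA_integer_, provenance = NA_character_,
    stringsAsFactors = FALSE), data.frame(
      subject = subj, relation_type = "produces", object = "fatigue",
      provenance = NA_character_, stringsAsFactors = FALSE))
  kg <- build_graph(list(mk("d1", "Fryns syndrome"),
                         mk("d2", "FRYNS SYNDROME")))
  expect_equal(nrow(kg$nodes), 2L)
  expect_equal(nrow(kg$edges), 1L)
  expect_equal(kg$edges$support, 2L)
  expect_equal(kg$nodes$name[kg$nodes$key == "fryns syndrome"],
               "Fryns syndrome")  # first-seen display name
  expect_false("lonely term" %in% kg$nodes$key)  # isolated node excluded
  expect_equal(nrow(build_graph(list())$nodes), 0L)
})

test_that("a rare disease producing three phenotypes forms a 4-node star", {
  ents <- data.frame(
    surface = c("Turcot syndrome", "abdominal pain", "bleeding", "fatigue"),
    entity_type = c("rare_disease", rep("symptom_and_sign", 3)),
    start = NA_integer_, end = NA_integer_, provenance = NA_character_,
    stringsAsFactors = FALSE)
  rels <- data.frame(
    subject = "Turcot syndrome", relation_type = "produces",
    object = c("abdominal pain", "bleeding", "fatigue"),
    provenance = NA_character_, stringsAsFactors = FALSE)
  kg <- build_graph(list(raremine:::new_extraction("d", ents, rels)))
  expect_equal(nrow(kg$nodes), 4L)
  expect_equal(nrow(kg$edges), 3L)
  expect_true(all(kg$edges$subject == "turcot syndrome"))
})

test_that("conflicting node types resolve by rare_disease > disease > symptom_and_sign", {
  mk <- function(doc, type) raremine:::new_extraction(doc, data.frame(
    surface = c("ambiguous term", "fatigue"),
    entity_type = c(type, "symptom_and_sign"),
    start = NA_integer_, end = NA_integer_, provenance = NA_character_,
    stringsAsFactors = FALSE), data.frame(
      subject = "ambiguous term", relation_type = "produces",
      object = "fatigue", provenance = NA_character_, stringsAsFactors = FALSE))
  expect_message(kg <- build_graph(list(mk("d1", "disease"),
                                        mk("d2", "rare_disease"))),
                 "precedence")
  expect_equal(kg$nodes$type[kg$nodes$key == "ambiguous term"], "rare_disease")
})

test_that("CSV export round-trips an isomorphic graph; other formats are well-formed", {
  setup <- study_setup(n_docs = 5)
  res <- run_corpus(setup$corpus, setup$kb, setup$config)
  kg <- build_graph(res)
  expect_false(any(kg$nodes$type == "anaphor"))
  expect_false(any(kg$edges$relation == "anaphora"))
  dir <- tempfile()
  export_graph(kg, dir, "csv_pair")
  back <- import_graph_csv(dir)
  expect_equal(back$nodes, kg$nodes)
  expect_equal(back$edges, kg$edges)
  # graphml parses and carries every node and edge
  export_graph(kg, dir, "graphml")
  doc <- xml2::read_xml(file.path(dir, "graph.graphml"))
  ns <- xml2::xml_ns(doc)
  expect_length(xml2::xml_find_all(doc, "//d1:node", ns), nrow(kg$nodes))
  expect_length(xml2::xml_find_all(doc, "//d1:edge", ns), nrow(kg$edges))
  # cypher emits one MERGE per node and edge
  export_graph(kg, dir, "cypher")
  lines <- readLines(file.path(dir, "graph.cypher"))
  expect_equal(sum(grepl("^MERGE", lines)), nrow(kg$nodes))
  expect_equal(sum(grepl("^MATCH", lines)), nrow(kg$edges))
  expect_error(export_graph(kg, dir, "dot"))
  # empty graph: headers only
  empty_dir <- tempfile()
  export_graph(build_graph(list()), empty_dir, "csv_pair")
  expect_equal(nrow(utils::read.csv(file.path(empty_dir, "nodes.csv"))), 0L)
})
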