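# Compact constructors for scoring fixtures: gold documents and predictions
# from (surface, type) and (subject, type, object) rows.
gold_doc <- function(doc_id, ents, rels = NULL) {
  text <- paste(rep("x", 2000), collapse = "")  # spans unused in scoring
  if (is.null(ents) || !nrow(ents)) {
    return(rd_document(doc_id, text, raremine:::empty_entities(),
                       raremine:::empty_relations()))
  }
  edf <- data.frame(mention_id = paste0("T", seq_len(nrow(ents))),
                    surface = ents$surface, entity_type = ents$type,
                    start = NA_integer_, end = NA_integer_,
                    stringsAsFactors = FALSE)
  rdf <- if (is.null(rels) || !nrow(rels)) raremine:::empty_relations() else {
    id_of <- function(s) edf$mention_id[match(s, edf$surface)]
    data.frame(rel_id = paste0("R", seq_len(nrow(rels))),
               relation_type = rels$type,
               subject_ref = id_of(rels$subject),
               object_ref = id_of(rels$object), stringsAsFactors = FALSE)
  }
  rd_document(doc_id, text, edf, rdf)
}

pred_doc <- function(doc_id, ents, rels = NULL) {
  edf <- if (is.null(ents) || !nrow(ents)) raremine:::empty_pred_entities() else
    data.frame(surface = ents$surface, entity_type = ents$type,
               start = NA_integer_, end = NA_integer_,
               provenance = NA_character_, stringsAsFactors = FALSE)
  rdf <- if (is.null(rels) || !nrow(rels)) raremine:::empty_pred_relations() else
    data.frame(subject = rels$subject, relation_type = rels$type,
               object = rels$object, provenance = NA_character_,
               stringsAsFactors = FALSE)
  raremine:::new_extraction(doc_id, edf, rdf)
}

rows <- function(...) data.frame(..., stringsAsFactors = FALSE)

test_that("perfect predictions score 100 everywhere", {
  g <- gold_doc("d", rows(surface = c("Fryns syndrome", "fatigue"),
                          type = c("rare_disease", "symptom_and_sign")),
                rows(subject = "Fryns syndrome", type = "produces",
                     object = "fatigue"))
  p <- pred_doc("d", rows(surface = c("FRYNS SYNDROME", "fatigue"),
                          type = c("rare_disease", "symptom_and_sign")),
                rows(subject = "fryns syndrome", type = "produces",
                     object = "Fatigue"))
  m <- metrics_report(list(p), list(g))
  expect_equal(unname(m$overall), c(100, 100, 100))
  expect_equal(m$per_entity_type$rare_disease[["f1"]], 100)
  expect_equal(m$per_relation_type$produces[["recall"]], 100)
})

test_that("replicated mentions pair as a multiset", {
  g <- gold_doc("d", rows(surface = c("anemia", "anemia"),
                          type = c("disease", "disease")))
  p <- pred_doc("d", rows(surface = "anemia", type = "disease"))
  s <- score_entities(list(p), list(g))
  expect_equal(s$per_type$disease[["recall"]], 50)
  expect_equal(s$per_type$disease[["precision"]], 100)
  # an extra duplicate prediction costs precision, not recall
  p2 <- pred_doc("d", rows(surface = c("anemia", "anemia", "anemia"),
                           type = rep("disease", 3)))
  s2 <- score_entities(list(p2), list(g))
  expect_equal(s2$per_type$disease[["recall"]], 100)
  expect_equal(round(s2$per_type$disease[["precision"]], 4), round(200 / 3, 4))
})

test_that("a type confusion is a miss for the gold type and a false positive for the predicted", {
  g <- gold_doc("d", rows(surface = "Fryns syndrome", type = "rare_disease"))
  p <- pred_doc("d", rows(surface = "Fryns syndrome", type = "disease"))
  s <- score_entities(list(p), list(g))
  expect_equal(s$per_type$rare_disease[["recall"]], 0)
  expect_equal(s$per_type$disease[["precision"]], 0)
  expect_equal(s$overall[["f1"]], 0)
})

test_that("relation scoring is name-normalized and per-type", {
  g <- gold_doc("d", rows(surface = c("A syndrome", "fatigue", "rash"),
                          type = c("rare_disease", "symptom_and_sign",
                                   "symptom_and_sign")),
                rows(subject = c("A syndrome", "A syndrome"),
                     type = c("produces", "produces"),
                     object = c("fatigue", "rash")))
  p <- pred_doc("d", rows(surface = "A syndrome", type = "rare_disease"),
                rows(subject = c("A SYNDROME", "A syndrome"),
                     type = c("produces", "is_a"),
                     object = c("fatigue", "fatigue")))
  s <- score_relations(list(p), list(g))
  expect_equal(s$per_type$produces[["recall"]], 50)
  expect_equal(s$per_type$produces[["precision"]], 100)
  expect_equal(s$per_type$is_a[["precision"]], 0)
  expect_equal(s$overall[["matched"]], 1)
})

test_that("empty predictions score zero with the empty flag", {
  g <- gold_doc("d", rows(surface = "fatigue", type = "symptom_and_sign"))
  m <- metrics_report(list(pred_doc("d", NULL)), list(g))
  expect_true(m$empty_pred)
  expect_equal(unname(m$overall), c(0, 0, 0))
  expect_warning(report(m), "empty prediction")
})

test_that("overall F1 is the rounded mean of entity and relation F1", {
  expect_equal(overall_score(0, 0), 0)
  expect_equal(overall_score(100, 100), 100)
  expect_equal(overall_score(50, 40.25), 45.1)  # 45.125 rounds up
  expect_equal(round_half_up(c(2.25, -2.25, 2.24)), c(2.3, -2.3, 2.2))
})

test_that("micro scores obey F1 bounds and match a brute-force optimal matcher", {
  set.seed(202)
  names_pool <- c("alpha", "beta", "gamma", "delta", "epsilon")
  for (trial in 1:200) {
    n_g <- sample(0:10, 1); n_p <- sample(0:10, 1)
    g <- gold_doc("d", rows(
      surface = sample(names_pool, n_g, replace = TRUE),
      type = sample(c("disease", "rare_disease"), n_g, replace = TRUE))[seq_len(n_g), , drop = FALSE])
    p <- pred_doc("d", rows(
      surface = sample(names_pool, n_p, replace = TRUE),
      type = sample(c("disease", "rare_disease"), n_p, replace = TRUE))[seq_len(n_p), , drop = FALSE])
    s <- score_entities(list(p), list(g))
    o <- s$overall
    expect_lte(o[["f1"]], max(o[["precision"]], o[["recall"]]) + 1e-9)
    expect_equal(o[["f1"]] == 0, o[["matched"]] == 0)
    pk <- paste(normalize_name(p$entities$surface), p$entities$entity_type)
    gk <- paste(normalize_name(g$entities$surface), g$entities$entity_type)
    expect_equal(o[["matched"]], brute_force_matched(pk, gk))
  }
})

test_that("confusion matrices deduplicate names and route misses to Error", {
  g <- gold_doc("d", rows(surface = c("Fryns syndrome", "fatigue", "fatigue"),
                          type = c("rare_disease", "symptom_and_sign",
                                   "symptom_and_sign")))
  p <- pred_doc("d", rows(surface = c("Fryns syndrome", "spurious finding"),
                          type = c("disease", "disease")))
  cm <- confusion_matrices(list(p), list(g))$entity
  expect_equal(cm["rare_disease", "disease"], 1L)
  expect_equal(cm["symptom_and_sign", "Error"], 1L)  # duplicate counted once
  expect_equal(cm["Error", "disease"], 1L)           # spurious prediction
  expect_equal(sum(cm), 3L)
  # perfect predictions give a diagonal matrix
  p2 <- pred_doc("d", rows(surface = c("Fryns syndrome", "fatigue"),
                           type = c("rare_disease", "symptom_and_sign")))
  cm2 <- confusion_matrices(list(p2), list(g))$entity
  expect_equal(cm2["rare_disease", "rare_disease"], 1L)
  expect_equal(cm2["symptom_and_sign", "symptom_and_sign"], 1L)
  expect_equal(sum(cm2), 2L)
  expect_equal(sum(cm2["Error", ]) + sum(cm2[, "Error"]), 0L)
  # row sums (excluding Error row) equal deduplicated gold counts
  expect_equal(unname(rowSums(cm)[c("rare_disease", "symptom_and_sign")]),
               c(1, 1))
})

test_that("scoring is invariant under document order permutation", {
  setup <- study_setup(n_docs = 6)
  res <- run_corpus(setup$corpus, setup$kb, setup$config)
  m1 <- metrics_report(res, setup$corpus)
  perm <- c(4, 1, 6, 2, 5, 3)
  m2 <- metrics_report(res[perm], setup$corpus[perm])
  expect_equal(m1$overall, m2$overall)
  expect_equal(m1$entity_overall, m2$entity_overall)
})

test_that("reports render one-decimal rows with signed deltas against a reference", {
  g <- list(gold_doc("d", rows(surface = c("a", "b", "c"),
                               type = rep("disease", 3))))
  full <- metrics_report(list(pred_doc("d", rows(surface = c("a", "b", "c"),
                                                 type = rep("disease", 3)))), g)
  partial <- metrics_report(list(pred_doc("d", rows(surface = "a",
                                                    type = "disease"))), g)
  lines <- report(partial, "text_table", reference = full)
  expect_true(any(grepl("-66.7", lines)))  # recall drop rendered with sign
  csv <- report(full, "csv")
  expect_equal(csv[1], "row,precision,recall,f1")
  expect_length(csv, 1 + 4 + 1 + 6 + 2)
  parsed <- jsonlite::fromJSON(report(full, "json"))
  expect_equal(parsed$f1[parsed$row == "overall"], 50)
})
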