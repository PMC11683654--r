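test_that("OBO sources compile into a rare-disease lexicon, skipping obsolete terms", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: RD:0001", "name: Fryns syndrome",
    'def: "A rare congenital disorder." []',
    'synonym: "Fryns disease" EXACT []', "",
    "[Term]", "id: RD:0002", "name: Giant cell myocarditis",
    'def: "A rare heart disease." []', "",
    "[Term]", "id: RD:0003", "name: Old term", "is_obsolete: true", ""),
    obo)
  lex <- compile_rare_disease_lexicon(obo)
  # 2 non-obsolete concepts; Fryns indexed under preferred name + synonym
  expect_equal(lexicon_size(lex), 3L)
  kb <- knowledge_base(lex, compile_concept_lexicon(list()),
                       compile_association_index(
                         data.frame(rare_disease = character(0),
                                    frequency = character(0),
                                    phenotype = character(0))))
  hit <- lookup_rare_disease(kb, "fryns syndrome")
  expect_equal(hit$preferred_name, "Fryns syndrome")
  expect_equal(hit$definition, "A rare congenital disorder.")
  expect_equal(hit$category, "rare_disease")
  # case-insensitivity and synonym resolution
  expect_identical(lookup_rare_disease(kb, "FRYNS SYNDROME"), hit)
  expect_identical(lookup_rare_disease(kb, "Fryns disease"), hit)
  expect_null(lookup_rare_disease(kb, "influenza"))
})

test_that("malformed and empty ontology sources are handled", {
  bad <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: X:1", "no-colon-here line"), bad)
  expect_error(compile_rare_disease_lexicon(bad), "unparseable")
  noname <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: X:1"), noname)
  expect_error(compile_rare_disease_lexicon(noname), "no name")
  expect_equal(lexicon_size(compile_rare_disease_lexicon(list())), 0L)
})

test_that("duplicate names resolve first-seen-wins with a message", {
  terms <- list(term("A:1", "Shared name", def = "first"),
                term("A:2", "Shared Name", def = "second"))
  expect_message(lex <- compile_rare_disease_lexicon(terms),
                 "first-seen-wins")
  expect_equal(lexicon_size(lex), 1L)
  expect_equal(get("shared name", envir = lex$index)$concept_id, "A:1")
})

test_that("concept lexicon carries categories and counts synonym keys", {
  lex <- compile_concept_lexicon(list(
    term("C:1", "fatigue", category = "phenotype"),
    term("C:2", "influenza", synonyms = c("flu", "grippe"),
         category = "disease")))
  expect_equal(lexicon_size(lex), 4L)  # 2 names + 2 synonyms
  expect_equal(get("fatigue", envir = lex$index)$category, "phenotype")
  expect_equal(get("flu", envir = lex$index)$concept_id, "C:2")
  # preferred-only indexing behind the flag
  lex2 <- compile_concept_lexicon(list(
    term("C:2", "influenza", synonyms = c("flu", "grippe"),
         category = "disease")), include_synonyms = FALSE)
  expect_equal(lexicon_size(lex2), 1L)
})

test_that("association index groups triples by case-folded key, preserving order", {
  df <- data.frame(
    rare_disease = c("Fryns syndrome", "FRYNS SYNDROME", "Other disease"),
    frequency = c("Very frequent", "Occasional", "Frequent"),
    phenotype = c("fatigue", "rash", "pain"), stringsAsFactors = FALSE)
  idx <- compile_association_index(df)
  expect_equal(length(ls(idx$index)), 2L)
  kb <- tiny_kb()
  hits <- lookup_associations(kb, "fryns SYNDROME")
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$phenotype, c("fatigue", "rash"))  # input order kept
  expect_equal(nrow(lookup_associations(kb, "unknown disease")), 0L)
})

test_that("association rows missing a field are skipped with a warning, others conserved", {
  df <- data.frame(rare_disease = c("A", "", "B", "A"),
                   frequency = c("f1", "f2", "", "f3"),
                   phenotype = c("p1", "p2", "p3", "p4"),
                   stringsAsFactors = FALSE)
  expect_warning(idx <- compile_association_index(df), "skipped")
  sizes <- vapply(ls(idx$index), function(k) nrow(get(k, envir = idx$index)),
                  integer(1))
  expect_equal(sum(sizes), 2L)  # rows 1 and 4 survive
})

test_that("compiling then looking up every preferred name round-trips", {
  onto <- generate_ontology_fixture(fixture_spec(seed = 3))
  kb <- fixture_kb(onto)
  for (nm in onto$rare_names) {
    hit <- lookup_rare_disease(kb, nm)
    expect_equal(hit$preferred_name, nm)
    expect_identical(lookup_rare_disease(kb, toupper(nm)), hit)
  }
  for (nm in c(onto$disease_names, onto$phenotype_names)) {
    expect_equal(lookup_concept(kb, nm)$preferred_name, nm)
  }
})

test_that("the TSV compiled dialect round-trips a knowledge base", {
  kb <- tiny_kb()
  dir <- tempfile()
  write_kb_tsv(kb, dir)
  kb2 <- compile_kb(file.path(dir, "rare_diseases.tsv"),
                    file.path(dir, "concepts.tsv"),
                    file.path(dir, "associations.tsv"))
  expect_equal(lexicon_size(kb2$rare_disease_lexicon),
               lexicon_size(kb$rare_disease_lexicon))
  expect_equal(lexicon_size(kb2$concept_lexicon),
               lexicon_size(kb$concept_lexicon))
  hit <- lookup_rare_disease(kb2, "fryns disease")
  expect_equal(hit$preferred_name, "Fryns syndrome")
  expect_equal(lookup_concept(kb2, "fatigue")$category, "phenotype")
  expect_equal(nrow(lookup_associations(kb2, "Fryns syndrome")), 2L)
})
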