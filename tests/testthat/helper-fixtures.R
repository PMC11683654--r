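# In-code fixtures shared across the suite. Everything is generated at test
# time; nothing is read from disk except files the tests themselves write.

term <- function(id, name, synonyms = character(0), def = "",
                 obsolete = FALSE, category = NULL) {
  list(id = id, name = name, synonyms = synonyms, def = def,
       obsolete = obsolete, category = category)
}

# A tiny hand-built knowledge base with known content.
tiny_kb <- function() {
  rare <- list(
    term("RD:1", "Fryns syndrome", synonyms = "Fryns disease",
         def = "A rare congenital disorder."),
    term("RD:2", "Giant cell myocarditis",
         def = "A rare inflammatory heart disease."))
  concepts <- list(
    term("C:1", "fatigue", def = "A feeling of tiredness.",
         category = "phenotype"),
    term("C:2", "rash", category = "phenotype"),
    term("C:3", "heart", category = "phenotype"),
    term("C:4", "abnormal heart rate", category = "phenotype"),
    term("C:5", "influenza", def = "A viral infection.",
         category = "disease"))
  assoc <- data.frame(
    rare_disease = c("Fryns syndrome", "Fryns syndrome",
                     "Giant cell myocarditis"),
    frequency = c("Very frequent", "Occasional", "Frequent"),
    phenotype = c("fatigue", "rash", "abnormal heart rate"),
    stringsAsFactors = FALSE)
  knowledge_base(compile_rare_disease_lexicon(rare),
                 compile_concept_lexicon(concepts),
                 compile_association_index(assoc))
}

# Write a 2-entity, 1-relation standoff pair into `dir`; returns txt path.
write_tiny_standoff <- function(dir, doc_id = "d1") {
  text <- "Fryns syndrome produces fatigue."
  writeChar(text, file.path(dir, paste0(doc_id, ".txt")), eos = NULL)
  writeLines(c("T1\trare_disease 0 14\tFryns syndrome",
               "T2\tSymptom 24 31\tfatigue",
               "R1\tproduces Arg1:T1 Arg2:T2"),
             file.path(dir, paste0(doc_id, ".ann")))
  file.path(dir, paste0(doc_id, ".txt"))
}

# Standard small study corpus + oracle + backend, used by pipeline tests.
study_setup <- function(n_docs = 10, cross_boundary_rate = 0.2, seed = 7,
                        corruption = list(), oracle_seed = 11,
                        ...) {
  spec <- fixture_spec(n_docs = n_docs,
                       cross_boundary_rate = cross_boundary_rate, seed = seed)
  onto <- generate_ontology_fixture(spec)
  corpus <- generate_corpus(spec, onto)
  kb <- fixture_kb(onto)
  oracle <- build_oracle(corpus, corruption, seed = oracle_seed)
  config <- pipeline_config(backend_config("mock", oracle = oracle),
                            max_tokens = 12, bridge_tokens = 24, ...)
  list(spec = spec, onto = onto, corpus = corpus, kb = kb, oracle = oracle,
       config = config)
}

# A one-segment rd_segment wrapper for prompt-level tests.
as_segment <- function(text, doc_id = "doc", char_start = 0) {
  segment_document(text, max_tokens = 100000L, doc_id = doc_id)[[1]]
}

# Independent scoring oracle: maximum bipartite matching between predicted
# and gold mentions with edges on exact (doc, normalized name, type) keys.
brute_force_matched <- function(pred_keys, gold_keys) {
  if (!length(pred_keys) || !length(gold_keys)) return(0L)
  np <- length(pred_keys); ng <- length(gold_keys)
  edges <- integer(0)
  for (i in seq_len(np)) {
    for (j in seq_len(ng)) {
      if (pred_keys[i] == gold_keys[j]) edges <- c(edges, i, np + j)
    }
  }
  if (!length(edges)) return(0L)
  g <- igraph::make_bipartite_graph(c(rep(FALSE, np), rep(TRUE, ng)), edges)
  igraph::max_bipartite_match(g)$matching_size
}
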