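#' @title Synthetic ontologies, corpora and oracle states
#'
#' @description
#' Generates mini-ontologies (rare diseases, diseases, phenotypes,
#' association triples), gold-annotated corpora with exact character spans,
#' and oracle states for the mock backend, all deterministic per seed, so
#' the entire pipeline and its metrics are exercisable offline with
#' analytically known outcomes: under zero corruption the pipeline is a
#' fixed point of its gold corpus (end-to-end P = R = F1 = 100), and under
#' an entity drop probability p the expected entity recall is 1 - p.
#'
#' Documents are template sentences embedding generated names: relation
#' sentences carry the gold relations (every gold mention participates in
#' at least one relation within its document), anaphor sentences follow a
#' rare-disease sentence in the same paragraph, negation sentences mention
#' a phenotype that is gold-excluded, and a configurable fraction of
#' relations straddles adjacent paragraphs to exercise bridge windows.
#'
#' @name synthetic_fixtures
NULL

#' Specify a synthetic fixture
#'
#' Defaults emulate the statistical shape of a rare-disease abstract
#' corpus: entity occurrences approximately 34% rare_disease, 40%
#' symptom_and_sign, 15% disease and 11% anaphor, with `produces` dominating
#' the relation mix.
#'
#' @param n_rare_diseases,n_diseases,n_phenotypes Ontology sizes.
#' @param n_docs Number of documents.
#' @param entities_per_doc Range (lo, hi) of gold entity mentions per
#'   document.
#' @param relation_mix Named probabilities over the six relation types
#'   (normalized to sum to 1).
#' @param anaphor_rate When non-`NULL`, overrides the `anaphora` component
#'   of the mix.
#' @param cross_boundary_rate Fraction of `produces` relations rendered
#'   across adjacent paragraph boundaries.
#' @param negation_rate Probability a paragraph carries a negated (gold
#'   excluded) phenotype mention.
#' @param seed Integer seed; everything downstream is deterministic in it.
#' @return An `rd_fixture_spec`.
#' @export
fixture_spec <- function(n_rare_diseases = 12L, n_diseases = 8L,
                         n_phenotypes = 20L, n_docs = 20L,
                         entities_per_doc = c(5L, 10L),
                         relation_mix = c(produces = 0.57,
                                          increases_risk_of = 0.06,
                                          is_a = 0.09, is_acron = 0.04,
                                          is_synon = 0.04, anaphora = 0.20),
                         anaphor_rate = NULL, cross_boundary_rate = 0,
                         negation_rate = 0.15, seed = 1L) {
  stopifnot(length(entities_per_doc) == 2L,
            entities_per_doc[1] <= entities_per_doc[2],
            all(relation_mix >= 0), sum(relation_mix) > 0,
            cross_boundary_rate >= 0, cross_boundary_rate <= 1,
            negation_rate >= 0, negation_rate <= 1)
  mix <- relation_mix[RELATION_TYPES]
  mix[is.na(mix)] <- 0
  names(mix) <- RELATION_TYPES
  if (!is.null(anaphor_rate)) {
    stopifnot(anaphor_rate >= 0, anaphor_rate <= 1)
    rest <- sum(mix[names(mix) != "anaphora"])
    if (rest > 0) {
      mix[names(mix) != "anaphora"] <-
        mix[names(mix) != "anaphora"] / rest * (1 - anaphor_rate)
    }
    mix["anaphora"] <- anaphor_rate
  }
  mix <- mix / sum(mix)
  structure(list(n_rare_diseases = as.integer(n_rare_diseases),
                 n_diseases = as.integer(n_diseases),
                 n_phenotypes = as.integer(n_phenotypes),
                 n_docs = as.integer(n_docs),
                 entities_per_doc = as.integer(entities_per_doc),
                 relation_mix = mix,
                 cross_boundary_rate = cross_boundary_rate,
                 negation_rate = negation_rate, seed = as.integer(seed)),
            class = "rd_fixture_spec")
}

SYLLABLES <- c("va", "len", "mor", "ni", "tal", "ru", "ket", "lin", "dor",
               "sa", "bel", "tri", "gan", "hel", "pex", "zam", "cor", "ful",
               "mir", "osk")

make_words <- function(n, seen = character(0)) {
  out <- character(0)
  while (length(out) < n) {
    w <- paste(sample(SYLLABLES, sample(2:3, 1L), replace = TRUE),
               collapse = "")
    if (!(w %in% seen) && !(w %in% out)) out <- c(out, w)
  }
  out
}

cap <- function(x) paste0(toupper(substring(x, 1L, 1L)), substring(x, 2L))

#' Generate a synthetic ontology fixture
#'
#' Synthesizes pronounceable unique names with definitions and
#' rare-disease/phenotype association triples (each rare disease linked to
#' 1-5 phenotypes with an occurrence-frequency qualifier). Half of the rare
#' diseases carry one synonym and a derived acronym. When `dir` is given,
#' the fixture is also written in both dialects: OBO term stanzas and the
#' compiled TSV.
#'
#' @param spec An `rd_fixture_spec`.
#' @param dir Optional output directory.
#' @return List: `rare` / `concepts` (term lists consumable by the lexicon
#'   compilers), `associations` (data.frame), `rare_names`,
#'   `disease_names`, `phenotype_names`, `acronym_of`, `synonym_of`,
#'   and `files` when written.
#' @export
generate_ontology_fixture <- function(spec, dir = NULL) {
  with_seed(spec$seed, {
    words <- make_words(spec$n_rare_diseases + spec$n_diseases +
                          spec$n_phenotypes + spec$n_rare_diseases)
    i <- 0L
    take <- function(n) {
      out <- words[seq_len(n) + i]
      i <<- i + n
      out
    }
    rare_names <- paste(cap(take(spec$n_rare_diseases)),
                        sample(c("syndrome", "disease"),
                               spec$n_rare_diseases, replace = TRUE))
    disease_names <- if (spec$n_diseases)
      paste0(take(spec$n_diseases),
             sample(c("itis", "osis", "opathy", "oma"), spec$n_diseases,
                    replace = TRUE)) else character(0)
    phen_names <- if (spec$n_phenotypes)
      paste0(take(spec$n_phenotypes),
             sample(c("algia", "emia", "penia", "pnea", "uria"),
                    spec$n_phenotypes, replace = TRUE)) else character(0)
    syn_words <- take(spec$n_rare_diseases)
    synonym_of <- character(0)
    acronym_of <- character(0)
    rare <- lapply(seq_along(rare_names), function(k) {
      nm <- rare_names[k]
      syns <- character(0)
      if (k %% 2L == 0L) {
        syn <- paste(cap(syn_words[k]), "disorder")
        syns <- syn
        synonym_of[syn] <<- nm
      }
      acr <- toupper(substring(gsub(" .*$", "", nm), 1L, 3L))
      acr <- paste0(acr, k)  # numbered to keep acronyms unique
      acronym_of[acr] <<- nm
      list(id = sprintf("RD:%04d", k), name = nm, synonyms = syns,
           def = paste0("A rare disorder named ", nm, "."), obsolete = FALSE)
    })
    concepts <- c(
      lapply(seq_along(disease_names), function(k) {
        list(id = sprintf("DIS:%04d", k), name = disease_names[k],
             synonyms = character(0),
             def = paste0("A disease named ", disease_names[k], "."),
             obsolete = FALSE, category = "disease")
      }),
      lapply(seq_along(phen_names), function(k) {
        list(id = sprintf("PH:%04d", k), name = phen_names[k],
             synonyms = character(0),
             def = paste0("A phenotypic abnormality named ", phen_names[k], "."),
             obsolete = FALSE, category = "phenotype")
      }))
    freq <- c("Very frequent", "Frequent", "Occasional", "Very rare")
    assoc <- if (length(phen_names)) {
      do.call(rbind, lapply(rare_names, function(nm) {
        k <- sample(1:min(5L, length(phen_names)), 1L)
        data.frame(rare_disease = nm,
                   frequency = sample(freq, k, replace = TRUE),
                   phenotype = sample(phen_names, k), stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(rare_disease = character(0), frequency = character(0),
                 phenotype = character(0), stringsAsFactors = FALSE)
    }
    out <- list(rare = rare, concepts = concepts, associations = assoc,
                rare_names = rare_names, disease_names = disease_names,
                phenotype_names = phen_names, acronym_of = acronym_of,
                synonym_of = synonym_of)
    if (!is.null(dir)) out$files <- write_ontology_fixture(out, dir)
    out
  })
}

write_ontology_fixture <- function(onto, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obo_stanza <- function(t, extra = character(0)) {
    c("[Term]", paste0("id: ", t$id), paste0("name: ", t$name),
      sprintf('def: "%s" []', t$def),
      sprintf('synonym: "%s" EXACT []', t$synonyms),
      extra, "")
  }
  rare_obo <- file.path(dir, "rare_diseases.obo")
  writeLines(c("format-version: 1.2", "",
               unlist(lapply(onto$rare, obo_stanza))), rare_obo)
  concept_obo <- file.path(dir, "concepts.obo")
  writeLines(c("format-version: 1.2", "",
               unlist(lapply(onto$concepts, function(t) {
                 obo_stanza(t, if (identical(t$category, "phenotype"))
                   "subset: phenotype" else character(0))
               }))), concept_obo)
  tsv_of <- function(terms, path, with_category = FALSE) {
    df <- do.call(rbind, lapply(terms, function(t) {
      row <- data.frame(id = t$id, name = t$name,
                        synonyms = paste(t$synonyms, collapse = "|"),
                        definition = t$def, stringsAsFactors = FALSE)
      if (with_category) row$category <- t$category %||% "disease"
      row
    }))
    if (is.null(df)) {
      df <- data.frame(id = character(0), name = character(0),
                       synonyms = character(0), definition = character(0))
      if (with_category) df$category <- character(0)
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    path
  }
  rare_tsv <- tsv_of(onto$rare, file.path(dir, "rare_diseases.tsv"))
  concept_tsv <- tsv_of(onto$concepts, file.path(dir, "concepts.tsv"), TRUE)
  assoc_tsv <- file.path(dir, "associations.tsv")
  utils::write.table(onto$associations, assoc_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  c(rare_obo = rare_obo, concept_obo = concept_obo, rare_tsv = rare_tsv,
    concept_tsv = concept_tsv, assoc_tsv = assoc_tsv)
}

#' Compile a knowledge base from an in-memory ontology fixture
#'
#' @param onto From [generate_ontology_fixture()].
#' @return An `rd_kb`.
#' @export
fixture_kb <- function(onto) {
  knowledge_base(
    compile_rare_disease_lexicon(onto$rare),
    compile_concept_lexicon(onto$concepts),
    compile_association_index(onto$associations))
}

ANAPHOR_SURFACES <- c("This disease", "This disorder", "This condition",
                      "This syndrome")

# A sentence is a list of pieces: bare strings, or mention pieces
# list(surface, type, ref = local key). Events carry sentences plus
# relations over local keys; `split = TRUE` marks a produces event whose
# two sentences must straddle a paragraph boundary.
mention <- function(surface, type, ref) {
  list(surface = surface, type = type, ref = ref)
}

#' Generate a gold-annotated synthetic corpus
#'
#' @param spec An `rd_fixture_spec`.
#' @param onto From [generate_ontology_fixture()].
#' @param dir Optional directory: each document is also written as BRAT
#'   standoff (`.txt` + `.ann`).
#' @return List of `rd_document` with exact spans and mention-level
#'   relations.
#' @export
generate_corpus <- function(spec, onto, dir = NULL) {
  docs <- with_seed(spec$seed + 1L, {
    lapply(seq_len(spec$n_docs), function(d) {
      generate_document(sprintf("doc%03d", d), spec, onto)
    })
  })
  if (!is.null(dir)) for (doc in docs) write_standoff(doc, dir)
  docs
}

generate_document <- function(doc_id, spec, onto) {
  rd_pool <- sample(onto$rare_names, min(3L, length(onto$rare_names)))
  dis_pool <- sample(onto$disease_names,
                     min(4L, length(onto$disease_names)))
  target <- sample(spec$entities_per_doc[1]:spec$entities_per_doc[2], 1L)
  used_triples <- character(0)
  used_pairs <- character(0)
  events <- list()
  n_mentions <- 0L
  guard <- 0L
  fresh_pair <- function(subjects, objects) {
    for (k in 1:8) {
      s <- sample(subjects, 1L); o <- sample(objects, 1L)
      if (identical(s, o)) next
      key <- paste(s, o)
      if (!(key %in% used_pairs)) {
        used_pairs <<- c(used_pairs, key)
        return(c(s, o))
      }
    }
    NULL
  }
  add_triple <- function(s, type, o) {
    key <- paste(normalize_name(s), type, normalize_name(o))
    if (key %in% used_triples) return(FALSE)
    used_triples <<- c(used_triples, key)
    TRUE
  }
  while (n_mentions < target && guard < 200L) {
    guard <- guard + 1L
    ev_type <- sample(RELATION_TYPES, 1L, prob = spec$relation_mix)
    ev <- make_event(ev_type, rd_pool, dis_pool, onto, fresh_pair, add_triple)
    if (is.null(ev)) next
    if (ev$type == "produces" && stats::runif(1L) < spec$cross_boundary_rate) {
      ev <- split_produces_event(ev)
    }
    events[[length(events) + 1L]] <- ev
    n_mentions <- n_mentions + ev$n_mentions
  }
  assemble_document(doc_id, events, spec, onto)
}

make_event <- function(ev_type, rd_pool, dis_pool, onto, fresh_pair,
                       add_triple) {
  phen <- onto$phenotype_names
  if (ev_type == "produces" || ev_type == "anaphora") {
    if (ev_type == "anaphora" && !length(rd_pool)) return(NULL)
    subj_rare <- length(rd_pool) && (ev_type == "anaphora" ||
                                       stats::runif(1L) < 0.65 ||
                                       !length(dis_pool))
    subjects <- if (subj_rare) rd_pool else dis_pool
    if (!length(subjects) || !length(phen)) return(NULL)
    pair <- fresh_pair(subjects, phen)
    if (is.null(pair)) return(NULL)
    if (!add_triple(pair[1L], "produces", pair[2L])) return(NULL)
    s1 <- list(mention(pair[1L], if (subj_rare) "rare_disease" else "disease", "s"),
               " produces ", mention(pair[2L], "symptom_and_sign", "o"), ".")
    rels <- data.frame(relation_type = "produces", subject = "s",
                       object = "o", stringsAsFactors = FALSE)
    if (ev_type == "anaphora") {
      pair2 <- fresh_pair(ANAPHOR_SURFACES, phen)
      if (is.null(pair2)) {
        return(list(type = "produces", sentences = list(s1), relations = rels,
                    n_mentions = 2L, split = FALSE))
      }
      ana <- pair2[1L]; p2 <- pair2[2L]
      if (!add_triple(ana, "anaphora", pair[1L]) ||
          !add_triple(ana, "produces", p2)) {
        return(list(type = "produces", sentences = list(s1), relations = rels,
                    n_mentions = 2L, split = FALSE))
      }
      s2 <- list(mention(ana, "anaphor", "a"), " also produces ",
                 mention(p2, "symptom_and_sign", "o2"), ".")
      rels <- rbind(rels,
                    data.frame(relation_type = c("anaphora", "produces"),
                               subject = c("a", "a"), object = c("s", "o2"),
                               stringsAsFactors = FALSE))
      return(list(type = "anaphora", sentences = list(s1, s2),
                  relations = rels, n_mentions = 4L, split = FALSE))
    }
    return(list(type = "produces", sentences = list(s1), relations = rels,
                n_mentions = 2L, split = FALSE))
  }
  if (ev_type == "increases_risk_of") {
    if (!length(rd_pool) || !length(dis_pool)) return(NULL)
    pair <- fresh_pair(rd_pool, dis_pool)
    if (is.null(pair) || !add_triple(pair[1L], "increases_risk_of", pair[2L])) {
      return(NULL)
    }
    s <- list(mention(pair[1L], "rare_disease", "s"),
              " increases the risk of ", mention(pair[2L], "disease", "o"), ".")
    return(list(type = ev_type, sentences = list(s),
                relations = data.frame(relation_type = ev_type, subject = "s",
                                       object = "o", stringsAsFactors = FALSE),
                n_mentions = 2L, split = FALSE))
  }
  if (ev_type == "is_a") {
    if (!length(rd_pool) || !length(dis_pool)) return(NULL)
    pair <- fresh_pair(rd_pool, dis_pool)
    if (is.null(pair) || !add_triple(pair[1L], "is_a", pair[2L])) return(NULL)
    s <- list(mention(pair[1L], "rare_disease", "s"), " is a form of ",
              mention(pair[2L], "disease", "o"), ".")
    return(list(type = ev_type, sentences = list(s),
                relations = data.frame(relation_type = ev_type, subject = "s",
                                       object = "o", stringsAsFactors = FALSE),
                n_mentions = 2L, split = FALSE))
  }
  if (ev_type == "is_acron") {
    acrs <- names(onto$acronym_of)[onto$acronym_of %in% rd_pool]
    if (!length(acrs)) return(NULL)
    acr <- sample(acrs, 1L)
    full <- unname(onto$acronym_of[acr])
    if (!add_triple(acr, "is_acron", full)) return(NULL)
    s <- list(mention(acr, "rare_disease", "s"), " is short for ",
              mention(full, "rare_disease", "o"), ".")
    return(list(type = ev_type, sentences = list(s),
                relations = data.frame(relation_type = ev_type, subject = "s",
                                       object = "o", stringsAsFactors = FALSE),
                n_mentions = 2L, split = FALSE))
  }
  if (ev_type == "is_synon") {
    syns <- names(onto$synonym_of)[onto$synonym_of %in% rd_pool]
    if (!length(syns)) return(NULL)
    syn <- sample(syns, 1L)
    full <- unname(onto$synonym_of[syn])
    if (!add_triple(syn, "is_synon", full)) return(NULL)
    s <- list(mention(syn, "rare_disease", "s"), " is another name for ",
              mention(full, "rare_disease", "o"), ".")
    return(list(type = ev_type, sentences = list(s),
                relations = data.frame(relation_type = ev_type, subject = "s",
                                       object = "o", stringsAsFactors = FALSE),
                n_mentions = 2L, split = FALSE))
  }
  NULL
}

split_produces_event <- function(ev) {
  subj <- ev$sentences[[1L]][[1L]]
  obj <- ev$sentences[[1L]][[3L]]
  s1 <- list(mention(subj$surface, subj$type, "s"),
             " warrants particular attention in affected families.")
  s2 <- list("Clinicians frequently observe ",
             mention(obj$surface, obj$type, "o"),
             " among these patients.")
  list(type = "produces", sentences = list(s1, s2),
       relations = ev$relations, n_mentions = 2L, split = TRUE)
}

assemble_document <- function(doc_id, events, spec, onto) {
  # Layout: sentences inside a paragraph joined by " ", paragraphs joined by
  # "\n\n"; offsets tracked exactly while linearizing. A split event pins
  # its first sentence to a paragraph end and its second to the next start.
  for (k in seq_along(events)) events[[k]]$uid <- k
  para_struct <- list()
  cur_s <- list()
  n_in_para <- 0L
  para_target <- sample(2:3, 1L)
  for (ev in events) {
    if (isTRUE(ev$split)) {
      cur_s[[length(cur_s) + 1L]] <- list(ev = ev, sent = 1L)
      para_struct[[length(para_struct) + 1L]] <- cur_s
      cur_s <- list(list(ev = ev, sent = 2L))
      n_in_para <- 1L
      para_target <- sample(2:3, 1L)
    } else {
      for (j in seq_along(ev$sentences)) {
        cur_s[[length(cur_s) + 1L]] <- list(ev = ev, sent = j)
      }
      n_in_para <- n_in_para + length(ev$sentences)
      if (n_in_para >= para_target) {
        para_struct[[length(para_struct) + 1L]] <- cur_s
        cur_s <- list()
        n_in_para <- 0L
        para_target <- sample(2:3, 1L)
      }
    }
  }
  if (length(cur_s)) para_struct[[length(para_struct) + 1L]] <- cur_s
  # add negation sentences; never after the first half of a split event,
  # which must stay adjacent to its continuation in the next paragraph
  if (spec$negation_rate > 0 && length(onto$phenotype_names)) {
    for (k in seq_along(para_struct)) {
      last <- para_struct[[k]][[length(para_struct[[k]])]]
      splits_next <- !is.null(last$ev) && isTRUE(last$ev$split) &&
        last$sent == 1L
      if (!splits_next && stats::runif(1L) < spec$negation_rate) {
        para_struct[[k]][[length(para_struct[[k]]) + 1L]] <-
          list(neg = sample(onto$phenotype_names, 1L))
      }
    }
  }
  # linearize with exact offsets
  text <- ""
  pos <- 0L
  mid <- 0L
  rid <- 0L
  ents <- list()
  rels <- list()
  ref_map <- new.env(parent = emptyenv())  # "uid:ref" -> mention_id
  append_text <- function(s) {
    text <<- paste0(text, s)
    pos <<- pos + nchar(s)
  }
  for (p in seq_along(para_struct)) {
    if (p > 1L) append_text("\n\n")
    first <- TRUE
    for (item in para_struct[[p]]) {
      if (!first) append_text(" ")
      first <- FALSE
      if (!is.null(item$neg)) {
        append_text(sprintf("There was no evidence of %s.", item$neg))
        next
      }
      uid <- item$ev$uid
      for (piece in item$ev$sentences[[item$sent]]) {
        if (is.character(piece)) {
          append_text(piece)
        } else {
          start <- pos
          append_text(piece$surface)
          mid <- mid + 1L
          id <- paste0("T", mid)
          ents[[length(ents) + 1L]] <- data.frame(
            mention_id = id, surface = piece$surface,
            entity_type = piece$type, start = start, end = pos,
            stringsAsFactors = FALSE)
          assign(paste0(uid, ":", piece$ref), id, envir = ref_map)
        }
      }
    }
  }
  for (ev in events) {
    for (i in seq_len(nrow(ev$relations))) {
      rid <- rid + 1L
      subj <- get0(paste0(ev$uid, ":", ev$relations$subject[i]),
                   envir = ref_map)
      obj <- get0(paste0(ev$uid, ":", ev$relations$object[i]),
                  envir = ref_map)
      if (is.null(subj) || is.null(obj)) next
      rels[[length(rels) + 1L]] <- data.frame(
        rel_id = paste0("R", rid), relation_type = ev$relations$relation_type[i],
        subject_ref = subj, object_ref = obj, stringsAsFactors = FALSE)
    }
  }
  rd_document(doc_id, text,
              if (length(ents)) do.call(rbind, ents) else empty_entities(),
              if (length(rels)) do.call(rbind, rels) else empty_relations())
}

#' Build an oracle state for the mock backend
#'
#' @param corpus List of gold `rd_document`.
#' @param corruption List with any of `entity_drop_p`, `type_confuse_p`,
#'   `relation_drop_p`, `spurious_rate` (all default 0). With all zero the
#'   mock reproduces gold exactly; with `entity_drop_p = p` the expected
#'   entity recall is `1 - p`.
#' @param seed Integer seed for the corruption streams.
#' @return An `rd_oracle`.
#' @export
build_oracle <- function(corpus, corruption = list(), seed = 1L) {
  cr <- list(entity_drop_p = 0, type_confuse_p = 0, relation_drop_p = 0,
             spurious_rate = 0)
  for (k in names(corruption)) {
    if (!k %in% names(cr)) stop("unknown corruption parameter: ", k)
    stopifnot(corruption[[k]] >= 0, corruption[[k]] <= 1)
    cr[[k]] <- corruption[[k]]
  }
  docs <- stats::setNames(corpus, vapply(corpus, `[[`, "", "doc_id"))
  structure(list(docs = docs, corruption = cr, seed = as.integer(seed)),
            class = "rd_oracle")
}
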