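#' @title Extraction pipeline
#'
#' @description
#' End-to-end orchestration: segmentation, the three-step entity extraction
#' (dictionary matching, term expansion, typed entity extraction), relation
#' extraction with association-triple knowledge, bridge-window relation
#' re-extraction across segment boundaries, deduplication, and entity
#' calibration. The final entity set is the model's step-3 output —
#' dictionary matches are hints, not guarantees.
#'
#' @name extraction_pipeline
NULL

#' Configure a pipeline run
#'
#' @param backend An `rd_backend` from [backend_config()].
#' @param toggles [ablation_toggles()].
#' @param max_tokens Segment token budget (default 2000).
#' @param bridge_tokens Bridge window width in tokens (default 1000).
#' @param use_bridge Re-extract relations across segment boundaries.
#' @param calibration `"both"` (zero-relation rule, then model
#'   confirmation), `"rule"`, `"llm"`, or `"none"`.
#' @param exemplars_entity,exemplars_relation Exemplar lists from
#'   [select_exemplars()].
#' @param budget_tokens Instruction-token budget per prompt.
#' @param negation `rd_negation_lexicon` for the dictionary matcher.
#' @return An `rd_pipeline_config`.
#' @export
pipeline_config <- function(backend, toggles = ablation_toggles(),
                            max_tokens = 2000L, bridge_tokens = 1000L,
                            use_bridge = TRUE,
                            calibration = c("both", "rule", "llm", "none"),
                            exemplars_entity = list(),
                            exemplars_relation = list(),
                            budget_tokens = 1000L,
                            negation = negation_lexicon()) {
  calibration <- match.arg(calibration)
  stopifnot(inherits(backend, "rd_backend"))
  structure(list(backend = backend, toggles = toggles,
                 max_tokens = as.integer(max_tokens),
                 bridge_tokens = as.integer(bridge_tokens),
                 use_bridge = use_bridge, calibration = calibration,
                 exemplars_entity = exemplars_entity,
                 exemplars_relation = exemplars_relation,
                 budget_tokens = as.integer(budget_tokens),
                 negation = negation),
            class = "rd_pipeline_config")
}

#' Extract typed entities from one segment
#'
#' Step 1: dictionary matching with negation flags. Step 2: model-driven
#' term expansion and anaphor identification. Step 3: typed entity
#' extraction with rare-disease knowledge injected for candidates that hit
#' the rare-disease lexicon. The step-3 output is authoritative; entities
#' with types outside the working type system are dropped with a warning.
#'
#' @param segment An `rd_segment`.
#' @param kb An `rd_kb`.
#' @param config An `rd_pipeline_config`.
#' @return data.frame: `surface`, `entity_type`, `start`, `end` (absolute
#'   document offsets when the backend reports them), `provenance`.
#' @export
extract_entities <- function(segment, kb, config) {
  matches <- annotate_negation(match_terms(segment$text, kb$concept_lexicon),
                               segment$text, config$negation)
  p1 <- render_extract_more_terms(segment, matches, config$toggles)
  r1 <- parse_json_payload(complete(config$backend, p1)$response_text,
                           c("terms", "anaphors"))
  terms <- unique(c(matches$surface, unlist(r1$terms, use.names = FALSE)))
  anaphors <- unique(unlist(r1$anaphors, use.names = FALSE))
  hits <- Filter(Negate(is.null), lapply(terms, lookup_rare_disease, kb = kb))
  rd_knowledge <- if (length(hits)) {
    data.frame(name = vapply(hits, `[[`, "", "preferred_name"),
               definition = vapply(hits, `[[`, "", "definition"),
               stringsAsFactors = FALSE)
  } else NULL
  p2 <- render_entity_prompt(segment, terms, anaphors,
                             config$exemplars_entity, rd_knowledge,
                             config$toggles, config$budget_tokens)
  r2 <- parse_json_payload(complete(config$backend, p2)$response_text,
                           "entities")
  parse_entity_items(r2$entities, segment)
}

parse_entity_items <- function(items, segment) {
  out <- empty_pred_entities()
  dropped <- character(0)
  for (e in items) {
    type <- as.character(e$type %||% "")
    if (!type %in% ENTITY_TYPES) {
      dropped <- c(dropped, paste0(e$name %||% "?", ":", type))
      next
    }
    start <- suppressWarnings(as.integer(e$start %||% NA))
    end <- suppressWarnings(as.integer(e$end %||% NA))
    if (!is.na(start)) {
      # offsets are absolute document positions; verify against the segment
      rel <- start - segment$char_start
      got <- substring(segment$text, rel + 1L, end - segment$char_start)
      if (!identical(got, as.character(e$name))) { start <- NA_integer_; end <- NA_integer_ }
    }
    out <- rbind(out, data.frame(
      surface = as.character(e$name), entity_type = type, start = start,
      end = end,
      provenance = paste0("llm_entities:",
                          if (segment$is_bridge) "bridge" else "segment",
                          segment$seg_index),
      stringsAsFactors = FALSE))
  }
  if (length(dropped)) {
    warning("dropped entity(ies) with types outside the type system: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  out
}

#' Extract relations among a segment's entities
#'
#' Renders the relation prompt (with association triples for any
#' rare-disease entity when knowledge is enabled), parses the response and
#' filters it: unknown relation types, relations whose subject or object is
#' not among the provided entities, and anaphora relations whose antecedent
#' is not a rare disease are dropped with a warning.
#'
#' @param segment An `rd_segment` (segment or bridge window).
#' @param entities data.frame of extracted entities fed to the prompt.
#' @param kb An `rd_kb`.
#' @param config An `rd_pipeline_config`.
#' @return data.frame: `subject`, `relation_type`, `object`, `provenance`.
#' @export
extract_relations <- function(segment, entities, kb, config) {
  rds <- unique(entities$surface[entities$entity_type == "rare_disease"])
  assoc <- if (length(rds)) {
    do.call(rbind, lapply(rds, lookup_associations, kb = kb))
  } else NULL
  prompt <- render_relation_prompt(segment, entities, assoc,
                                   config$exemplars_relation, config$toggles,
                                   config$budget_tokens)
  parsed <- parse_json_payload(complete(config$backend, prompt)$response_text,
                               "relations")
  keys <- normalize_name(entities$surface)
  rd_keys <- keys[entities$entity_type == "rare_disease"]
  out <- empty_pred_relations()
  n_drop <- 0L
  for (r in parsed$relations) {
    type <- as.character(r$type %||% "")
    subj <- as.character(r$subject %||% "")
    obj <- as.character(r$object %||% "")
    ok <- type %in% RELATION_TYPES &&
      normalize_name(subj) %in% keys && normalize_name(obj) %in% keys &&
      (type != "anaphora" || normalize_name(obj) %in% rd_keys)
    if (!ok) { n_drop <- n_drop + 1L; next }
    out <- rbind(out, data.frame(
      subject = subj, relation_type = type, object = obj,
      provenance = if (segment$is_bridge) paste0("bridge", segment$seg_index)
                   else paste0("segment", segment$seg_index),
      stringsAsFactors = FALSE))
  }
  if (n_drop) {
    warning(n_drop, " relation(s) dropped (unknown type, unresolved ",
            "endpoint, or non-rare-disease antecedent)", call. = FALSE)
  }
  out
}

#' Calibrate an entity set against its relations
#'
#' Entities participating in no relation are likely irrelevant; the rule
#' mode removes them, the llm mode asks the backend to confirm a retained
#' subset (constrained to the input), and `both` applies the rule first.
#' Relations referencing a removed entity are removed too. Output entities
#' are always a subset of the input.
#'
#' @param entities,relations Prediction data.frames (see
#'   [extract_entities()], [extract_relations()]).
#' @param config An `rd_pipeline_config` (uses its backend for llm mode).
#' @param doc_id Document id for the calibration prompt.
#' @param mode Override of `config$calibration`.
#' @return list(entities, relations).
#' @export
calibrate <- function(entities, relations, config, doc_id = "doc",
                      mode = config$calibration) {
  if (mode %in% c("rule", "both") && nrow(entities)) {
    related <- normalize_name(c(relations$subject, relations$object))
    entities <- entities[normalize_name(entities$surface) %in% related, ,
                         drop = FALSE]
  }
  if (mode %in% c("llm", "both") && nrow(entities)) {
    prompt <- render_calibration_prompt(entities, relations, doc_id)
    parsed <- parse_json_payload(complete(config$backend, prompt)$response_text,
                                 "entities")
    retained <- normalize_name(unlist(parsed$entities, use.names = FALSE))
    entities <- entities[normalize_name(entities$surface) %in% retained, ,
                         drop = FALSE]
  }
  keys <- normalize_name(entities$surface)
  if (nrow(relations)) {
    keep <- normalize_name(relations$subject) %in% keys &
      normalize_name(relations$object) %in% keys
    relations <- relations[keep, , drop = FALSE]
  }
  list(entities = entities, relations = relations)
}

#' Run the full pipeline on one document
#'
#' Segments the text, extracts entities and relations per segment,
#' re-extracts relations over bridge windows (feeding them the entities
#' from the flanking segments whose spans fall inside the window),
#' deduplicates (entities at the occurrence level only when spans coincide;
#' relations by subject/type/object), calibrates, and returns the result.
#'
#' @param doc_text Document text.
#' @param doc_id Document id.
#' @param kb An `rd_kb`.
#' @param config An `rd_pipeline_config`.
#' @return An `rd_extraction`.
#' @export
run_document <- function(doc_text, doc_id, kb, config) {
  segs <- segment_document(doc_text, config$max_tokens, doc_id)
  ents <- empty_pred_entities()
  rels <- empty_pred_relations()
  seg_entities <- vector("list", length(segs))
  for (k in seq_along(segs)) {
    e <- extract_entities(segs[[k]], kb, config)
    seg_entities[[k]] <- e
    ents <- rbind(ents, e)
    rels <- rbind(rels, extract_relations(segs[[k]], e, kb, config))
  }
  if (config$use_bridge && length(segs) > 1L) {
    for (bw in bridge_windows(segs, config$bridge_tokens, doc_text)) {
      k <- bw$seg_index + 1L  # boundary between segs k and k+1
      flank <- rbind(seg_entities[[k]], seg_entities[[k + 1L]])
      inside <- !is.na(flank$start) & flank$start >= bw$char_start &
        flank$end <= bw$char_end
      rels <- rbind(rels, extract_relations(bw, flank[inside, , drop = FALSE],
                                            kb, config))
    }
  }
  # dedup: entity occurrences only when spans coincide; relations by triple
  if (nrow(ents)) {
    has_span <- !is.na(ents$start)
    key <- ifelse(has_span,
                  paste(ents$surface, ents$entity_type, ents$start, ents$end),
                  paste("nospan", seq_len(nrow(ents))))
    ents <- ents[!duplicated(key), , drop = FALSE]
  }
  if (nrow(rels)) {
    key <- paste(normalize_name(rels$subject), rels$relation_type,
                 normalize_name(rels$object))
    rels <- rels[!duplicated(key), , drop = FALSE]
  }
  if (config$calibration != "none") {
    cal <- calibrate(ents, rels, config, doc_id)
    ents <- cal$entities
    rels <- cal$relations
  }
  rownames(ents) <- NULL
  rownames(rels) <- NULL
  new_extraction(doc_id, ents, rels)
}

#' Run the pipeline over a corpus
#'
#' @param docs List of `rd_document` (their gold annotations are not
#'   consulted; only text and id are used).
#' @param kb An `rd_kb`.
#' @param config An `rd_pipeline_config`.
#' @return List of `rd_extraction`.
#' @export
run_corpus <- function(docs, kb, config) {
  lapply(docs, function(d) run_document(d$text, d$doc_id, kb, config))
}
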