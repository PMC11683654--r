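#' @title Prompt rendering
#'
#' @description
#' Four prompt stages drive the pipeline: `extract_more_terms`,
#' `extract_entities`, `extract_relations` and `calibrate`. Every prompt is
#' assembled from the same fixed section skeleton — stage marker, task
#' description, type definitions, notice (guidelines), exemplars, knowledge
#' and input slots, output format — with the wording of the static sections
#' shipped as editable text files under `inst/templates/`. Rendering is pure
#' and deterministic; the three ablation toggles only add or remove whole
#' sections.
#'
#' @name prompting
NULL

PROMPT_STAGES <- c("extract_more_terms", "extract_entities",
                   "extract_relations", "calibrate")

template_text <- function(name, dir = NULL) {
  path <- if (!is.null(dir) && file.exists(file.path(dir, paste0(name, ".txt")))) {
    file.path(dir, paste0(name, ".txt"))
  } else {
    system.file("templates", paste0(name, ".txt"), package = "raremine")
  }
  if (!nzchar(path) || !file.exists(path)) stop("missing template: ", name)
  paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n")
}

#' Ablation toggles
#'
#' @param use_knowledge Include ontology knowledge slots (rare-disease
#'   definitions, association triples).
#' @param use_exemplars Include gold input-output exemplars.
#' @param use_notice Include the hand-tuned guideline block.
#' @return An `rd_toggles` list.
#' @export
ablation_toggles <- function(use_knowledge = TRUE, use_exemplars = TRUE,
                             use_notice = TRUE) {
  structure(list(use_knowledge = use_knowledge, use_exemplars = use_exemplars,
                 use_notice = use_notice), class = "rd_toggles")
}

make_stage_marker <- function(stage, doc_id, span_start = 0L, span_end = 0L,
                              kind = "segment") {
  sprintf("#>raremine stage=%s doc=%s span=%d:%d kind=%s", stage, doc_id,
          as.integer(span_start), as.integer(span_end), kind)
}

# Recover the routing information the mock backend needs. Returns NULL when
# the first line is not a marker.
parse_stage_marker <- function(prompt_text) {
  first <- strsplit(prompt_text, "\n", fixed = TRUE)[[1L]][1L]
  m <- regexec("^#>raremine stage=(\\S+) doc=(\\S+) span=(\\d+):(\\d+) kind=(\\S+)$",
               first)
  p <- regmatches(first, m)[[1L]]
  if (length(p) != 6L) return(NULL)
  list(stage = p[2L], doc = p[3L], span_start = as.integer(p[4L]),
       span_end = as.integer(p[5L]), kind = p[6L])
}

section <- function(title, body) paste0("## ", title, "\n", body)

assemble_prompt <- function(marker, parts) {
  paste(c(marker, parts[nzchar(parts)]), collapse = "\n\n")
}

#' Select exemplars from the training set
#'
#' Seeded uniform sample without replacement of `k` gold documents, each
#' serialized as an input-output pair in the requested stage's JSON schema.
#'
#' @param train_docs List of gold `rd_document`.
#' @param k Number of exemplars (default 5).
#' @param seed RNG seed.
#' @param stage `"extract_entities"` or `"extract_relations"`.
#' @return List of exemplars: `input_text`, `gold_output_json`,
#'   `source_doc_id`.
#' @export
select_exemplars <- function(train_docs, k = 5L, seed = 1L,
                             stage = c("extract_entities", "extract_relations")) {
  stage <- match.arg(stage)
  if (k > length(train_docs)) {
    stop("k = ", k, " exceeds training set size ", length(train_docs))
  }
  if (k == 0L) return(list())
  idx <- with_seed(seed, sample.int(length(train_docs), k))
  lapply(train_docs[idx], function(d) {
    gold <- if (stage == "extract_entities") {
      jsonlite::toJSON(list(entities = lapply(seq_len(nrow(d$entities)),
        function(i) list(name = d$entities$surface[i],
                         type = d$entities$entity_type[i]))),
        auto_unbox = TRUE)
    } else {
      surf <- stats::setNames(d$entities$surface, d$entities$mention_id)
      jsonlite::toJSON(list(relations = lapply(seq_len(nrow(d$relations)),
        function(i) list(subject = unname(surf[d$relations$subject_ref[i]]),
                         type = d$relations$relation_type[i],
                         object = unname(surf[d$relations$object_ref[i]])))),
        auto_unbox = TRUE)
    }
    list(input_text = d$text, gold_output_json = as.character(gold),
         source_doc_id = d$doc_id)
  })
}

render_exemplar_block <- function(exemplars) {
  if (!length(exemplars)) return("")
  blocks <- vapply(seq_along(exemplars), function(i) {
    ex <- exemplars[[i]]
    sprintf("Example %d\nInput:\n%s\nOutput:\n%s", i, ex$input_text,
            ex$gold_output_json)
  }, character(1))
  section("Examples", paste(blocks, collapse = "\n\n"))
}

#' Render the extract-more-terms prompt
#'
#' Contains the segment text, the dictionary matches (with negation flags
#' and lexicon definitions, or an explicit "none found" marker), entity-type
#' definitions, the notice block when enabled, the anaphor instruction, and
#' the JSON output format.
#'
#' @param segment An `rd_segment`.
#' @param matches data.frame from [annotate_negation()].
#' @param toggles [ablation_toggles()].
#' @param template_dir Optional directory overriding packaged templates.
#' @return Prompt text.
#' @export
render_extract_more_terms <- function(segment, matches,
                                      toggles = ablation_toggles(),
                                      template_dir = NULL) {
  marker <- make_stage_marker("extract_more_terms", segment$doc_id,
                              segment$char_start, segment$char_end,
                              if (segment$is_bridge) "bridge" else "segment")
  match_lines <- if (nrow(matches)) {
    paste(sprintf("- %s%s%s", matches$surface,
                  ifelse(matches$negated, " [negated]", ""),
                  ifelse(nzchar(matches$definition),
                         paste0(" -- ", matches$definition), "")),
          collapse = "\n")
  } else "none found"
  assemble_prompt(marker, c(
    template_text("task_extract_more_terms", template_dir),
    template_text("definitions_entities", template_dir),
    if (toggles$use_notice) template_text("notice", template_dir) else "",
    section("Dictionary matches", match_lines),
    section("Passage", segment$text),
    template_text("output_extract_more_terms", template_dir)))
}

#' Render the entity-extraction prompt
#'
#' @param segment An `rd_segment`.
#' @param terms Character vector of candidate medical terms.
#' @param anaphors Character vector of candidate anaphors.
#' @param exemplars From [select_exemplars()] (entity stage).
#' @param rd_knowledge data.frame with columns `name`, `definition`:
#'   candidates confirmed as rare diseases by the ontology.
#' @param toggles [ablation_toggles()].
#' @param budget_tokens Instruction-token budget (segment text excluded);
#'   over budget, exemplars are dropped from the end, then knowledge lines
#'   truncated, never the segment.
#' @param template_dir Optional template override directory.
#' @return Prompt text.
#' @export
render_entity_prompt <- function(segment, terms, anaphors, exemplars = list(),
                                 rd_knowledge = NULL,
                                 toggles = ablation_toggles(),
                                 budget_tokens = 1000L, template_dir = NULL) {
  marker <- make_stage_marker("extract_entities", segment$doc_id,
                              segment$char_start, segment$char_end,
                              if (segment$is_bridge) "bridge" else "segment")
  build <- function(exemplars, knowledge_lines) {
    parts <- c(
      template_text("task_extract_entities", template_dir),
      template_text("definitions_entities", template_dir),
      if (toggles$use_notice) template_text("notice", template_dir) else "",
      if (toggles$use_exemplars) render_exemplar_block(exemplars) else "",
      section("Candidate medical terms",
              if (length(terms)) paste0("- ", terms, collapse = "\n")
              else "none found"),
      section("Candidate anaphors",
              if (length(anaphors)) paste0("- ", anaphors, collapse = "\n")
              else "none found"),
      if (toggles$use_knowledge) {
        section("Rare disease knowledge",
                if (length(knowledge_lines)) paste(knowledge_lines, collapse = "\n")
                else "none")
      } else "",
      section("Passage", segment$text),
      template_text("output_extract_entities", template_dir))
    assemble_prompt(marker, parts)
  }
  knowledge_lines <- if (!is.null(rd_knowledge) && nrow(rd_knowledge)) {
    sprintf("- %s is a rare disease.%s", rd_knowledge$name,
            ifelse(nzchar(rd_knowledge$definition),
                   paste0(" ", rd_knowledge$definition), ""))
  } else character(0)
  fit_to_budget(build, exemplars, knowledge_lines, segment, budget_tokens)
}

#' Render the relation-extraction prompt
#'
#' @param segment An `rd_segment`.
#' @param entities data.frame with `surface`, `entity_type` (the extracted
#'   entities of this segment).
#' @param associations data.frame of association triples (`rare_disease`,
#'   `frequency`, `phenotype`) for the rare-disease entities present.
#' @inheritParams render_entity_prompt
#' @param exemplars From [select_exemplars()] (relation stage).
#' @return Prompt text.
#' @export
render_relation_prompt <- function(segment, entities, associations = NULL,
                                   exemplars = list(),
                                   toggles = ablation_toggles(),
                                   budget_tokens = 1000L, template_dir = NULL) {
  marker <- make_stage_marker("extract_relations", segment$doc_id,
                              segment$char_start, segment$char_end,
                              if (segment$is_bridge) "bridge" else "segment")
  ent_lines <- if (nrow(entities)) {
    paste(sprintf("- %s | %s", entities$surface, entities$entity_type),
          collapse = "\n")
  } else "none"
  build <- function(exemplars, knowledge_lines) {
    parts <- c(
      template_text("task_extract_relations", template_dir),
      template_text("definitions_entities", template_dir),
      template_text("definitions_relations", template_dir),
      if (toggles$use_notice) template_text("notice", template_dir) else "",
      if (toggles$use_exemplars) render_exemplar_block(exemplars) else "",
      section("Entities", ent_lines),
      if (toggles$use_knowledge) {
        section("Known rare-disease associations",
                if (length(knowledge_lines)) paste(knowledge_lines, collapse = "\n")
                else "none")
      } else "",
      section("Passage", segment$text),
      template_text("output_extract_relations", template_dir))
    assemble_prompt(marker, parts)
  }
  knowledge_lines <- if (!is.null(associations) && nrow(associations)) {
    sprintf("- %s has the phenotype %s (%s).", associations$rare_disease,
            associations$phenotype, associations$frequency)
  } else character(0)
  fit_to_budget(build, exemplars, knowledge_lines, segment, budget_tokens)
}

#' Render the entity-calibration prompt
#'
#' Lists every entity with its relation participation count and asks for
#' the retained-entity list in JSON. Deterministic in its inputs.
#'
#' @param entities data.frame with `surface`, `entity_type`.
#' @param relations data.frame with `subject`, `relation_type`, `object`.
#' @param doc_id Document id for the stage marker.
#' @param template_dir Optional template override directory.
#' @return Prompt text.
#' @export
render_calibration_prompt <- function(entities, relations, doc_id = "doc",
                                      template_dir = NULL) {
  marker <- make_stage_marker("calibrate", doc_id, 0L, 0L, "doc")
  counts <- if (nrow(entities)) {
    vapply(seq_len(nrow(entities)), function(i) {
      key <- normalize_name(entities$surface[i])
      sum(normalize_name(relations$subject) == key |
            normalize_name(relations$object) == key)
    }, integer(1))
  } else integer(0)
  ent_lines <- if (nrow(entities)) {
    paste(sprintf("- %s | %s | relations=%d", entities$surface,
                  entities$entity_type, counts), collapse = "\n")
  } else "none"
  rel_lines <- if (nrow(relations)) {
    paste(sprintf("- %s %s %s", relations$subject, relations$relation_type,
                  relations$object), collapse = "\n")
  } else "none"
  assemble_prompt(marker, c(
    template_text("task_calibrate", template_dir),
    section("Entities", ent_lines),
    section("Relations", rel_lines),
    template_text("output_calibrate", template_dir)))
}

# Enforce the instruction-token budget: drop exemplars from the end, then
# truncate knowledge lines, never the segment text.
fit_to_budget <- function(build, exemplars, knowledge_lines, segment,
                          budget_tokens) {
  limit <- budget_tokens + segment$token_count
  prompt <- build(exemplars, knowledge_lines)
  while (count_tokens(prompt) > limit && length(exemplars)) {
    exemplars <- exemplars[-length(exemplars)]
    warning("prompt over budget: dropping an exemplar", call. = FALSE)
    prompt <- build(exemplars, knowledge_lines)
  }
  while (count_tokens(prompt) > limit && length(knowledge_lines)) {
    knowledge_lines <- knowledge_lines[-length(knowledge_lines)]
    warning("prompt over budget: truncating knowledge slot", call. = FALSE)
    prompt <- build(exemplars, knowledge_lines)
  }
  prompt
}
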