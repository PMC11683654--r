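#' @title Language-model runtime
#'
#' @description
#' All model access goes through [complete()], behind a backend contract:
#' the default backend is a deterministic fixture-driven mock that routes on
#' the machine-readable stage marker embedded in every rendered prompt and
#' answers from gold annotations (optionally corrupted at configured rates);
#' a custom backend is any R function `function(prompt) -> character`, which
#' is how an API-backed adapter would plug in. No other module performs any
#' network or model I/O.
#'
#' @name llm_runtime
NULL

rd_error <- function(class, message, data = list()) {
  stop(structure(c(list(message = message, call = sys.call(-1)), data),
                 class = c(class, "rd_error", "error", "condition")))
}

#' Configure a completion backend
#'
#' @param backend_name `"mock"` or `"function"`.
#' @param oracle Oracle state from [build_oracle()] (mock backend).
#' @param handler `function(prompt) -> character` (function backend).
#' @param temperature Sampling temperature; the pipeline uses 0 for stable
#'   output (recorded for live adapters, ignored by the mock).
#' @param max_context_tokens Model context limit (default 8000).
#' @param reserve_tokens Tokens reserved for the response when checking the
#'   prompt against the context limit.
#' @param retry_limit Retries on transient backend failure.
#' @return An `rd_backend` configuration.
#' @export
backend_config <- function(backend_name = c("mock", "function"),
                           oracle = NULL, handler = NULL, temperature = 0,
                           max_context_tokens = 8000L, reserve_tokens = 1000L,
                           retry_limit = 2L) {
  backend_name <- match.arg(backend_name)
  stopifnot(temperature >= 0, max_context_tokens > reserve_tokens)
  if (backend_name == "mock" && is.null(oracle)) {
    stop("mock backend requires an oracle state")
  }
  if (backend_name == "function" && !is.function(handler)) {
    stop("function backend requires a handler function")
  }
  structure(list(backend_name = backend_name, oracle = oracle,
                 handler = handler, temperature = temperature,
                 max_context_tokens = as.integer(max_context_tokens),
                 reserve_tokens = as.integer(reserve_tokens),
                 retry_limit = as.integer(retry_limit),
                 log = new.env(parent = emptyenv())),
            class = "rd_backend")
}

#' Request a completion
#'
#' Checks the prompt against the context budget before dispatch, retries up
#' to `retry_limit` times on backend failure, and logs every exchange on the
#' backend's log environment.
#'
#' @param config An `rd_backend`.
#' @param prompt_text Rendered prompt.
#' @return An `rd_completion`: `prompt_text`, `response_text`,
#'   `backend_name`, `latency` (seconds), `token_counts` (prompt, response).
#' @export
complete <- function(config, prompt_text) {
  stopifnot(inherits(config, "rd_backend"))
  ptok <- count_tokens(prompt_text)
  if (ptok + config$reserve_tokens > config$max_context_tokens) {
    rd_error("rd_context_overflow",
             sprintf("prompt of %d tokens exceeds context budget %d - %d",
                     ptok, config$max_context_tokens, config$reserve_tokens))
  }
  t0 <- proc.time()[["elapsed"]]
  response <- NULL
  last_err <- NULL
  for (attempt in seq_len(config$retry_limit + 1L)) {
    response <- tryCatch({
      if (config$backend_name == "mock") {
        mock_respond(config$oracle, prompt_text)
      } else {
        config$handler(prompt_text)
      }
    }, error = function(e) { last_err <<- e; NULL })
    if (!is.null(response)) break
  }
  if (is.null(response)) {
    rd_error("rd_backend_error",
             paste0("backend failed after ", config$retry_limit + 1L,
                    " attempts: ", conditionMessage(last_err)))
  }
  rec <- structure(list(prompt_text = prompt_text, response_text = response,
                        backend_name = config$backend_name,
                        latency = proc.time()[["elapsed"]] - t0,
                        token_counts = c(prompt = ptok,
                                         response = count_tokens(response))),
                   class = "rd_completion")
  n <- length(ls(config$log))
  assign(sprintf("rec%06d", n + 1L), rec, envir = config$log)
  rec
}

#' Retrieve the completion log
#' @param config An `rd_backend`.
#' @return List of `rd_completion` in dispatch order.
#' @export
completion_log <- function(config) {
  keys <- sort(ls(config$log))
  lapply(keys, get, envir = config$log)
}

# ---- JSON payload parsing --------------------------------------------------

#' Parse a JSON payload out of a model response
#'
#' Extraction ladder: a fenced code block if present, else the first
#' balanced JSON object in the raw text, else a bracket-balancing repair of
#' a truncated object. The parsed object is validated against
#' `expected_keys`; keys listed in `optional_lists` default to empty lists
#' when missing.
#'
#' @param response_text Raw model response.
#' @param expected_keys Keys that must be present after defaulting.
#' @param optional_lists Keys coerced to `list()` when absent.
#' @return Named list.
#' @export
parse_json_payload <- function(response_text, expected_keys,
                               optional_lists = expected_keys) {
  candidate <- extract_json_object(response_text)
  if (is.null(candidate)) {
    rd_error("rd_parse_error", "no JSON object found in response",
             list(raw = response_text))
  }
  parsed <- tryCatch(jsonlite::fromJSON(candidate, simplifyVector = FALSE),
                     error = function(e) NULL)
  if (is.null(parsed)) {
    repaired <- repair_truncated_json(candidate)
    parsed <- tryCatch(jsonlite::fromJSON(repaired, simplifyVector = FALSE),
                       error = function(e) NULL)
  }
  if (is.null(parsed) || !is.list(parsed)) {
    rd_error("rd_parse_error", "response JSON could not be parsed",
             list(raw = response_text))
  }
  for (k in optional_lists) if (is.null(parsed[[k]])) parsed[k] <- list(list())
  missing <- setdiff(expected_keys, names(parsed))
  if (length(missing)) {
    rd_error("rd_schema_error",
             paste("response JSON missing key(s):", paste(missing, collapse = ", ")),
             list(missing = missing, raw = response_text))
  }
  parsed
}

extract_json_object <- function(text) {
  fenced <- regmatches(text, regexec("(?s)```(?:json)?[ \t]*\n(.*?)```", text,
                                     perl = TRUE))[[1L]]
  if (length(fenced) == 2L && grepl("\\{", fenced[2L])) text <- fenced[2L]
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L; start <- NA_integer_; in_str <- FALSE; esc <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (in_str) {
      if (esc) esc <- FALSE
      else if (ch == "\\") esc <- TRUE
      else if (ch == '"') in_str <- FALSE
      next
    }
    if (ch == '"' && depth > 0L) in_str <- TRUE
    else if (ch == "{") { if (depth == 0L) start <- i; depth <- depth + 1L }
    else if (ch == "}") {
      depth <- depth - 1L
      if (depth == 0L && !is.na(start)) {
        return(paste(chars[start:i], collapse = ""))
      }
    }
  }
  if (!is.na(start)) return(paste(chars[start:length(chars)], collapse = ""))
  NULL
}

# Append the closers a truncated object needs (after stripping a dangling
# partial token), best-effort.
repair_truncated_json <- function(text) {
  text <- sub(",\\s*$", "", text)
  text <- sub(":\\s*$", ": null", text)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  stack <- character(0); in_str <- FALSE; esc <- FALSE
  for (ch in chars) {
    if (in_str) {
      if (esc) esc <- FALSE
      else if (ch == "\\") esc <- TRUE
      else if (ch == '"') in_str <- FALSE
      next
    }
    if (ch == '"') in_str <- TRUE
    else if (ch == "{") stack <- c(stack, "}")
    else if (ch == "[") stack <- c(stack, "]")
    else if (ch %in% c("}", "]")) stack <- stack[-length(stack)]
  }
  closers <- paste(rev(stack), collapse = "")
  if (in_str) closers <- paste0('"', closers)
  paste0(text, closers)
}

# ---- mock backend ----------------------------------------------------------

#' Answer a prompt from gold fixtures
#'
#' The deterministic mock backend. It parses the stage marker that
#' [render_prompt()] embeds in every prompt (stage, document id, character
#' span, segment/bridge kind), looks up the gold annotations for that span,
#' applies the oracle's seeded corruption (entity drops, type confusions,
#' spurious additions, relation drops) and emits the stage's JSON schema.
#' Identical `(oracle_state, prompt_text)` always yields an identical
#' response; slot content outside the marker is ignored except for the
#' calibration entity list.
#'
#' @param oracle_state From [build_oracle()].
#' @param prompt_text A rendered prompt.
#' @return Response text (JSON).
#' @export
mock_respond <- function(oracle_state, prompt_text) {
  mk <- parse_stage_marker(prompt_text)
  if (is.null(mk)) rd_error("rd_mock_error", "prompt carries no stage marker")
  if (mk$stage == "calibrate") {
    ents <- parse_calibration_entities(prompt_text)
    return(jsonlite::toJSON(list(entities = as.list(ents)),
                            auto_unbox = TRUE))
  }
  doc <- oracle_state$docs[[mk$doc]]
  if (is.null(doc)) rd_error("rd_mock_error", paste("unknown document:", mk$doc))
  seed <- (oracle_state$seed %% 65011 + 1L) * 33013L +
    str_hash31(paste(mk$stage, mk$doc, mk$span_start, mk$span_end, mk$kind)) %% 1000003L
  cr <- oracle_state$corruption
  ents <- doc$entities
  in_span <- ents$start >= mk$span_start & ents$end <= mk$span_end
  ents <- ents[in_span, , drop = FALSE]
  if (mk$stage == "extract_more_terms") {
    is_ana <- ents$entity_type == "anaphor"
    return(jsonlite::toJSON(list(terms = as.list(ents$surface[!is_ana]),
                                 anaphors = as.list(ents$surface[is_ana])),
                            auto_unbox = TRUE))
  }
  if (mk$stage == "extract_entities") {
    out <- with_seed(seed, corrupt_entities(ents, cr))
    payload <- lapply(seq_len(nrow(out)), function(i) {
      e <- list(name = out$surface[i], type = out$entity_type[i])
      if (!is.na(out$start[i])) { e$start <- out$start[i]; e$end <- out$end[i] }
      e
    })
    return(jsonlite::toJSON(list(entities = payload), auto_unbox = TRUE))
  }
  if (mk$stage == "extract_relations") {
    rels <- doc$relations
    keep <- logical(nrow(rels))
    if (nrow(rels)) {
      span_of <- stats::setNames(seq_len(nrow(doc$entities)),
                                 doc$entities$mention_id)
      ents_all <- doc$entities[in_span, , drop = FALSE]
      in_ids <- ents_all$mention_id
      keep <- rels$subject_ref %in% in_ids & rels$object_ref %in% in_ids
    }
    rels <- rels[keep, , drop = FALSE]
    if (nrow(rels) && cr$relation_drop_p > 0) {
      drop <- with_seed(seed + 7L,
                        stats::runif(nrow(rels)) < cr$relation_drop_p)
      rels <- rels[!drop, , drop = FALSE]
    }
    surf <- stats::setNames(doc$entities$surface, doc$entities$mention_id)
    payload <- lapply(seq_len(nrow(rels)), function(i) {
      list(subject = unname(surf[rels$subject_ref[i]]),
           type = rels$relation_type[i],
           object = unname(surf[rels$object_ref[i]]))
    })
    return(jsonlite::toJSON(list(relations = payload), auto_unbox = TRUE))
  }
  rd_error("rd_mock_error", paste("unknown stage:", mk$stage))
}

corrupt_entities <- function(ents, cr) {
  n <- nrow(ents)
  if (n && cr$entity_drop_p > 0) {
    keep <- stats::runif(n) >= cr$entity_drop_p
    ents <- ents[keep, , drop = FALSE]
  }
  if (nrow(ents) && cr$type_confuse_p > 0) {
    flip <- stats::runif(nrow(ents)) < cr$type_confuse_p &
      ents$entity_type != "anaphor"
    for (i in which(flip)) {
      others <- setdiff(c("rare_disease", "disease", "symptom_and_sign"),
                        ents$entity_type[i])
      ents$entity_type[i] <- sample(others, 1L)
    }
  }
  if (n && cr$spurious_rate > 0) {
    n_sp <- stats::rbinom(1L, n, cr$spurious_rate)
    if (n_sp > 0) {
      sp <- data.frame(
        mention_id = paste0("SP", seq_len(n_sp)),
        surface = paste("unrelated finding", sample.int(10000L, n_sp)),
        entity_type = sample(c("disease", "symptom_and_sign"), n_sp,
                             replace = TRUE),
        start = NA_integer_, end = NA_integer_, stringsAsFactors = FALSE)
      ents <- rbind(ents[, names(sp), drop = FALSE], sp)
    }
  }
  ents
}

parse_calibration_entities <- function(prompt_text) {
  lines <- strsplit(prompt_text, "\n", fixed = TRUE)[[1L]]
  m <- regmatches(lines, regexec("^- (.*) \\| [a-z_]+ \\| relations=\\d+$", lines))
  names_out <- vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_,
                      character(1))
  names_out[!is.na(names_out)]
}
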