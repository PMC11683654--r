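#' @title Evaluation harness
#'
#' @description
#' Occurrence-level multiset scoring against gold standoff annotations:
#' within a document, predicted and gold mentions pair by (normalized name,
#' type), each gold occurrence satisfying at most one prediction. Precision,
#' recall and F1 are reported per type and micro-averaged overall, on a
#' 0-100 scale; the headline metric is the overall F1, the arithmetic mean
#' of entity-overall and relation-overall F1. Error-augmented confusion
#' matrices summarize type confusions at the deduplicated-name level.
#'
#' @name evaluation
NULL

# Mention keys for matching. `entities`/`relations` are data.frames with a
# doc column added by the callers below.
entity_keys <- function(df) {
  paste(df$doc, normalize_name(df$surface), df$entity_type, sep = "\r")
}

relation_keys <- function(df) {
  paste(df$doc, normalize_name(df$subject), df$relation_type,
        normalize_name(df$object), sep = "\r")
}

# Gold documents store relations by mention id; flatten to surfaces.
gold_entity_frame <- function(docs) {
  do.call(rbind, c(list(data.frame(doc = character(0), surface = character(0),
                                   entity_type = character(0),
                                   stringsAsFactors = FALSE)),
    lapply(docs, function(d) {
      if (!nrow(d$entities)) return(NULL)
      data.frame(doc = d$doc_id, surface = d$entities$surface,
                 entity_type = d$entities$entity_type, stringsAsFactors = FALSE)
    })))
}

gold_relation_frame <- function(docs) {
  do.call(rbind, c(list(data.frame(doc = character(0), subject = character(0),
                                   relation_type = character(0),
                                   object = character(0),
                                   stringsAsFactors = FALSE)),
    lapply(docs, function(d) {
      if (!nrow(d$relations)) return(NULL)
      surf <- stats::setNames(d$entities$surface, d$entities$mention_id)
      data.frame(doc = d$doc_id,
                 subject = unname(surf[d$relations$subject_ref]),
                 relation_type = d$relations$relation_type,
                 object = unname(surf[d$relations$object_ref]),
                 stringsAsFactors = FALSE)
    })))
}

pred_entity_frame <- function(results) {
  do.call(rbind, c(list(data.frame(doc = character(0), surface = character(0),
                                   entity_type = character(0),
                                   stringsAsFactors = FALSE)),
    lapply(results, function(r) {
      if (!nrow(r$entities)) return(NULL)
      data.frame(doc = r$doc_id, surface = r$entities$surface,
                 entity_type = r$entities$entity_type, stringsAsFactors = FALSE)
    })))
}

pred_relation_frame <- function(results) {
  do.call(rbind, c(list(data.frame(doc = character(0), subject = character(0),
                                   relation_type = character(0),
                                   object = character(0),
                                   stringsAsFactors = FALSE)),
    lapply(results, function(r) {
      if (!nrow(r$relations)) return(NULL)
      data.frame(doc = r$doc_id, subject = r$relations$subject,
                 relation_type = r$relations$relation_type,
                 object = r$relations$object, stringsAsFactors = FALSE)
    })))
}

# Multiset matching: matched count per key = min(pred count, gold count);
# equivalent to greedy pairing in document order because pairing requires
# exact key equality (exchange argument).
score_multiset <- function(pred_keys, gold_keys, pred_types, gold_types,
                           all_types) {
  matched_per_key <- function() {
    pk <- table(pred_keys); gk <- table(gold_keys)
    shared <- intersect(names(pk), names(gk))
    stats::setNames(pmin(as.integer(pk[shared]), as.integer(gk[shared])), shared)
  }
  m <- matched_per_key()
  key_type <- function(keys, types) {
    idx <- !duplicated(keys)
    stats::setNames(types[idx], keys[idx])
  }
  gt <- key_type(gold_keys, gold_types)
  per_type <- lapply(all_types, function(tp) {
    npred <- sum(pred_types == tp)
    ngold <- sum(gold_types == tp)
    nmatch <- sum(m[names(m) %in% names(gt)[gt == tp]])
    prf(nmatch, npred, ngold)
  })
  names(per_type) <- all_types
  overall <- prf(sum(m), length(pred_keys), length(gold_keys))
  list(per_type = per_type, overall = overall)
}

prf <- function(matched, npred, ngold) {
  p <- if (npred > 0) 100 * matched / npred else 0
  r <- if (ngold > 0) 100 * matched / ngold else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f, matched = matched, n_pred = npred,
    n_gold = ngold)
}

#' Score entity predictions
#'
#' @param pred List of `rd_extraction` (or anything with `doc_id` and a
#'   predicted `entities` frame).
#' @param gold List of gold `rd_document`.
#' @return list with `per_type` (named list of precision/recall/F1 on the
#'   0-100 scale plus counts) and `overall` (micro-averaged).
#' @export
score_entities <- function(pred, gold) {
  pf <- pred_entity_frame(pred)
  gf <- gold_entity_frame(gold)
  score_multiset(entity_keys(pf), entity_keys(gf), pf$entity_type,
                 gf$entity_type, ENTITY_TYPES)
}

#' Score relation predictions
#'
#' A predicted relation matches an unmatched gold relation in the same
#' document with equal (normalized subject name, relation type, normalized
#' object name); matching does not condition on whether the endpoint
#' entities were themselves scored correct.
#'
#' @inheritParams score_entities
#' @return As [score_entities()], keyed by relation type.
#' @export
score_relations <- function(pred, gold) {
  pf <- pred_relation_frame(pred)
  gf <- gold_relation_frame(gold)
  score_multiset(relation_keys(pf), relation_keys(gf), pf$relation_type,
                 gf$relation_type, RELATION_TYPES)
}

#' Overall F1 from entity and relation F1
#'
#' The headline metric: the arithmetic mean of the entity-overall and
#' relation-overall F1 scores, reported to one decimal with ties rounding
#' up in magnitude.
#'
#' @param entity_f1,relation_f1 F1 scores on the 0-100 scale.
#' @param digits Decimal places for reporting.
#' @return The rounded mean.
#' @export
overall_score <- function(entity_f1, relation_f1, digits = 1L) {
  round_half_up((entity_f1 + relation_f1) / 2, digits)
}

#' Full metrics report
#'
#' @inheritParams score_entities
#' @return An `rd_metrics`: `per_entity_type`, `entity_overall`,
#'   `per_relation_type`, `relation_overall` and `overall` (elementwise
#'   means of the entity/relation overall P, R and F1), all unrounded on
#'   the 0-100 scale, plus an `empty_pred` flag when nothing was predicted.
#' @export
metrics_report <- function(pred, gold) {
  es <- score_entities(pred, gold)
  rs <- score_relations(pred, gold)
  overall <- (es$overall[c("precision", "recall", "f1")] +
                rs$overall[c("precision", "recall", "f1")]) / 2
  structure(list(per_entity_type = es$per_type, entity_overall = es$overall,
                 per_relation_type = rs$per_type,
                 relation_overall = rs$overall, overall = overall,
                 empty_pred = es$overall[["n_pred"]] == 0 &&
                   rs$overall[["n_pred"]] == 0),
            class = "rd_metrics")
}

#' @export
print.rd_metrics <- function(x, ...) {
  cat(report(x, "text_table"), sep = "\n")
  invisible(x)
}

#' Error-augmented confusion matrices
#'
#' Replicated mentions are excluded: per document, gold and predicted items
#' reduce to (normalized name, type) sets, then names pair across the two
#' sets. Cell (true = t, predicted = p) counts gold names of type t whose
#' predicted type is p; gold names never predicted fall in the `Error`
#' column, predicted names absent from gold fall in the `Error` row.
#'
#' @inheritParams score_entities
#' @return list(entity = matrix, relation = matrix); rows are true labels,
#'   columns predicted labels, both augmented with `Error`.
#' @export
confusion_matrices <- function(pred, gold) {
  list(entity = confusion_one(pred_entity_frame(pred), gold_entity_frame(gold),
                              "surface", "entity_type", ENTITY_TYPES),
       relation = confusion_one(pred_relation_frame(pred),
                                gold_relation_frame(gold), NULL,
                                "relation_type", RELATION_TYPES))
}

confusion_one <- function(pf, gf, name_col, type_col, types) {
  labels <- c(types, "Error")
  mat <- matrix(0L, length(labels), length(labels),
                dimnames = list(true = labels, predicted = labels))
  ident <- function(df) {
    if (is.null(name_col)) {
      paste(df$doc, normalize_name(df$subject), normalize_name(df$object),
            sep = "\r")
    } else {
      paste(df$doc, normalize_name(df[[name_col]]), sep = "\r")
    }
  }
  # deduplicate to (identity, type) pairs
  pk <- paste(ident(pf), pf[[type_col]], sep = "\r")
  pf <- pf[!duplicated(pk), , drop = FALSE]
  gk <- paste(ident(gf), gf[[type_col]], sep = "\r")
  gf <- gf[!duplicated(gk), , drop = FALSE]
  pid <- ident(pf); gid <- ident(gf)
  used_pred <- logical(nrow(pf))
  for (i in seq_len(nrow(gf))) {
    cand <- which(pid == gid[i] & !used_pred)
    if (!length(cand)) {
      mat[gf[[type_col]][i], "Error"] <- mat[gf[[type_col]][i], "Error"] + 1L
      next
    }
    same <- cand[pf[[type_col]][cand] == gf[[type_col]][i]]
    j <- if (length(same)) same[1L] else cand[1L]
    used_pred[j] <- TRUE
    mat[gf[[type_col]][i], pf[[type_col]][j]] <-
      mat[gf[[type_col]][i], pf[[type_col]][j]] + 1L
  }
  for (j in which(!used_pred)) {
    mat["Error", pf[[type_col]][j]] <- mat["Error", pf[[type_col]][j]] + 1L
  }
  mat
}

#' Render a metrics report
#'
#' Per-type rows then overall rows, one-decimal percentages (ties round up
#' in magnitude). With a `reference` report, delta columns (this minus
#' reference) are appended, negative deltas carrying a minus sign.
#'
#' @param metrics An `rd_metrics`.
#' @param format `"text_table"`, `"json"` or `"csv"`.
#' @param reference Optional `rd_metrics` to difference against.
#' @return Character vector of rendered lines (`text_table`, `csv`) or a
#'   JSON string.
#' @export
report <- function(metrics, format = c("text_table", "json", "csv"),
                   reference = NULL) {
  format <- match.arg(format)
  if (isTRUE(metrics$empty_pred)) {
    warning("empty prediction set: report is all zeros", call. = FALSE)
  }
  df <- report_frame(metrics)
  if (!is.null(reference)) {
    rf <- report_frame(reference)
    stopifnot(identical(df$row, rf$row))
    for (col in c("precision", "recall", "f1")) {
      df[[paste0("delta_", col)]] <- round_half_up(df[[col]] - rf[[col]], 1L)
    }
  }
  num_cols <- setdiff(names(df), "row")
  for (col in num_cols) df[[col]] <- round_half_up(df[[col]], 1L)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(df, dataframe = "rows", digits = NA)))
  }
  if (format == "csv") {
    return(c(paste(names(df), collapse = ","),
             vapply(seq_len(nrow(df)), function(i) {
               paste(vapply(df[i, ], as.character, ""), collapse = ",")
             }, character(1))))
  }
  widths <- 10L
  header <- sprintf("%-22s%s", "type",
                    paste(formatC(num_cols, width = widths), collapse = ""))
  rows <- vapply(seq_len(nrow(df)), function(i) {
    sprintf("%-22s%s", df$row[i],
            paste(formatC(sprintf("%.1f", as.numeric(df[i, num_cols])),
                          width = widths), collapse = ""))
  }, character(1))
  c(header, rows)
}

report_frame <- function(m) {
  row_of <- function(name, v) {
    data.frame(row = name, precision = v[["precision"]],
               recall = v[["recall"]], f1 = v[["f1"]],
               stringsAsFactors = FALSE)
  }
  rows <- c(lapply(names(m$per_entity_type), function(tp) {
              row_of(tp, m$per_entity_type[[tp]])
            }),
            list(row_of("entity_overall", m$entity_overall)),
            lapply(names(m$per_relation_type), function(tp) {
              row_of(tp, m$per_relation_type[[tp]])
            }),
            list(row_of("relation_overall", m$relation_overall),
                 row_of("overall", m$overall)))
  do.call(rbind, rows)
}
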