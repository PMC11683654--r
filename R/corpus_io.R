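#' @title Annotated corpus input/output
#'
#' @description
#' Documents travel through the pipeline as `rd_document` objects: the raw
#' text plus entity mentions (with 0-based half-open character spans) and
#' relation instances referencing mentions by id. Gold corpora are read from
#' BRAT-style standoff files (`.txt` + `.ann`); predictions are serialized
#' to a documented JSON schema.
#'
#' @name corpus_io
NULL

ENTITY_TYPES <- c("rare_disease", "disease", "symptom_and_sign", "anaphor")
RELATION_TYPES <- c("produces", "increases_risk_of", "is_a", "is_acron",
                    "is_synon", "anaphora")

empty_entities <- function() {
  data.frame(mention_id = character(0), surface = character(0),
             entity_type = character(0), start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)
}

empty_relations <- function() {
  data.frame(rel_id = character(0), relation_type = character(0),
             subject_ref = character(0), object_ref = character(0),
             stringsAsFactors = FALSE)
}

#' Construct an annotated document
#'
#' @param doc_id Document identifier.
#' @param text Document text (UTF-8).
#' @param entities data.frame with columns `mention_id`, `surface`,
#'   `entity_type`, `start`, `end` (0-based half-open; `NA` spans allowed).
#' @param relations data.frame with columns `rel_id`, `relation_type`,
#'   `subject_ref`, `object_ref` (mention ids).
#' @return An `rd_document`.
#' @export
rd_document <- function(doc_id, text, entities = empty_entities(),
                        relations = empty_relations()) {
  entities <- as.data.frame(entities, stringsAsFactors = FALSE)
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  # raw symptom/sign tags are tolerated here so corpora can be read before
  # merge_symptom_sign() normalizes them to the working type system
  bad <- setdiff(unique(entities$entity_type),
                 c(ENTITY_TYPES, "symptom", "sign"))
  if (length(bad)) stop("unknown entity type(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(relations$relation_type), RELATION_TYPES)
  if (length(bad)) stop("unknown relation type(s): ", paste(bad, collapse = ", "))
  if (nrow(entities)) {
    has_span <- !is.na(entities$start)
    if (any(has_span)) {
      got <- substring(text, entities$start[has_span] + 1L, entities$end[has_span])
      off <- got != entities$surface[has_span]
      if (any(off)) {
        stop("span/text mismatch for mention(s): ",
             paste(entities$mention_id[has_span][off], collapse = ", "))
      }
    }
  }
  if (nrow(relations)) {
    refs <- c(relations$subject_ref, relations$object_ref)
    missing <- setdiff(refs, entities$mention_id)
    if (length(missing)) {
      stop("relation reference(s) do not resolve: ", paste(missing, collapse = ", "))
    }
  }
  structure(list(doc_id = doc_id, text = text, entities = entities,
                 relations = relations), class = "rd_document")
}

#' @export
print.rd_document <- function(x, ...) {
  cat(sprintf("<rd_document %s> %d chars, %d entities, %d relations\n",
              x$doc_id, nchar(x$text), nrow(x$entities), nrow(x$relations)))
  invisible(x)
}

#' Read a BRAT standoff document
#'
#' Accepts entity records `T<id>\t<type> <start> <end>\t<surface>` and binary
#' relation records `R<id>\t<type> Arg1:T<id> Arg2:T<id>`. Spans are
#' validated against the text; `Symptom` and `Sign` tags are accepted and
#' merged into `symptom_and_sign` by [merge_symptom_sign()] (not here).
#'
#' @param txt_path Path to the `.txt` file.
#' @param ann_path Path to the `.ann` file; defaults to `txt_path` with the
#'   extension swapped.
#' @param doc_id Document id; defaults to the file stem.
#' @return An `rd_document`.
#' @export
read_standoff <- function(txt_path, ann_path = sub("\\.txt$", ".ann", txt_path),
                          doc_id = sub("\\.txt$", "", basename(txt_path))) {
  text <- read_text_file(txt_path)
  lines <- readLines(ann_path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  ents <- list(); rels <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    tag <- fields[1L]
    if (startsWith(tag, "T")) {
      if (length(fields) < 3L) stop("malformed entity record: ", ln)
      hdr <- strsplit(fields[2L], " ", fixed = TRUE)[[1L]]
      if (length(hdr) != 3L) stop("malformed entity record: ", ln)
      type <- canonical_entity_type(hdr[1L], ln)
      start <- as.integer(hdr[2L]); end <- as.integer(hdr[3L])
      surface <- fields[3L]
      got <- substring(text, start + 1L, end)
      if (!identical(got, surface)) {
        stop(sprintf("record %s: offsets %d:%d yield %s, not %s",
                     tag, start, end, dQuote(got), dQuote(surface)))
      }
      ents[[length(ents) + 1L]] <- data.frame(
        mention_id = tag, surface = surface, entity_type = type,
        start = start, end = end, stringsAsFactors = FALSE)
    } else if (startsWith(tag, "R")) {
      m <- regexec("^(\\S+) Arg1:(\\S+) Arg2:(\\S+)$", fields[2L])
      p <- regmatches(fields[2L], m)[[1L]]
      if (length(p) != 4L) stop("malformed relation record: ", ln)
      type <- p[2L]
      if (!type %in% RELATION_TYPES) {
        stop("unknown relation type tag in record: ", ln)
      }
      rels[[length(rels) + 1L]] <- data.frame(
        rel_id = tag, relation_type = type, subject_ref = p[3L],
        object_ref = p[4L], stringsAsFactors = FALSE)
    } else if (startsWith(tag, "#")) {
      next  # comments/notes
    } else {
      stop("unknown standoff record type: ", ln)
    }
  }
  rd_document(doc_id, text,
              if (length(ents)) do.call(rbind, ents) else empty_entities(),
              if (length(rels)) do.call(rbind, rels) else empty_relations())
}

canonical_entity_type <- function(tag, ln) {
  if (tag %in% ENTITY_TYPES) return(tag)
  low <- tolower(tag)
  if (low %in% c("symptom", "sign")) return(low)  # merged downstream
  if (low %in% ENTITY_TYPES) return(low)
  stop("unknown entity type tag in record: ", ln)
}

#' Merge symptom and sign mentions into one type
#'
#' Retypes every mention annotated `Symptom` or `Sign` (any case) as
#' `symptom_and_sign`, leaving everything else unchanged. Idempotent.
#'
#' @param doc An `rd_document` (possibly carrying raw `symptom`/`sign` tags
#'   straight from [read_standoff()]).
#' @return The document with the merged type system.
#' @export
merge_symptom_sign <- function(doc) {
  tp <- tolower(doc$entities$entity_type)
  doc$entities$entity_type[tp %in% c("symptom", "sign")] <- "symptom_and_sign"
  doc
}

#' Read a directory of standoff files
#'
#' @param dir Directory containing paired `.txt`/`.ann` files.
#' @param merge Apply [merge_symptom_sign()] to each document.
#' @return List of `rd_document`.
#' @export
read_standoff_dir <- function(dir, merge = TRUE) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  docs <- lapply(txts, read_standoff)
  if (merge) docs <- lapply(docs, merge_symptom_sign)
  docs
}

#' Write a document as BRAT standoff
#'
#' @param doc An `rd_document`.
#' @param dir Output directory.
#' @return Invisibly, the `.txt` path.
#' @export
write_standoff <- function(doc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  txt_path <- file.path(dir, paste0(doc$doc_id, ".txt"))
  writeChar(doc$text, txt_path, eos = NULL, useBytes = TRUE)
  ann <- character(0)
  if (nrow(doc$entities)) {
    ann <- c(ann, sprintf("%s\t%s %d %d\t%s", doc$entities$mention_id,
                          doc$entities$entity_type, doc$entities$start,
                          doc$entities$end, doc$entities$surface))
  }
  if (nrow(doc$relations)) {
    ann <- c(ann, sprintf("%s\t%s Arg1:%s Arg2:%s", doc$relations$rel_id,
                          doc$relations$relation_type,
                          doc$relations$subject_ref, doc$relations$object_ref))
  }
  writeLines(ann, file.path(dir, paste0(doc$doc_id, ".ann")), useBytes = TRUE)
  invisible(txt_path)
}

#' Split a corpus into train/validation/test sets
#'
#' Seeded shuffle followed by a contiguous partition whose sizes follow
#' largest-remainder apportionment of `length(docs)` across `ratios`
#' (ties go to the earlier part). 1040 documents at 6:2:2 gives 624/208/208.
#'
#' @param docs List of documents (any objects).
#' @param ratios Positive numeric vector, e.g. `c(6, 2, 2)`.
#' @param seed Integer RNG seed for the shuffle.
#' @return An `rd_split`: list with `train`, `validation`, `test` (when
#'   3 parts; otherwise `part1..k`), `ratios`, `seed`, `sizes`.
#' @export
split_dataset <- function(docs, ratios = c(6, 2, 2), seed = 1L) {
  stopifnot(all(ratios > 0), length(docs) >= 1)
  n <- length(docs)
  if (n < length(ratios)) {
    stop("need at least ", length(ratios), " documents, got ", n)
  }
  sizes <- apportion_largest_remainder(n, ratios)
  idx <- with_seed(seed, sample.int(n))
  bounds <- cumsum(c(0L, sizes))
  parts <- lapply(seq_along(sizes), function(k) {
    docs[idx[seq.int(bounds[k] + 1L, length.out = sizes[k])]]
  })
  names(parts) <- if (length(sizes) == 3L) c("train", "validation", "test")
                  else paste0("part", seq_along(sizes))
  structure(c(parts, list(ratios = ratios, seed = seed, sizes = sizes)),
            class = "rd_split")
}

apportion_largest_remainder <- function(n, ratios) {
  quota <- n * ratios / sum(ratios)
  sizes <- floor(quota)
  left <- n - sum(sizes)
  if (left > 0) {
    frac <- quota - sizes
    # ties broken toward earlier parts: order() is stable on equal keys
    take <- order(-frac)[seq_len(left)]
    sizes[take] <- sizes[take] + 1
  }
  as.integer(sizes)
}

# ---- extraction-result JSON ------------------------------------------------

#' Write extraction results as JSON
#'
#' One object per document: `doc_id`, `entities` (surface, type, optional
#' start/end, provenance) and `relations` (subject, type, object,
#' provenance). Loss-free: [read_extraction()] restores the same results.
#'
#' @param results List of `rd_extraction` objects (see [run_document()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_extraction <- function(results, path) {
  payload <- lapply(results, function(r) {
    list(doc_id = jsonlite::unbox(r$doc_id),
         entities = entities_payload(r$entities),
         relations = relations_payload(r$relations))
  })
  jsonlite::write_json(payload, path, auto_unbox = FALSE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

entities_payload <- function(e) {
  if (!nrow(e)) return(list())
  lapply(seq_len(nrow(e)), function(i) {
    out <- list(surface = jsonlite::unbox(e$surface[i]),
                entity_type = jsonlite::unbox(e$entity_type[i]))
    if (!is.na(e$start[i])) {
      out$start <- jsonlite::unbox(e$start[i])
      out$end <- jsonlite::unbox(e$end[i])
    }
    if (!is.null(e$provenance) && !is.na(e$provenance[i])) {
      out$provenance <- jsonlite::unbox(e$provenance[i])
    }
    out
  })
}

relations_payload <- function(r) {
  if (!nrow(r)) return(list())
  lapply(seq_len(nrow(r)), function(i) {
    out <- list(subject = jsonlite::unbox(r$subject[i]),
                relation_type = jsonlite::unbox(r$relation_type[i]),
                object = jsonlite::unbox(r$object[i]))
    if (!is.null(r$provenance) && !is.na(r$provenance[i])) {
      out$provenance <- jsonlite::unbox(r$provenance[i])
    }
    out
  })
}

#' Read extraction results written by [write_extraction()]
#'
#' @param path JSON file.
#' @return List of `rd_extraction` objects.
#' @export
read_extraction <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    ents <- if (length(r$entities)) {
      do.call(rbind, lapply(r$entities, function(e) data.frame(
        surface = e$surface, entity_type = e$entity_type,
        start = as.integer(e$start %||% NA), end = as.integer(e$end %||% NA),
        provenance = e$provenance %||% NA_character_,
        stringsAsFactors = FALSE)))
    } else empty_pred_entities()
    rels <- if (length(r$relations)) {
      do.call(rbind, lapply(r$relations, function(x) data.frame(
        subject = x$subject, relation_type = x$relation_type,
        object = x$object, provenance = x$provenance %||% NA_character_,
        stringsAsFactors = FALSE)))
    } else empty_pred_relations()
    new_extraction(r$doc_id, ents, rels)
  })
}

empty_pred_entities <- function() {
  data.frame(surface = character(0), entity_type = character(0),
             start = integer(0), end = integer(0), provenance = character(0),
             stringsAsFactors = FALSE)
}

empty_pred_relations <- function() {
  data.frame(subject = character(0), relation_type = character(0),
             object = character(0), provenance = character(0),
             stringsAsFactors = FALSE)
}

new_extraction <- function(doc_id, entities, relations) {
  structure(list(doc_id = doc_id, entities = entities, relations = relations),
            class = "rd_extraction")
}

#' @export
print.rd_extraction <- function(x, ...) {
  cat(sprintf("<rd_extraction %s> %d entities, %d relations\n", x$doc_id,
              nrow(x$entities), nrow(x$relations)))
  invisible(x)
}
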