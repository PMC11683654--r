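#' @title Knowledge graph construction
#'
#' @description
#' Extraction results become a typed graph: anaphoric relations are
#' rewritten to their antecedents' names, entities are aligned by lowercase
#' name matching, duplicate triples merge with a support count, and the
#' graph is exported in Neo4j-loadable forms (GraphML, CSV node/edge lists,
#' Cypher MERGE statements). The final graph contains no anaphor nodes and
#' no anaphora edges.
#'
#' @name kg_builder
NULL

NODE_TYPE_RANK <- c(rare_disease = 1L, disease = 2L, symptom_and_sign = 3L)

#' Rewrite anaphoric relations to their antecedents
#'
#' Every relation whose subject or object is an anaphor is rewritten to the
#' rare-disease antecedent named by that anaphor's `anaphora` link; the
#' anaphora relations and anaphor entities are then removed. An anaphor
#' with several links resolves to the textually nearest preceding
#' antecedent (with a warning); an anaphor lacking any link is removed
#' together with its relations (with a warning).
#'
#' @param result An `rd_extraction`.
#' @return The rewritten `rd_extraction`.
#' @export
resolve_anaphora <- function(result) {
  ents <- result$entities
  rels <- result$relations
  ana_keys <- unique(normalize_name(ents$surface[ents$entity_type == "anaphor"]))
  if (!length(ana_keys)) return(result)
  is_ana_rel <- rels$relation_type == "anaphora"
  antecedent <- character(0)
  for (key in ana_keys) {
    links <- rels[is_ana_rel & normalize_name(rels$subject) == key, ,
                  drop = FALSE]
    if (!nrow(links)) {
      warning("anaphor '", key, "' has no anaphora link; removed", call. = FALSE)
      next
    }
    if (nrow(links) > 1L) {
      # nearest preceding antecedent: latest-starting antecedent occurrence
      # before the anaphor's first occurrence, by recorded spans
      warning("anaphor '", key, "' has ", nrow(links),
              " anaphora links; using the nearest antecedent", call. = FALSE)
      a_start <- suppressWarnings(
        min(ents$start[normalize_name(ents$surface) == key], na.rm = TRUE))
      best <- 1L; best_pos <- -Inf
      for (i in seq_len(nrow(links))) {
        cand <- normalize_name(links$object[i])
        pos <- suppressWarnings(
          max(ents$start[normalize_name(ents$surface) == cand &
                           ents$start < a_start], na.rm = TRUE))
        if (is.finite(pos) && pos > best_pos) { best_pos <- pos; best <- i }
      }
      antecedent[key] <- links$object[best]
    } else {
      antecedent[key] <- links$object[1L]
    }
  }
  # rewrite non-anaphora relations through the substitution
  rels <- rels[!is_ana_rel, , drop = FALSE]
  if (nrow(rels)) {
    subj_key <- normalize_name(rels$subject)
    obj_key <- normalize_name(rels$object)
    resolved <- names(antecedent)
    drop <- (subj_key %in% ana_keys & !subj_key %in% resolved) |
      (obj_key %in% ana_keys & !obj_key %in% resolved)
    rels <- rels[!drop, , drop = FALSE]
    subj_key <- subj_key[!drop]; obj_key <- obj_key[!drop]
    hit <- subj_key %in% resolved
    rels$subject[hit] <- unname(antecedent[subj_key[hit]])
    hit <- obj_key %in% resolved
    rels$object[hit] <- unname(antecedent[obj_key[hit]])
  }
  ents <- ents[ents$entity_type != "anaphor", , drop = FALSE]
  rownames(ents) <- NULL
  rownames(rels) <- NULL
  new_extraction(result$doc_id, ents, rels)
}

#' Build a knowledge graph from extraction results
#'
#' Anaphora are resolved per document, nodes are created per normalized
#' name (first-seen display name kept; conflicting node types resolve
#' rare_disease over disease over symptom_and_sign, with a message),
#' duplicate triples merge with their support count incremented, and
#' isolated nodes are excluded.
#'
#' @param results List of `rd_extraction`.
#' @return An `rd_kg`: list with data.frames `nodes` (`key`, `name`,
#'   `type`) and `edges` (`subject`, `relation`, `object`, `support`).
#' @export
build_graph <- function(results) {
  nodes <- new.env(parent = emptyenv())
  edges <- new.env(parent = emptyenv())
  conflicts <- character(0)
  add_node <- function(name, type) {
    key <- normalize_name(name)
    cur <- get0(key, envir = nodes, inherits = FALSE)
    if (is.null(cur)) {
      assign(key, list(name = name, type = type), envir = nodes)
    } else if (!identical(cur$type, type)) {
      win <- if (NODE_TYPE_RANK[type] < NODE_TYPE_RANK[cur$type]) type else cur$type
      if (!identical(win, cur$type)) {
        assign(key, list(name = cur$name, type = win), envir = nodes)
      }
      conflicts <<- c(conflicts, key)
    }
    key
  }
  for (res in results) {
    r <- resolve_anaphora(res)
    type_of <- stats::setNames(r$entities$entity_type,
                               normalize_name(r$entities$surface))
    for (i in seq_len(nrow(r$relations))) {
      subj <- r$relations$subject[i]; obj <- r$relations$object[i]
      st <- unname(type_of[normalize_name(subj)])
      ot <- unname(type_of[normalize_name(obj)])
      if (is.na(st) || is.na(ot)) next  # endpoint lost during resolution
      sk <- add_node(subj, st)
      ok <- add_node(obj, ot)
      ek <- paste(sk, r$relations$relation_type[i], ok, sep = "\r")
      cur <- get0(ek, envir = edges, inherits = FALSE) %||% 0L
      assign(ek, cur + 1L, envir = edges)
    }
  }
  if (length(conflicts)) {
    message("node type conflicts resolved by precedence for: ",
            paste(unique(conflicts), collapse = ", "))
  }
  ekeys <- ls(edges)
  edf <- if (length(ekeys)) {
    parts <- do.call(rbind, strsplit(ekeys, "\r", fixed = TRUE))
    data.frame(subject = parts[, 1L], relation = parts[, 2L],
               object = parts[, 3L],
               support = vapply(ekeys, get, 0L, envir = edges,
                                USE.NAMES = FALSE),
               stringsAsFactors = FALSE)
  } else {
    data.frame(subject = character(0), relation = character(0),
               object = character(0), support = integer(0))
  }
  used <- unique(c(edf$subject, edf$object))
  ndf <- if (length(used)) {
    do.call(rbind, lapply(sort(used), function(k) {
      n <- get(k, envir = nodes)
      data.frame(key = k, name = n$name, type = n$type, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(key = character(0), name = character(0), type = character(0))
  }
  edf <- edf[order(edf$subject, edf$relation, edf$object), , drop = FALSE]
  rownames(ndf) <- NULL
  rownames(edf) <- NULL
  structure(list(nodes = ndf, edges = edf), class = "rd_kg")
}

#' @export
print.rd_kg <- function(x, ...) {
  cat(sprintf("<rd_kg> %d nodes, %d edges\n", nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Export a knowledge graph
#'
#' @param kg An `rd_kg`.
#' @param dir Output directory (created if needed).
#' @param format `"csv_pair"` (`nodes.csv` + `edges.csv`, bulk-import
#'   compatible headers), `"graphml"` (`graph.graphml`), or `"cypher"`
#'   (`graph.cypher`, one MERGE per node and edge).
#' @return Character vector of the files written, invisibly.
#' @export
export_graph <- function(kg, dir, format = c("csv_pair", "graphml", "cypher")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "csv_pair") {
    nf <- file.path(dir, "nodes.csv"); ef <- file.path(dir, "edges.csv")
    utils::write.csv(kg$nodes, nf, row.names = FALSE)
    utils::write.csv(kg$edges, ef, row.names = FALSE)
    return(invisible(c(nf, ef)))
  }
  if (format == "graphml") {
    path <- file.path(dir, "graph.graphml")
    xml_escape <- function(x) {
      x <- gsub("&", "&amp;", x, fixed = TRUE)
      x <- gsub("<", "&lt;", x, fixed = TRUE)
      x <- gsub(">", "&gt;", x, fixed = TRUE)
      gsub('"', "&quot;", x, fixed = TRUE)
    }
    lines <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <key id="d0" for="node" attr.name="name" attr.type="string"/>',
      '  <key id="d1" for="node" attr.name="type" attr.type="string"/>',
      '  <key id="d2" for="edge" attr.name="relation" attr.type="string"/>',
      '  <key id="d3" for="edge" attr.name="support" attr.type="int"/>',
      '  <graph id="G" edgedefault="directed">',
      if (nrow(kg$nodes)) sprintf(
        '    <node id="%s"><data key="d0">%s</data><data key="d1">%s</data></node>',
        xml_escape(kg$nodes$key), xml_escape(kg$nodes$name),
        kg$nodes$type) else character(0),
      if (nrow(kg$edges)) sprintf(
        '    <edge source="%s" target="%s"><data key="d2">%s</data><data key="d3">%d</data></edge>',
        xml_escape(kg$edges$subject), xml_escape(kg$edges$object),
        kg$edges$relation, kg$edges$support) else character(0),
      '  </graph>',
      '</graphml>')
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(path))
  }
  # cypher
  path <- file.path(dir, "graph.cypher")
  esc <- function(x) gsub("'", "\\\\'", x)
  lines <- c(
    if (nrow(kg$nodes)) sprintf(
      "MERGE (n:Entity {key: '%s'}) SET n.name = '%s', n.type = '%s';",
      esc(kg$nodes$key), esc(kg$nodes$name), kg$nodes$type) else character(0),
    if (nrow(kg$edges)) sprintf(
      paste0("MATCH (a:Entity {key: '%s'}), (b:Entity {key: '%s'}) ",
             "MERGE (a)-[r:%s]->(b) SET r.support = %d;"),
      esc(kg$edges$subject), esc(kg$edges$object),
      toupper(kg$edges$relation), kg$edges$support) else character(0))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Re-import a CSV-pair export
#'
#' @param dir Directory containing `nodes.csv` and `edges.csv`.
#' @return An `rd_kg` isomorphic to the exported graph.
#' @export
import_graph_csv <- function(dir) {
  nodes <- utils::read.csv(file.path(dir, "nodes.csv"),
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "character"))
  edges <- utils::read.csv(file.path(dir, "edges.csv"),
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "character", "integer"))
  structure(list(nodes = nodes, edges = edges), class = "rd_kg")
}
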