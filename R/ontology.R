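#' @title Ontology knowledge base
#'
#' @description
#' Lexicons compiled from rare-disease and general medical ontologies drive
#' two knowledge-injection points in the pipeline: dictionary string matching
#' against the concept lexicon (diseases, symptoms and signs), and
#' rare-disease knowledge / association-triple slots in the extraction
#' prompts. Sources are accepted in OBO format (term stanzas) or a compiled
#' 4-column TSV dialect.
#'
#' @name ontology_kb
NULL

RD_CATEGORIES <- c("rare_disease", "disease", "phenotype")

new_concept <- function(concept_id, preferred_name, synonyms = character(0),
                        definition = "", category) {
  stopifnot(nzchar(preferred_name), category %in% RD_CATEGORIES)
  # drop duplicate synonyms after case-folding, keep first spelling
  syn <- as.character(synonyms)
  syn <- syn[nzchar(syn)]
  syn <- syn[!duplicated(normalize_name(syn))]
  syn <- syn[normalize_name(syn) != normalize_name(preferred_name)]
  structure(list(concept_id = as.character(concept_id),
                 preferred_name = preferred_name,
                 synonyms = syn,
                 definition = definition %||% "",
                 category = category),
            class = "rd_concept")
}

#' @export
print.rd_concept <- function(x, ...) {
  cat(sprintf("<%s> %s [%s]\n", x$concept_id, x$preferred_name, x$category))
  if (length(x$synonyms)) cat("  synonyms:", paste(x$synonyms, collapse = "; "), "\n")
  if (nzchar(x$definition)) cat("  def:", x$definition, "\n")
  invisible(x)
}

# ---- OBO parsing -----------------------------------------------------------

# Minimal reader for OBO [Term] stanzas: id, name, synonym, def, is_obsolete.
parse_obo <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  terms <- list()
  cur <- NULL
  cur_line <- 0L
  flush <- function(cur, where) {
    if (is.null(cur)) return(NULL)
    if (is.null(cur$name)) {
      stop(sprintf("OBO stanza starting at line %d of %s has no name", where, path))
    }
    cur
  }
  in_term <- FALSE
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line) || startsWith(line, "!")) next
    if (grepl("^\\[.*\\]$", line)) {
      t <- flush(cur, cur_line)
      if (!is.null(t)) terms[[length(terms) + 1L]] <- t
      cur <- NULL
      in_term <- identical(line, "[Term]")
      if (in_term) {
        cur <- list(synonyms = character(0), obsolete = FALSE)
        cur_line <- i
      }
      next
    }
    if (!in_term) next
    kv <- regmatches(line, regexec("^([A-Za-z_]+):\\s*(.*)$", line))[[1L]]
    if (length(kv) != 3L) {
      stop(sprintf("unparseable OBO line %d in %s: %s", i, path, line))
    }
    key <- kv[2L]; val <- kv[3L]
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "def") cur$def <- first_quoted(val)
    else if (key == "synonym") cur$synonyms <- c(cur$synonyms, first_quoted(val))
    else if (key == "is_obsolete") cur$obsolete <- identical(tolower(val), "true")
    else if (key == "subset") cur$category <- val  # carries phenotype marking
    # other tags ignored
  }
  t <- flush(cur, cur_line)
  if (!is.null(t)) terms[[length(terms) + 1L]] <- t
  terms
}

first_quoted <- function(x) {
  m <- regmatches(x, regexec('"((?:[^"\\\\]|\\\\.)*)"', x))[[1L]]
  if (length(m) == 2L) gsub('\\\\(.)', "\\1", m[2L]) else x
}

# ---- TSV compiled dialect --------------------------------------------------

# Columns: id, name, synonyms (pipe-separated), definition.
parse_concept_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE, colClasses = "character",
                          encoding = "UTF-8")
  need <- c("id", "name", "synonyms", "definition")
  if (!all(need %in% names(df))) {
    stop("TSV concept file ", path, " must have columns: ",
         paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    if (!nzchar(df$name[i])) stop("TSV row ", i, " of ", path, " has empty name")
    syn <- strsplit(df$synonyms[i], "|", fixed = TRUE)[[1L]]
    list(id = df$id[i], name = df$name[i], synonyms = syn[nzchar(syn)],
         def = df$definition[i], obsolete = FALSE,
         category = if ("category" %in% names(df)) df$category[i])
  })
}

read_ontology_source <- function(source, dialect = c("auto", "obo", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.obo$", source, ignore.case = TRUE)) "obo" else "tsv"
  }
  if (dialect == "obo") parse_obo(source) else parse_concept_tsv(source)
}

# ---- lexicon compilation ---------------------------------------------------

new_lexicon <- function() {
  structure(list(index = new.env(parent = emptyenv(), hash = TRUE)),
            class = "rd_lexicon")
}

lexicon_insert <- function(lex, key, concept, conflicts) {
  key <- normalize_name(key)
  if (!nzchar(key)) return(conflicts)
  existing <- get0(key, envir = lex$index, inherits = FALSE)
  if (is.null(existing)) {
    assign(key, concept, envir = lex$index)
  } else if (!identical(existing$concept_id, concept$concept_id)) {
    # first-seen concept wins; record the losing claim
    conflicts <- c(conflicts, sprintf("'%s': kept %s, ignored %s", key,
                                      existing$concept_id, concept$concept_id))
  }
  conflicts
}

#' Number of distinct keys in a lexicon
#' @param lex An `rd_lexicon`.
#' @return Integer key count.
#' @export
lexicon_size <- function(lex) length(ls(lex$index))

#' Keys of a lexicon
#' @param lex An `rd_lexicon`.
#' @return Character vector of normalized index keys.
#' @export
lexicon_keys <- function(lex) ls(lex$index)

compile_lexicon <- function(source, dialect, category_for, include_synonyms) {
  terms <- if (is.list(source) && !is.character(source)) source
           else read_ontology_source(source, dialect)
  lex <- new_lexicon()
  conflicts <- character(0)
  for (t in terms) {
    if (isTRUE(t$obsolete)) next
    concept <- new_concept(t$id %||% t$name, t$name, t$synonyms %||% character(0),
                           t$def %||% "", category_for(t))
    conflicts <- lexicon_insert(lex, concept$preferred_name, concept, conflicts)
    if (include_synonyms) {
      for (s in concept$synonyms) conflicts <- lexicon_insert(lex, s, concept, conflicts)
    }
  }
  if (length(conflicts)) {
    message("duplicate lexicon names resolved first-seen-wins:\n  ",
            paste(conflicts, collapse = "\n  "))
  }
  lex
}

#' Compile the rare-disease lexicon
#'
#' Builds a name-to-concept index from a rare-disease ontology source
#' (emulating ORDO): every non-obsolete term is indexed under its preferred
#' name and, optionally, each synonym, with category `rare_disease`.
#' Definitions are carried along for prompt knowledge slots. Keys are
#' case-folded and whitespace-normalized; duplicate names resolve
#' first-seen-wins with a message.
#'
#' @param source Path to an `.obo` file or a compiled TSV
#'   (columns `id`, `name`, `synonyms` pipe-separated, `definition`).
#' @param dialect `"auto"` (by extension), `"obo"` or `"tsv"`.
#' @param include_synonyms Index synonyms in addition to preferred names.
#' @return An `rd_lexicon`.
#' @export
compile_rare_disease_lexicon <- function(source, dialect = "auto",
                                         include_synonyms = TRUE) {
  compile_lexicon(source, dialect, function(t) "rare_disease", include_synonyms)
}

#' Compile the general concept lexicon
#'
#' Builds the dictionary used for string matching (emulating Mondo): disease,
#' symptom and sign concepts with their definitions. Terms carrying a
#' `category` field of `phenotype` keep it; everything else defaults to
#' `disease`. TSV sources may add a fifth `category` column.
#'
#' @inheritParams compile_rare_disease_lexicon
#' @return An `rd_lexicon`.
#' @export
compile_concept_lexicon <- function(source, dialect = "auto",
                                    include_synonyms = TRUE) {
  compile_lexicon(source, dialect, function(t) {
    cat <- t$category %||% "disease"
    if (identical(cat, "phenotype")) "phenotype" else "disease"
  }, include_synonyms)
}

#' Compile the association-triple index
#'
#' Groups (rare disease, frequency, phenotype) triples (emulating HOOM) by
#' case-folded rare-disease name, preserving input order within each group.
#' Rows missing any of the three fields are skipped with a warning.
#'
#' @param source Path to a TSV with columns `rare_disease`, `frequency`,
#'   `phenotype`, or a data.frame with those columns.
#' @return An `rd_assoc_index`: environment mapping normalized rare-disease
#'   name to a data.frame of its triples.
#' @export
compile_association_index <- function(source) {
  df <- if (is.data.frame(source)) source
        else utils::read.delim(source, sep = "\t", quote = "",
                               stringsAsFactors = FALSE,
                               colClasses = "character", encoding = "UTF-8")
  need <- c("rare_disease", "frequency", "phenotype")
  if (!all(need %in% names(df))) {
    stop("association source must have columns: ", paste(need, collapse = ", "))
  }
  ok <- nzchar(df$rare_disease) & nzchar(df$frequency) & nzchar(df$phenotype)
  if (any(!ok)) {
    warning(sum(!ok), " association row(s) missing a field were skipped")
    df <- df[ok, , drop = FALSE]
  }
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  if (nrow(df)) {
    keys <- normalize_name(df$rare_disease)
    for (k in unique(keys)) {
      assign(k, df[keys == k, need, drop = FALSE], envir = idx)
    }
  }
  structure(list(index = idx), class = "rd_assoc_index")
}

#' Assemble a knowledge base
#'
#' @param rare_disease_lexicon `rd_lexicon` of rare diseases.
#' @param concept_lexicon `rd_lexicon` of diseases/phenotypes for dictionary
#'   matching.
#' @param association_index `rd_assoc_index` of rare-disease/phenotype
#'   frequency triples.
#' @return An `rd_kb` object.
#' @export
knowledge_base <- function(rare_disease_lexicon, concept_lexicon,
                           association_index) {
  stopifnot(inherits(rare_disease_lexicon, "rd_lexicon"),
            inherits(concept_lexicon, "rd_lexicon"),
            inherits(association_index, "rd_assoc_index"))
  structure(list(rare_disease_lexicon = rare_disease_lexicon,
                 concept_lexicon = concept_lexicon,
                 association_index = association_index),
            class = "rd_kb")
}

#' @export
print.rd_kb <- function(x, ...) {
  cat("Rare-disease knowledge base\n")
  cat("  rare-disease lexicon:", lexicon_size(x$rare_disease_lexicon), "keys\n")
  cat("  concept lexicon:     ", lexicon_size(x$concept_lexicon), "keys\n")
  cat("  association index:   ", length(ls(x$association_index$index)),
      "rare diseases\n")
  invisible(x)
}

#' Compile a knowledge base from ontology files
#'
#' @param ordo,mondo Ontology sources (OBO or TSV) for rare diseases and for
#'   the general concept dictionary.
#' @param hoom TSV source of association triples.
#' @param include_synonyms Index synonyms (applies to both lexicons).
#' @return An `rd_kb`.
#' @export
compile_kb <- function(ordo, mondo, hoom, include_synonyms = TRUE) {
  knowledge_base(
    compile_rare_disease_lexicon(ordo, include_synonyms = include_synonyms),
    compile_concept_lexicon(mondo, include_synonyms = include_synonyms),
    compile_association_index(hoom)
  )
}

#' Look up a rare disease by name
#'
#' Case-insensitive exact match against preferred names and synonyms.
#' Absence is a value (`NULL`), not an error.
#'
#' @param kb An `rd_kb`.
#' @param name Candidate name.
#' @return The matching `rd_concept`, or `NULL`.
#' @export
lookup_rare_disease <- function(kb, name) {
  get0(normalize_name(name), envir = kb$rare_disease_lexicon$index,
       inherits = FALSE)
}

#' Look up a concept in the general lexicon
#' @inheritParams lookup_rare_disease
#' @return The matching `rd_concept`, or `NULL`.
#' @export
lookup_concept <- function(kb, name) {
  get0(normalize_name(name), envir = kb$concept_lexicon$index, inherits = FALSE)
}

#' Look up association triples for a rare disease
#'
#' @inheritParams lookup_rare_disease
#' @return A data.frame with columns `rare_disease`, `frequency`,
#'   `phenotype`; zero rows when the key is absent.
#' @export
lookup_associations <- function(kb, name) {
  hit <- get0(normalize_name(name), envir = kb$association_index$index,
              inherits = FALSE)
  hit %||% data.frame(rare_disease = character(0), frequency = character(0),
                      phenotype = character(0), stringsAsFactors = FALSE)
}

#' Write a knowledge base in the compiled TSV dialect
#'
#' Emits `rare_diseases.tsv`, `concepts.tsv` (id, name, synonyms, definition,
#' category) and `associations.tsv` into `dir`.
#'
#' @param kb An `rd_kb`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_kb_tsv <- function(kb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dump_lex <- function(lex, path) {
    keys <- lexicon_keys(lex)
    seen <- character(0)
    rows <- list()
    for (k in keys) {
      cpt <- get(k, envir = lex$index)
      if (cpt$concept_id %in% seen) next
      seen <- c(seen, cpt$concept_id)
      rows[[length(rows) + 1L]] <- data.frame(
        id = cpt$concept_id, name = cpt$preferred_name,
        synonyms = paste(cpt$synonyms, collapse = "|"),
        definition = cpt$definition, category = cpt$category,
        stringsAsFactors = FALSE)
    }
    df <- if (length(rows)) do.call(rbind, rows)
          else data.frame(id = character(0), name = character(0),
                          synonyms = character(0), definition = character(0),
                          category = character(0))
    df <- df[order(df$id), , drop = FALSE]
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  dump_lex(kb$rare_disease_lexicon, file.path(dir, "rare_diseases.tsv"))
  dump_lex(kb$concept_lexicon, file.path(dir, "concepts.tsv"))
  keys <- ls(kb$association_index$index)
  assoc <- if (length(keys)) {
    do.call(rbind, lapply(sort(keys),
                          function(k) get(k, envir = kb$association_index$index)))
  } else {
    data.frame(rare_disease = character(0), frequency = character(0),
               phenotype = character(0))
  }
  utils::write.table(assoc, file.path(dir, "associations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(dir)
}
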