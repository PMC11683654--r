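#' @title Dictionary term matching with negation detection
#'
#' @description
#' Step 1 of entity extraction: case-insensitive, word-boundary,
#' longest-match-wins scanning of segment text against the compiled concept
#' lexicon. Matches carry the concept's definition into the prompt slots.
#' A small regex-driven negation detector flags matches preceded by a
#' negation cue within a token window, with clause boundaries (period,
#' semicolon) blocking the scope. Negated matches are kept and flagged, not
#' dropped; the flag is surfaced to the language model.
#'
#' @name term_matcher
NULL

#' The built-in negation cue list
#'
#' @return Character vector of cues (read from the packaged lexicon file,
#'   one cue per line; user-extendable via [negation_lexicon()]).
#' @export
default_negation_cues <- function() {
  path <- system.file("extdata", "negation_lexicon.txt", package = "raremine")
  cues <- readLines(path, encoding = "UTF-8", warn = FALSE)
  cues[nzchar(trimws(cues))]
}

#' Construct a negation lexicon
#'
#' @param keywords Negation cue strings (possibly multi-word).
#' @param window_tokens Scope: a cue negates a match when it ends within
#'   this many tokens before the match with no intervening clause boundary.
#' @return An `rd_negation_lexicon`.
#' @export
negation_lexicon <- function(keywords = default_negation_cues(),
                             window_tokens = 5L) {
  stopifnot(length(keywords) >= 1L, window_tokens >= 1L)
  structure(list(keywords = tolower(keywords),
                 window_tokens = as.integer(window_tokens)),
            class = "rd_negation_lexicon")
}

# Word tokens = maximal alphanumeric runs; word boundaries are transitions
# between alphanumeric and non-alphanumeric characters.
word_tokens <- function(text) {
  m <- gregexpr("[[:alnum:]]+", text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(token = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  len <- attr(m, "match.length")
  data.frame(token = substring(text, m, m + len - 1L),
             start = as.integer(m - 1L), end = as.integer(m - 1L + len),
             stringsAsFactors = FALSE)
}

#' Match lexicon terms in a segment
#'
#' Scans left to right over word tokens; at each position the longest
#' indexed term wins and the scan resumes after it, so returned spans never
#' overlap. A candidate only counts when the raw surface, case-folded and
#' whitespace-collapsed, equals the index key (terms joined by anything but
#' whitespace do not match).
#'
#' @param segment_text Text to scan.
#' @param lexicon `rd_lexicon` (the concept lexicon).
#' @return data.frame of matches: `surface`, `concept_id`, `start`, `end`
#'   (0-based half-open into `segment_text`), `negated` (all `FALSE` here;
#'   see [annotate_negation()]), `definition`.
#' @export
match_terms <- function(segment_text, lexicon) {
  stopifnot(inherits(lexicon, "rd_lexicon"))
  empty <- data.frame(surface = character(0), concept_id = character(0),
                      start = integer(0), end = integer(0),
                      negated = logical(0), definition = character(0),
                      stringsAsFactors = FALSE)
  toks <- word_tokens(segment_text)
  if (!nrow(toks)) return(empty)
  max_len <- max(c(1L, vapply(lexicon_keys(lexicon),
                              function(k) length(strsplit(k, " ", fixed = TRUE)[[1L]]),
                              1L)))
  rows <- list()
  i <- 1L
  n <- nrow(toks)
  while (i <= n) {
    hit_len <- 0L
    hit <- NULL
    for (L in seq.int(min(max_len, n - i + 1L), 1L)) {
      s <- toks$start[i]; e <- toks$end[i + L - 1L]
      surface <- substring(segment_text, s + 1L, e)
      key <- normalize_name(surface)
      cpt <- get0(key, envir = lexicon$index, inherits = FALSE)
      if (!is.null(cpt)) { hit_len <- L; hit <- list(cpt, s, e, surface); break }
    }
    if (hit_len > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        surface = hit[[4L]], concept_id = hit[[1L]]$concept_id,
        start = hit[[2L]], end = hit[[3L]], negated = FALSE,
        definition = hit[[1L]]$definition, stringsAsFactors = FALSE)
      i <- i + hit_len
    } else {
      i <- i + 1L
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Decide whether a single match is negated
#'
#' True iff a negation cue ends within `neg$window_tokens` word tokens
#' preceding the match with no clause boundary (`.` or `;`) between the cue
#' and the match. Pure function of `(text, span, lexicon)`.
#'
#' @param segment_text Segment text.
#' @param start Match start offset (0-based).
#' @param neg `rd_negation_lexicon`.
#' @return Logical scalar.
#' @export
detect_negation <- function(segment_text, start, neg = negation_lexicon()) {
  prefix <- substring(segment_text, 1L, start)
  toks <- word_tokens(prefix)
  if (!nrow(toks)) return(FALSE)
  window_start_tok <- max(1L, nrow(toks) - neg$window_tokens + 1L)
  for (cue in neg$keywords) {
    cue_toks <- strsplit(cue, "[[:space:]]+")[[1L]]
    L <- length(cue_toks)
    # cue must END inside the window
    for (last in seq.int(nrow(toks), window_start_tok)) {
      first <- last - L + 1L
      if (first < 1L) next
      if (all(tolower(toks$token[first:last]) == cue_toks)) {
        between <- substring(segment_text, toks$end[last] + 1L, start)
        if (!grepl("[.;]", between)) return(TRUE)
      }
    }
  }
  FALSE
}

#' Flag negated matches
#'
#' Applies [detect_negation()] to every match, preserving order.
#'
#' @param matches data.frame from [match_terms()].
#' @param segment_text Segment text.
#' @param neg `rd_negation_lexicon`.
#' @return The matches with the `negated` column set.
#' @export
annotate_negation <- function(matches, segment_text, neg = negation_lexicon()) {
  if (!nrow(matches)) return(matches)
  matches$negated <- vapply(matches$start, function(s) {
    detect_negation(segment_text, s, neg)
  }, logical(1))
  matches
}
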