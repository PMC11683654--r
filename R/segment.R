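#' @title Document segmentation under a token budget
#'
#' @description
#' Language-model context limits force long documents to be processed in
#' slices. Segmentation packs consecutive paragraphs greedily while the
#' running token count stays under the budget (default 2000 tokens, chosen
#' against an 8000-token context with roughly 1000 instruction tokens).
#' Because relations occasionally straddle a segment boundary, bridge
#' windows centered on each boundary are re-submitted for relation
#' extraction only.
#'
#' @name preprocess
NULL

new_segment <- function(doc_id, seg_index, text, char_start, char_end,
                        is_bridge = FALSE) {
  structure(list(doc_id = doc_id, seg_index = seg_index, text = text,
                 char_start = char_start, char_end = char_end,
                 token_count = count_tokens(text), is_bridge = is_bridge),
            class = "rd_segment")
}

#' @export
print.rd_segment <- function(x, ...) {
  cat(sprintf("<rd_segment %s#%d%s> chars %d:%d, %d tokens\n", x$doc_id,
              x$seg_index, if (x$is_bridge) " bridge" else "", x$char_start,
              x$char_end, x$token_count))
  invisible(x)
}

# Paragraph boundaries: one or more blank lines. Returns 0-based half-open
# char spans covering the whole document (separators attached to the
# preceding paragraph so concatenation reconstructs the input).
paragraph_spans <- function(text) {
  n <- nchar(text)
  if (n == 0L) return(data.frame(start = integer(0), end = integer(0)))
  m <- gregexpr("\\n[ \t]*\\n[ \t\n]*", text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(data.frame(start = 0L, end = n))
  len <- attr(m, "match.length")
  sep_end <- as.integer(m - 1L + len)     # 0-based end of each separator
  starts <- c(0L, sep_end)
  ends <- c(sep_end, n)
  keep <- starts < ends
  data.frame(start = starts[keep], end = ends[keep])
}

# Sentence boundaries within a chunk: period/question/exclamation followed
# by whitespace. Spans cover the chunk.
sentence_spans <- function(text) {
  n <- nchar(text)
  if (n == 0L) return(data.frame(start = integer(0), end = integer(0)))
  m <- gregexpr("[.?!]+[ \t\n]+", text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(data.frame(start = 0L, end = n))
  len <- attr(m, "match.length")
  sep_end <- as.integer(m - 1L + len)
  starts <- c(0L, sep_end)
  ends <- c(sep_end, n)
  keep <- starts < ends
  data.frame(start = starts[keep], end = ends[keep])
}

#' Segment a document at paragraph boundaries under a token budget
#'
#' Greedily packs consecutive paragraphs (split on blank-line boundaries)
#' while the running token count stays strictly under `max_tokens`. A single
#' paragraph at or over budget falls back to sentence-boundary packing; an
#' unsplittable over-budget sentence is hard-wrapped at the token level with
#' a warning. Segment character spans are non-overlapping, ordered, and
#' cover the document, so concatenating segment texts reconstructs the
#' input exactly.
#'
#' @param text Document text.
#' @param max_tokens Token budget per segment (default 2000); segments
#'   satisfy `token_count < max_tokens`.
#' @param doc_id Document id recorded on each segment.
#' @return List of `rd_segment` with `is_bridge = FALSE`.
#' @export
segment_document <- function(text, max_tokens = 2000L, doc_id = "doc") {
  stopifnot(max_tokens >= 1)
  paras <- paragraph_spans(text)
  units <- list()
  for (i in seq_len(nrow(paras))) {
    s <- paras$start[i]; e <- paras$end[i]
    ptext <- substring(text, s + 1L, e)
    if (count_tokens(ptext) < max_tokens) {
      units[[length(units) + 1L]] <- c(s, e)
    } else {
      sent <- sentence_spans(ptext)
      for (j in seq_len(nrow(sent))) {
        ss <- s + sent$start[j]; se <- s + sent$end[j]
        stext <- substring(text, ss + 1L, se)
        if (count_tokens(stext) < max_tokens) {
          units[[length(units) + 1L]] <- c(ss, se)
        } else {
          # pathological unsplittable run: hard-wrap on token boundaries
          warning("hard-wrapping an over-budget sentence in ", doc_id)
          toks <- tokenize_text(stext)
          k <- 1L
          while (k <= nrow(toks)) {
            k2 <- min(k + max_tokens - 2L, nrow(toks))
            we <- if (k2 == nrow(toks)) se else ss + toks$end[k2]
            ws <- if (k == 1L) ss else ss + toks$start[k]
            # extend the first wrap back to the unit start, the last to its
            # end, so coverage is preserved
            units[[length(units) + 1L]] <- c(ws, we)
            k <- k2 + 1L
          }
        }
      }
    }
  }
  if (!length(units)) {
    return(list(new_segment(doc_id, 0L, text, 0L, nchar(text))))
  }
  # greedy packing of units
  segs <- list()
  cur_start <- units[[1L]][1L]
  cur_end <- units[[1L]][2L]
  for (u in units[-1L]) {
    cand <- substring(text, cur_start + 1L, u[2L])
    if (count_tokens(cand) < max_tokens) {
      cur_end <- u[2L]
    } else {
      segs[[length(segs) + 1L]] <- c(cur_start, cur_end)
      cur_start <- u[1L]; cur_end <- u[2L]
    }
  }
  segs[[length(segs) + 1L]] <- c(cur_start, cur_end)
  # absorb any leading/trailing slack so spans cover the full document
  segs[[1L]][1L] <- 0L
  segs[[length(segs)]][2L] <- nchar(text)
  for (k in seq_len(length(segs) - 1L)) segs[[k + 1L]][1L] <- segs[[k]][2L]
  lapply(seq_along(segs), function(k) {
    new_segment(doc_id, k - 1L,
                substring(text, segs[[k]][1L] + 1L, segs[[k]][2L]),
                segs[[k]][1L], segs[[k]][2L])
  })
}

#' Bridge windows across segment boundaries
#'
#' For each boundary between adjacent non-bridge segments, builds a window
#' centered on the boundary drawing up to `window_tokens / 2` tokens from
#' each side (clipped at the flanking segments' edges). Bridge windows are
#' used for relation re-extraction only.
#'
#' @param segments List of `rd_segment` from [segment_document()].
#' @param window_tokens Total window width in tokens (default 1000).
#' @param text Full document text (to slice windows from); when `NULL`,
#'   windows are sliced from the concatenated segment texts.
#' @return List of `rd_segment` with `is_bridge = TRUE`; empty when fewer
#'   than two segments.
#' @export
bridge_windows <- function(segments, window_tokens = 1000L, text = NULL) {
  segments <- Filter(function(s) !s$is_bridge, segments)
  if (length(segments) < 2L) return(list())
  if (is.null(text)) {
    text <- paste(vapply(segments, `[[`, "", "text"), collapse = "")
  }
  half <- max(1L, floor(window_tokens / 2))
  out <- list()
  for (k in seq_len(length(segments) - 1L)) {
    left <- segments[[k]]; right <- segments[[k + 1L]]
    ltoks <- tokenize_text(left$text)
    rtoks <- tokenize_text(right$text)
    ws <- if (nrow(ltoks) <= half) left$char_start
          else left$char_start + ltoks$start[nrow(ltoks) - half + 1L]
    we <- if (nrow(rtoks) <= half) right$char_end
          else right$char_start + rtoks$end[half]
    out[[length(out) + 1L]] <- new_segment(
      left$doc_id, k - 1L, substring(text, ws + 1L, we), ws, we,
      is_bridge = TRUE)
  }
  out
}
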