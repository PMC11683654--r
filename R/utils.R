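#' Normalize an entity or concept name
#'
#' Case-folds, trims leading/trailing whitespace and collapses internal
#' whitespace runs to a single space. This is the single string-equality
#' notion used everywhere: lexicon keys, entity alignment during knowledge
#' graph construction, and name matching during scoring. Idempotent.
#'
#' @param x Character vector of names.
#' @return Character vector of normalized names.
#' @examples
#' normalize_name("Fryns Syndrome")
#' normalize_name("  giant  cell myocarditis ")
#' @export
normalize_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

#' Round half away from zero
#'
#' Report-time rounding rule: ties round up in magnitude (2.25 -> 2.3,
#' -2.25 -> -2.3), unlike base R's round-half-even. Internal metric math is
#' never rounded; this is applied only when rendering tables.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Tokenize text into whitespace-delimited tokens with character offsets
#'
#' The package's token counter: a token is a maximal run of non-whitespace
#' characters. Offsets are 0-based half-open into `text`.
#'
#' @param text A single string.
#' @return A data.frame with columns `token`, `start`, `end` (0-based
#'   half-open character offsets).
#' @export
tokenize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(token = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  m <- gregexpr("\\S+", text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(token = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  len <- attr(m, "match.length")
  data.frame(token = substring(text, m, m + len - 1L),
             start = as.integer(m - 1L),
             end = as.integer(m - 1L + len),
             stringsAsFactors = FALSE)
}

#' Count tokens in a text
#'
#' Deterministic token count under the whitespace tokenizer. Empty text
#' counts as 0 tokens; `count_tokens(paste(a, b)) >= count_tokens(a)`.
#'
#' @param text A single string.
#' @param tokenizer Tokenizer name; only `"whitespace"` is provided.
#' @return Integer token count.
#' @export
count_tokens <- function(text, tokenizer = "whitespace") {
  if (!identical(tokenizer, "whitespace")) {
    stop("unknown tokenizer: ", tokenizer)
  }
  nrow(tokenize_text(text))
}

# Deterministic 31-bit polynomial string hash, used to derive reproducible
# RNG streams for the mock backend from (seed, prompt marker). Arithmetic in
# doubles stays exact: h < 2^31 and h*131 + 255 < 2^39 < 2^53.
str_hash31 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. Keeps the mock backend a pure function of its inputs.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Read a whole file preserving the exact byte content as one string.
read_text_file <- function(path) {
  n <- file.info(path)$size
  if (is.na(n)) stop("cannot read file: ", path)
  txt <- readChar(path, n, useBytes = TRUE)
  Encoding(txt) <- "UTF-8"
  txt
}
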