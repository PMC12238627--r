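#' Normalize an expression
#'
#' Lowercases the input, strips leading/trailing whitespace and collapses
#' internal runs of whitespace to single spaces. This is the canonical form
#' used for embedding-cache keys, duplicate detection and routing.
#'
#' @param text Character scalar. Must be non-empty after trimming.
#' @return The normalized character scalar.
#' @examples
#' normalize_expression("  Ice  CREAM ") # "ice cream"
#' @export
normalize_expression <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stopf("`text` must be a single character string", class = "concretr_empty_input")
  }
  out <- tolower(trimws(text))
  out <- gsub("[[:space:]]+", " ", out)
  if (!nzchar(out)) {
    stopf("input is empty after trimming", class = "concretr_empty_input")
  }
  out
}

#' Join a multi-word expression into a single token
#'
#' Whitespace-separated tokens are concatenated with underscores (e.g.
#' "ice cream" becomes "ice_cream") so that downstream embedding backends
#' treat the expression as one token.
#'
#' @param text Character scalar with at least two whitespace-separated tokens;
#'   a single token is returned unchanged with a warning.
#' @return Character scalar with spaces replaced by underscores.
#' @export
join_multiword <- function(text) {
  text <- normalize_expression(text)
  if (!grepl(" ", text, fixed = TRUE)) {
    warnf("'%s' is a single token; nothing to join", text)
    return(text)
  }
  gsub(" ", "_", text, fixed = TRUE)
}

# Characters permitted inside expressions after cleaning: Unicode letters,
# digits, space, hyphen, underscore, apostrophe.
.allowed_chars_regex <- "^[\\p{L}\\p{N} _'-]+$"

has_only_allowed_chars <- function(x) {
  grepl(.allowed_chars_regex, x, perl = TRUE)
}

# Map typographic punctuation to ASCII equivalents and drop control chars.
normalize_punctuation <- function(text) {
  text <- gsub("[‐‑‒–—―−]", "-", text)
  text <- gsub("[‘’‚ʼ]", "'", text)
  text <- gsub("[“”„]", "\"", text)
  text <- gsub("…", "...", text)
  gsub("[[:cntrl:]]", " ", text)
}

#' Clean raw or translated text for prediction
#'
#' Applies the shared cleaning pipeline used for both original inputs and
#' machine-translation output: punctuation normalization to ASCII, removal of
#' standalone articles ("a", "an", "the") and conjunctions ("and", "or",
#' "but"), truncation of trailing ellipsis periods, hyphen normalization and
#' case normalization. Article/conjunction matching is whole-token and
#' case-insensitive; substrings ("theory") are never touched.
#'
#' @param text Character scalar.
#' @param remove_articles,remove_conjunctions,normalize_punct Logical flags
#'   toggling the individual rules.
#' @return Cleaned character scalar; `""` when cleaning removes every token
#'   (callers fall back on the uncleaned input).
#' @examples
#' clean_translation("The freedom")      # "freedom"
#' clean_translation("bread and butter") # "bread butter"
#' @export
clean_translation <- function(text, remove_articles = TRUE,
                              remove_conjunctions = TRUE,
                              normalize_punct = TRUE) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stopf("`text` must be a single character string", class = "concretr_empty_input")
  }
  out <- text
  if (normalize_punct) out <- normalize_punctuation(out)
  out <- tolower(trimws(gsub("[[:space:]]+", " ", out)))
  # trailing ellipsis / sentence periods
  out <- sub("[.]+$", "", out)
  out <- trimws(out)
  if (!nzchar(out)) return("")
  toks <- strsplit(out, " ", fixed = TRUE)[[1]]
  drop <- character(0)
  if (remove_articles) drop <- c(drop, "a", "an", "the")
  if (remove_conjunctions) drop <- c(drop, "and", "or", "but")
  toks <- toks[!(toks %in% drop)]
  paste(toks, collapse = " ")
}

#' Classify an expression for model routing
#'
#' Tokenizes normalized text on whitespace with a secondary punctuation-aware
#' pass (surrounding punctuation is stripped from tokens; internal hyphens,
#' underscores and apostrophes are kept). Hyphenated compounds such as
#' "self-esteem" count as one token. Inputs are classified as
#' `"single"` (one token), `"sentence"` (requested by the caller, or ending
#' in sentence punctuation with >= 3 tokens, or longer than ten words) or
#' `"multi"` otherwise.
#'
#' @param text Character scalar.
#' @param sentence Logical; `TRUE` forces sentence classification (per-word
#'   rating), `NA` (default) applies the heuristic.
#' @return An object of class `"expression_info"`: a list with elements
#'   `raw`, `normalized`, `tokens` and `kind`.
#' @examples
#' classify_expression("self-esteem")$kind # "single"
#' classify_expression("ice cream")$kind   # "multi"
#' @export
classify_expression <- function(text, sentence = NA) {
  raw <- text
  normalized <- normalize_expression(normalize_punctuation(text))
  ends_sentence <- grepl("[.!?]$", normalized)
  toks <- strsplit(normalized, " ", fixed = TRUE)[[1]]
  # secondary pass: strip surrounding punctuation, keep word-internal marks
  toks <- gsub("^[^\\p{L}\\p{N}_]+|[^\\p{L}\\p{N}_'-]+$", "", toks, perl = TRUE)
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) {
    stopf("no tokens remain after tokenization", class = "concretr_empty_input")
  }
  kind <- if (isTRUE(sentence)) {
    "sentence"
  } else if (length(toks) == 1L) {
    "single"
  } else if (!isFALSE(sentence) && ((ends_sentence && length(toks) >= 3L) ||
                                    length(toks) > 10L)) {
    "sentence"
  } else {
    "multi"
  }
  structure(
    list(raw = raw, normalized = normalized, tokens = toks, kind = kind),
    class = "expression_info"
  )
}

#' @export
print.expression_info <- function(x, ...) {
  cat(sprintf("<expression: '%s' kind=%s tokens=%d>\n",
              x$normalized, x$kind, length(x$tokens)))
  invisible(x)
}
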