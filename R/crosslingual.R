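# Small stopword/diacritic evidence tables for the heuristic detector.
.lang_evidence <- list(
  en = list(stop = c("the", "a", "an", "and", "or", "of", "to", "in", "is",
                     "it", "that", "for", "with", "on", "dog", "house"),
            chars = ""),
  et = list(stop = c("ja", "on", "ei", "see", "ta", "ma", "kas", "koer",
                     "maja", "vesi", "olema", "mis"),
            chars = "õäöüšž"),
  de = list(stop = c("der", "die", "das", "und", "ist", "ein", "eine", "nicht",
                     "ich", "mit"),
            chars = "äöüß"),
  fr = list(stop = c("le", "la", "les", "et", "est", "un", "une", "je", "de",
                     "pas"),
            chars = "éèêàçùâî"),
  es = list(stop = c("el", "los", "las", "y", "es", "un", "una", "no", "que",
                     "de"),
            chars = "ñáéíóú¿¡")
)

#' Built-in heuristic language detector
#'
#' A lightweight lexical detector scoring a handful of languages by stopword
#' hits and diacritic evidence. It exists so the detection contract can be
#' exercised deterministically offline; any function returning
#' `list(language, confidence)` can replace it.
#'
#' @param text Character scalar.
#' @return List with `language` (code or `"unknown"`), `confidence` in
#'   `[0, 1]`, and `runner_up_confidence`.
#' @export
heuristic_detector <- function(text) {
  low <- tolower(text)
  toks <- strsplit(gsub("[^\\p{L}']+", " ", low, perl = TRUE), " +")[[1]]
  toks <- toks[nzchar(toks)]
  scores <- vapply(.lang_evidence, function(ev) {
    s <- if (length(toks)) sum(toks %in% ev$stop) else 0
    if (nzchar(ev$chars) && grepl(sprintf("[%s]", ev$chars), low)) s <- s + 2
    s
  }, numeric(1))
  total <- sum(scores)
  if (total == 0) {
    return(list(language = "unknown", confidence = 0,
                runner_up_confidence = 0))
  }
  conf <- scores / total
  ord <- order(conf, decreasing = TRUE)
  list(language = names(conf)[ord[1]], confidence = unname(conf[ord[1]]),
       runner_up_confidence = unname(conf[ord[2]]))
}

#' Detect the language of an input
#'
#' Wraps a pluggable detector with the fallback policy: detections below the
#' confidence threshold, failures, and unknown languages all default to
#' English processing with a fallback flag. Mixed-language inputs — where
#' the runner-up language scores close to the winner — keep the top language
#' but are flagged for manual review.
#'
#' @param text Non-empty character scalar.
#' @param threshold Confidence threshold below which detection falls back to
#'   English (default 0.90).
#' @param detector Detector function; defaults to [heuristic_detector()].
#' @return An object of class `detection_result`: list with `language_code`,
#'   `confidence`, `fallback` and `review` flags.
#' @export
detect_language <- function(text, threshold = 0.90,
                            detector = heuristic_detector) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(trimws(text)))
  det <- tryCatch(detector(text), error = function(e) NULL)
  fallback <- FALSE; review <- FALSE
  if (is.null(det) || is.null(det$language) || det$language == "unknown" ||
      !is_scalar_number(det$confidence) || det$confidence < threshold) {
    lang <- "en"
    conf <- if (!is.null(det) && is_scalar_number(det$confidence)) {
      det$confidence
    } else 0
    fallback <- TRUE
  } else {
    lang <- det$language
    conf <- det$confidence
    ru <- det$runner_up_confidence %||% 0
    if (ru > 0 && conf - ru < 0.15) review <- TRUE
  }
  structure(list(language_code = lang, confidence = conf,
                 fallback = fallback, review = review),
            class = "detection_result")
}

#' Translation adapters
#'
#' A translator adapter is a list with a `translate(text, source_lang)`
#' function returning a data.frame of ranked `candidate` strings with
#' `score`s, a `name`, and a `config` (beam size 5, maximum sequence length
#' 128 tokens, target forced to English). Heavy neural translators plug in
#' behind this contract; the package ships two deterministic adapters:
#' `echo_adapter()` returns the input unchanged, `dictionary_adapter()`
#' looks tokens up in a user-supplied lexicon.
#'
#' @param lexicon Named character vector mapping source tokens to English.
#' @return A translator adapter.
#' @export
echo_adapter <- function() {
  structure(list(
    name = "echo",
    config = list(beam_size = 5, max_tokens = 128, target = "en"),
    translate = function(text, source_lang) {
      data.frame(candidate = text, score = 0, stringsAsFactors = FALSE)
    }
  ), class = "translator_adapter")
}

#' @rdname echo_adapter
#' @export
dictionary_adapter <- function(lexicon) {
  stopifnot(is.character(lexicon), !is.null(names(lexicon)))
  structure(list(
    name = "dictionary",
    config = list(beam_size = 5, max_tokens = 128, target = "en"),
    translate = function(text, source_lang) {
      toks <- strsplit(tolower(trimws(text)), "[[:space:]]+")[[1]]
      hit <- toks %in% names(lexicon)
      if (!any(hit)) {
        return(data.frame(candidate = character(0), score = numeric(0)))
      }
      out <- ifelse(hit, lexicon[toks], toks)
      data.frame(candidate = paste(out, collapse = " "),
                 score = mean(hit), stringsAsFactors = FALSE)
    }
  ), class = "translator_adapter")
}

# Permitted characters in verified translations: the expression character
# set plus basic sentence punctuation.
translation_charset_ok <- function(x) {
  grepl("^[\\p{L}\\p{N} _'.,;:!?\"()-]+$", x, perl = TRUE)
}

#' Verify a translation candidate
#'
#' A candidate passes when (1) the character-length ratio
#' `nchar(candidate) / nchar(source)` lies within `length_bounds`,
#' (2) its character set is within the permitted set, and (3) the cosine
#' similarity between the source and candidate embeddings is at least
#' `similarity_floor`. Checks run in that order and the first failure is
#' reported.
#'
#' @param source,candidate Non-empty character scalars.
#' @param embed_fn Function `text -> numeric vector` used for the semantic
#'   similarity check (typically the base backend's embedding).
#' @param length_bounds Two-element numeric (default `c(0.2, 5)`).
#' @param similarity_floor Minimum cosine similarity (default 0.2).
#' @return One of `"passed"`, `"failed-length"`, `"failed-charset"`,
#'   `"failed-similarity"`.
#' @export
verify_translation <- function(source, candidate, embed_fn,
                               length_bounds = c(0.2, 5),
                               similarity_floor = 0.2) {
  stopifnot(nzchar(source), nzchar(candidate))
  ratio <- nchar(candidate) / nchar(source)
  if (ratio < length_bounds[1] || ratio > length_bounds[2]) {
    return("failed-length")
  }
  if (!translation_charset_ok(candidate)) return("failed-charset")
  a <- as.numeric(embed_fn(source)); b <- as.numeric(embed_fn(candidate))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  sim <- if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
  if (sim < similarity_floor) return("failed-similarity")
  "passed"
}

#' Resolve among ranked translation candidates
#'
#' Among candidates passing [verify_translation()], returns the one with the
#' highest embedding similarity to the source (ties broken by beam rank).
#' When no candidate passes, the top-beam candidate is returned flagged for
#' review.
#'
#' @param candidates Character vector in beam-rank order.
#' @param source Source text.
#' @param embed_fn Embedding function as in [verify_translation()].
#' @return List with `english_text`, `review` flag and per-candidate
#'   `verification` statuses.
#' @export
resolve_candidates <- function(candidates, source, embed_fn) {
  stopifnot(length(candidates) >= 1)
  status <- vapply(candidates, verify_translation, character(1),
                   source = source, embed_fn = embed_fn, USE.NAMES = FALSE)
  passing <- which(status == "passed")
  if (length(passing) == 0) {
    return(list(english_text = candidates[1], review = TRUE,
                verification = status))
  }
  sims <- vapply(candidates[passing], function(cand) {
    a <- as.numeric(embed_fn(source)); b <- as.numeric(embed_fn(cand))
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
  }, numeric(1), USE.NAMES = FALSE)
  # which.max takes the first maximum, i.e. the best beam rank on ties
  pick <- passing[which.max(sims)]
  list(english_text = candidates[pick], review = FALSE, verification = status)
}

#' Translate text to English through an adapter
#'
#' Invokes the adapter (beam size 5, maximum length 128, forced-English
#' target, per its config), verifies the candidates, and resolves to a
#' single English text. An empty candidate list engages the fallback: the
#' source text is passed through untranslated and flagged.
#'
#' @param text Source text (non-English).
#' @param source_lang Source language code (must not be `"en"`).
#' @param adapter A translator adapter, e.g. [echo_adapter()].
#' @param embed_fn Embedding function for verification; defaults to a
#'   character-frequency embedding adequate for test doubles.
#' @return An object of class `translation_result`: list with
#'   `source_text`, `source_lang`, `english_text`, `verification`,
#'   `fallback_used`, `review`.
#' @export
translate_to_english <- function(text, source_lang, adapter,
                                 embed_fn = char_ngram_embed) {
  stopifnot(source_lang != "en")
  cands <- tryCatch(adapter$translate(text, source_lang), error = function(e) {
    stopf("translation of '%s' failed: %s", text, conditionMessage(e),
          class = "concretr_translation")
  })
  if (is.null(cands) || nrow(cands) == 0) {
    return(structure(list(source_text = text, source_lang = source_lang,
                          english_text = text, verification = "empty",
                          fallback_used = TRUE, review = TRUE),
                     class = "translation_result"))
  }
  res <- resolve_candidates(as.character(cands$candidate), text, embed_fn)
  structure(list(source_text = text, source_lang = source_lang,
                 english_text = res$english_text,
                 verification = res$verification,
                 fallback_used = FALSE, review = res$review),
            class = "translation_result")
}

#' Character-trigram bag embedding
#'
#' A deterministic text embedding based on hashed character trigrams; used
#' as the default similarity embedder for translation verification when no
#' backend is supplied. Identical strings map to identical vectors and
#' near-identical strings to similar ones.
#'
#' @param text Character scalar.
#' @param dim Dimensionality (default 64).
#' @return Numeric vector of length `dim`.
#' @export
char_ngram_embed <- function(text, dim = 64) {
  x <- paste0("^", tolower(text), "$")
  n <- nchar(x)
  v <- numeric(dim)
  if (n < 3) {
    v[token_hash(x) %% dim + 1] <- 1
    return(v)
  }
  for (i in seq_len(n - 2)) {
    tri <- substr(x, i, i + 2)
    v[token_hash(tri) %% dim + 1] <- v[token_hash(tri) %% dim + 1] + 1
  }
  v
}
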