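#' Train a model bundle
#'
#' Builds the two-model prediction bundle: a single-word regressor and a
#' multi-word regressor, each trained on dual (base + emotion) embeddings of
#' its corpus with its own feature standardizer. Both models share the same
#' backend pair. The single-word training mean is stored as the fallback
#' score for unprocessable inputs.
#'
#' @param single_corpus A [rating_corpus()] of single-word norms (two-word
#'   expressions are underscore-joined automatically).
#' @param multi_corpus Optional [rating_corpus()] of multi-word norms; when
#'   `NULL` the single-word model is reused for multi-word routing.
#' @param backends List with elements `base` and `emotion`
#'   ([embedding_backend()]s).
#' @param config A [train_config()].
#' @param cache Optional [embedding_cache()].
#' @return An object of class `model_bundle`.
#' @export
train_model_bundle <- function(single_corpus, multi_corpus = NULL, backends,
                               config = train_config(), cache = NULL) {
  stopifnot(inherits(single_corpus, "rating_corpus"),
            inherits(backends$base, "embedding_backend"),
            inherits(backends$emotion, "embedding_backend"))
  fit_one <- function(corpus) {
    tokens <- vapply(corpus$expression, function(e) {
      gsub(" ", "_", normalize_expression(e), fixed = TRUE)
    }, character(1), USE.NAMES = FALSE)
    feats <- embed_pair(tokens, backends$base, backends$emotion, cache = cache)
    scaler <- fit_standardizer(feats)
    fit <- train_regressor(apply_standardizer(scaler, feats),
                           corpus$rating_mean, config)
    list(params = fit$params, scaler = scaler, history = fit$history)
  }
  single <- fit_one(single_corpus)
  multi <- if (is.null(multi_corpus)) single else fit_one(multi_corpus)
  structure(
    list(single = single, multi = multi,
         backends = backends,
         backend_ids = c(base = backends$base$name,
                         emotion = backends$emotion$name),
         training_mean = mean(single_corpus$rating_mean),
         version = "concretr-bundle-1"),
    class = "model_bundle"
  )
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle: backends [%s | %s], fallback mean %.3f>\n",
              x$backend_ids["base"], x$backend_ids["emotion"],
              x$training_mean))
  invisible(x)
}

prediction_result <- function(input_text, normalized_form = NA_character_,
                              score, raw_score = NA_real_, model_used,
                              confidence = NA_real_, flags = character(0)) {
  data.frame(input_text = input_text, normalized_form = normalized_form,
             score = score, raw_score = raw_score, model_used = model_used,
             confidence = confidence,
             flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Test whether a prediction carries a flag
#'
#' @param result A row (or data.frame) returned by [rate()].
#' @param flag Flag name, e.g. `"fallback"`, `"translated"`, `"review"`.
#' @return Logical vector.
#' @export
has_flag <- function(result, flag) {
  vapply(strsplit(result$flags, ";", fixed = TRUE),
         function(f) flag %in% f, logical(1))
}

score_token <- function(token, model, bundle, confidence_passes = 20,
                        seed = 42, cache = NULL, feature = NULL) {
  m <- bundle[[model]]
  if (is.null(feature)) {
    feature <- embed_pair(token, bundle$backends$base,
                          bundle$backends$emotion, cache = cache)
  }
  z <- apply_standardizer(m$scaler, feature)
  pred <- predict_scores(m$params, z)
  conf <- predict_confidence(m$params, z, n_passes = confidence_passes,
                             seed = seed + token_hash(token) %% 1000L)
  list(score = pred$score[1], raw = pred$raw[1], confidence = conf[1])
}

#' Resolve a disagreement between the two models
#'
#' For ambiguous inputs scored by both the single- and multi-word model
#' (e.g. a hyphenated compound also parseable as two words), returns the
#' prediction with the higher Monte-Carlo-dropout confidence; ties go to
#' the single-word model.
#'
#' @param single_pred,multi_pred Single-row prediction data.frames.
#' @return The winning prediction with `model_used = "ensemble-resolved"`.
#' @export
resolve_disagreement <- function(single_pred, multi_pred) {
  win <- if (multi_pred$confidence > single_pred$confidence) {
    multi_pred
  } else {
    single_pred
  }
  win$model_used <- "ensemble-resolved"
  win
}

default_rate_options <- function(options) {
  defaults <- list(lang = "auto", translate = TRUE, adapter = NULL,
                   detector = heuristic_detector, detect_threshold = 0.90,
                   batch_size = 50, cache = NULL, contextual = TRUE,
                   confidence_passes = 20, seed = 42)
  defaults[names(options)] <- options
  defaults
}

rate_one <- function(text, bundle, opt) {
  flags <- character(0)
  normalized <- normalize_expression(normalize_punctuation(text))

  # language handling: English never enters the translation path
  working <- normalized
  if (isTRUE(opt$translate) && !is.null(opt$adapter)) {
    lang <- opt$lang
    review <- FALSE
    if (identical(opt$lang, "auto")) {
      det <- detect_language(normalized, threshold = opt$detect_threshold,
                             detector = opt$detector)
      lang <- det$language_code
      review <- det$review
    }
    if (review) flags <- c(flags, "review")
    if (!identical(lang, "en")) {
      tr <- translate_to_english(normalized, lang, opt$adapter)
      working <- normalize_expression(tr$english_text)
      flags <- c(flags, "translated")
      if (tr$fallback_used) flags <- c(flags, "fallback")
      if (tr$review) flags <- unique(c(flags, "review"))
    }
  }

  cleaned <- clean_translation(working)
  if (!nzchar(cleaned)) {
    flags <- c(flags, "cleaned-to-empty")
    cleaned <- working
  }
  info <- classify_expression(cleaned)

  if (info$kind == "sentence") {
    words <- rate_sentence(cleaned, bundle, options = opt)
    return(prediction_result(
      input_text = text, normalized_form = info$normalized,
      score = mean(words$score), raw_score = mean(words$raw_score),
      model_used = "single", confidence = mean(words$confidence),
      flags = c(flags, "sentence")))
  }

  if (info$kind == "single" && grepl("-", info$tokens[1], fixed = TRUE)) {
    # ambiguous hyphenated compound: score both readings and resolve
    sp <- score_token(info$tokens[1], "single", bundle,
                      opt$confidence_passes, opt$seed, opt$cache)
    alt <- gsub("-", "_", info$tokens[1], fixed = TRUE)
    mp <- score_token(alt, "multi", bundle,
                      opt$confidence_passes, opt$seed, opt$cache)
    res <- resolve_disagreement(
      prediction_result(text, info$normalized, sp$score, sp$raw, "single",
                        sp$confidence, flags),
      prediction_result(text, info$normalized, mp$score, mp$raw, "multi",
                        mp$confidence, flags))
    return(res)
  }

  model <- if (info$kind == "single") "single" else "multi"
  token <- paste(info$tokens, collapse = "_")
  s <- score_token(token, model, bundle, opt$confidence_passes, opt$seed,
                   opt$cache)
  prediction_result(text, info$normalized, s$score, s$raw, model,
                    s$confidence, flags)
}

#' Rate expressions for concreteness
#'
#' The general prediction pipeline: each input is normalized, language-
#' handled (detection and translation when an adapter is supplied),
#' cleaned, classified, embedded through the bundle's dual backends and
#' scored by the routed model — single-word model for one token, multi-word
#' model otherwise, with hyphenated compounds scored by both models and
#' resolved by confidence. Inputs classified as sentences are rated
#' per word and reported as the mean of their word scores. Inputs are
#' processed in batches (default 50) with embedding caching; items that
#' cannot be processed degrade to the fallback score (the single-word
#' training mean) with a `fallback` flag — no input is ever dropped.
#'
#' @param texts Character vector of inputs.
#' @param bundle A [train_model_bundle()] result (or one restored by
#'   [load_bundle()]).
#' @param options Named list overriding any of: `lang` (`"auto"` or a
#'   code), `translate`, `adapter`, `detector`, `detect_threshold`,
#'   `batch_size`, `cache`, `contextual`, `confidence_passes`, `seed`.
#' @return Data.frame with one row per input: `input_text`,
#'   `normalized_form`, `score` (in `[1, 5]`), `raw_score`, `model_used`,
#'   `confidence`, `flags` (semicolon-joined).
#' @export
rate <- function(texts, bundle, options = list()) {
  stopifnot(inherits(bundle, "model_bundle"), length(texts) >= 1)
  opt <- default_rate_options(options)
  if (is.null(opt$cache)) opt$cache <- embedding_cache()
  out <- vector("list", length(texts))
  for (start in seq(1, length(texts), by = opt$batch_size)) {
    idx <- start:min(start + opt$batch_size - 1L, length(texts))
    for (i in idx) {
      out[[i]] <- tryCatch(
        rate_one(texts[i], bundle, opt),
        error = function(e) {
          prediction_result(
            input_text = texts[i], score = clamp(bundle$training_mean),
            model_used = "fallback", confidence = 0,
            flags = c("fallback", "review"))
        })
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rate each content word of a sentence
#'
#' Articles and conjunctions are removed by the cleaning pipeline; every
#' remaining word receives its own concreteness rating from the single-word
#' model. In contextual mode (default) word features come from the
#' backends' context-sensitive embedding of the word within the sentence
#' when the backends expose one; in standalone mode each word is embedded
#' bare, so the same word receives the same rating in any sentence.
#'
#' @param sentence Character scalar.
#' @param bundle A [train_model_bundle()] result.
#' @param options As in [rate()]; `contextual = FALSE` selects standalone
#'   mode.
#' @return Data.frame with one row per content word.
#' @export
rate_sentence <- function(sentence, bundle, options = list()) {
  opt <- default_rate_options(options)
  cleaned <- clean_translation(normalize_expression(sentence))
  if (!nzchar(cleaned)) {
    stopf("sentence reduced to zero content words",
          class = "concretr_empty_input")
  }
  info <- classify_expression(cleaned, sentence = TRUE)
  be <- bundle$backends
  contextual <- isTRUE(opt$contextual) &&
    !is.null(be$base$embed_context) && !is.null(be$emotion$embed_context)
  rows <- lapply(info$tokens, function(w) {
    feature <- if (contextual) {
      matrix(c(be$base$embed_context(w, info$normalized),
               be$emotion$embed_context(w, info$normalized)), nrow = 1)
    } else NULL
    s <- score_token(w, "single", bundle, opt$confidence_passes, opt$seed,
                     cache = if (contextual) NULL else opt$cache,
                     feature = feature)
    fl <- if (contextual) "contextual" else character(0)
    prediction_result(w, w, s$score, s$raw, "single", s$confidence, fl)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Save / load a model bundle
#'
#' A bundle is persisted as a directory holding `bundle.rds` (weights,
#' scalers, backends, training metadata) and a plain-text `manifest.json`
#' recording the format version, backend identifiers, input dimensionality
#' and fallback mean. Loading verifies the manifest against the archive and
#' refuses incompatible or corrupted bundles.
#'
#' @param bundle A `model_bundle`.
#' @param path Directory path.
#' @return `path` (save) or the restored `model_bundle` (load).
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format = bundle$version,
    backend_ids = as.list(bundle$backend_ids),
    input_dim = bundle$single$params$meta$input_dim,
    training_mean = bundle$training_mean
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(bundle, file.path(path, "bundle.rds"))
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  rds_path <- file.path(path, "bundle.rds")
  if (!file.exists(mf_path) || !file.exists(rds_path)) {
    stopf("'%s' is not a bundle directory", path, class = "concretr_io")
  }
  manifest <- jsonlite::read_json(mf_path)
  bundle <- tryCatch(readRDS(rds_path), error = function(e) {
    stopf("bundle archive is corrupted: %s", conditionMessage(e),
          class = "concretr_io")
  })
  if (!inherits(bundle, "model_bundle") ||
      !identical(manifest$format, bundle$version)) {
    stopf("bundle format mismatch", class = "concretr_incompatible_bundle")
  }
  ids <- unlist(manifest$backend_ids)
  if (!identical(unname(ids[c("base", "emotion")]),
                 unname(bundle$backend_ids[c("base", "emotion")]))) {
    stopf("manifest backend ids do not match the archive (%s/%s vs %s/%s)",
          ids["base"], ids["emotion"], bundle$backend_ids["base"],
          bundle$backend_ids["emotion"],
          class = "concretr_incompatible_bundle")
  }
  bundle
}
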