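# Shared fixtures, all built in code at test time.

tiny_corpus <- function() {
  rating_corpus(
    expression = c("table", "freedom", "ice cream", "anxiety", "pencil",
                   "justice", "balloon", "theory", "hammer", "idea"),
    rating_mean = c(4.9, 1.4, 4.6, 1.8, 4.8, 1.6, 4.5, 1.9, 4.7, 1.5),
    rating_sd = c(0.4, 0.9, 0.5, 1.0, 0.3, 1.1, 0.6, 0.9, 0.4, 1.0),
    n_raters = rep(25L, 10)
  )
}

write_corpus_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path, useBytes = TRUE)
  path
}

# An embedding backend that counts how many tokens it actually embeds;
# wraps the planted base backend.
counting_backend <- function(inner) {
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  be <- embedding_backend(
    name = paste0(inner$name, "-counted"),
    embed = function(tokens) {
      counter$n <- counter$n + length(tokens)
      inner$embed(tokens)
    },
    dim = inner$dim,
    embed_context = inner$embed_context
  )
  list(backend = be, counter = counter)
}

# One small trained bundle shared across test files (training is the slow
# part; predictor and cross-lingual tests only need *a* trained model).
.bundle_store <- new.env(parent = emptyenv())

get_test_backends <- function() {
  if (is.null(.bundle_store$backends)) {
    .bundle_store$backends <- make_planted_backend(synth_spec(seed = 5))
  }
  .bundle_store$backends
}

get_test_bundle <- function() {
  if (is.null(.bundle_store$bundle)) {
    bk <- get_test_backends()
    corpus <- gen_corpus(synth_spec(n_expressions = 240, seed = 5))
    .bundle_store$bundle <- train_model_bundle(
      corpus, backends = bk,
      config = train_config(max_epochs = 12, seed = 5))
  }
  .bundle_store$bundle
}
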