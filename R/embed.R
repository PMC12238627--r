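#' Create an in-memory embedding cache
#'
#' Embeddings for repeated expressions are cached to avoid redundant
#' computation. Keys combine the two backend names with the normalized
#' token, so "Dog " and "dog" collide by design once normalized.
#'
#' @return An object of class `embedding_cache` (an environment).
#' @export
embedding_cache <- function() {
  structure(new.env(parent = emptyenv()), class = "embedding_cache")
}

cache_key <- function(base, emotion, token) {
  paste(base$name, emotion$name, token, sep = "\x1f")
}

#' Persist / restore an embedding cache
#'
#' The store is written as a directory holding `vectors.rds` (the keyed
#' binary store) and `index.tsv`, a plain-text index of cache keys with the
#' store format version.
#'
#' @param cache An [embedding_cache()].
#' @param path Directory to write to / read from.
#' @return `path` (save) or an `embedding_cache` (load).
#' @export
save_embedding_cache <- function(cache, path) {
  stopifnot(inherits(cache, "embedding_cache"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  keys <- ls(cache, all.names = TRUE)
  saveRDS(mget(keys, envir = cache), file.path(path, "vectors.rds"))
  utils::write.table(
    data.frame(format = "concretr-cache-1", key = keys),
    file.path(path, "index.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname save_embedding_cache
#' @export
load_embedding_cache <- function(path) {
  idx <- utils::read.table(file.path(path, "index.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  if (nrow(idx) > 0 && any(idx$format != "concretr-cache-1")) {
    stopf("unrecognized cache format '%s'", idx$format[1], class = "concretr_io")
  }
  vals <- readRDS(file.path(path, "vectors.rds"))
  cache <- embedding_cache()
  for (k in names(vals)) assign(k, vals[[k]], envir = cache)
  cache
}

#' Dual embedding of a token
#'
#' Embeds a token through the base and emotion backends and concatenates the
#' two 512-d vectors into the combined 1024-d feature (base half first,
#' emotion half second; the order is part of the contract). Multi-word
#' tokens are passed as their underscore-joined form and tokenized
#' internally by the backend. Results are cached when a cache is supplied.
#'
#' @param tokens Character vector of normalized (and, for multi-word
#'   expressions, underscore-joined) tokens.
#' @param base,emotion [embedding_backend()] objects.
#' @param cache Optional [embedding_cache()].
#' @return Numeric matrix `length(tokens) x (base$dim + emotion$dim)` with
#'   attribute `source_tokens`.
#' @export
embed_pair <- function(tokens, base, emotion, cache = NULL) {
  stopifnot(inherits(base, "embedding_backend"),
            inherits(emotion, "embedding_backend"))
  out <- matrix(NA_real_, nrow = length(tokens), ncol = base$dim + emotion$dim)
  todo <- seq_along(tokens)
  if (!is.null(cache)) {
    stopifnot(inherits(cache, "embedding_cache"))
    keys <- cache_key(base, emotion, tokens)
    hit <- vapply(keys, exists, logical(1), envir = cache, USE.NAMES = FALSE)
    if (any(hit)) {
      out[hit, ] <- do.call(rbind, mget(keys[hit], envir = cache))
    }
    todo <- which(!hit)
  }
  if (length(todo)) {
    fresh <- cbind(backend_embed(base, tokens[todo]),
                   backend_embed(emotion, tokens[todo]))
    out[todo, ] <- fresh
    if (!is.null(cache)) {
      for (i in seq_along(todo)) {
        assign(cache_key(base, emotion, tokens[todo[i]]), fresh[i, ],
               envir = cache)
      }
    }
  }
  attr(out, "source_tokens") <- tokens
  out
}

#' Fit a feature standardizer
#'
#' Computes per-dimension mean and scale (population SD, i.e. the
#' divide-by-n convention) such that the transformed training features have
#' zero mean and unit variance per dimension. Zero-variance dimensions get
#' scale 1, so they transform to exact zeros rather than dividing by zero.
#'
#' @param features Numeric matrix (rows = items, columns = dimensions),
#'   at least 2 rows.
#' @return An object of class `scaler_params` with fields `mean` and
#'   `scale`.
#' @export
fit_standardizer <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2) stopf("need at least 2 features to fit a standardizer")
  mu <- colMeans(features)
  centered <- sweep(features, 2, mu)
  sc <- sqrt(colMeans(centered^2))
  sc[sc == 0 | !is.finite(sc)] <- 1
  structure(list(mean = mu, scale = sc), class = "scaler_params")
}

#' Apply a fitted standardizer
#'
#' @param params A `scaler_params` from [fit_standardizer()].
#' @param features Numeric matrix or single vector with matching
#'   dimensionality.
#' @return Standardized matrix `(x - mean) / scale`.
#' @export
apply_standardizer <- function(params, features) {
  stopifnot(inherits(params, "scaler_params"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  features <- as.matrix(features)
  if (ncol(features) != length(params$mean)) {
    stopf("feature dimensionality %d does not match standardizer (%d)",
          ncol(features), length(params$mean))
  }
  sweep(sweep(features, 2, params$mean), 2, params$scale, "/")
}

#' Symmetric contrastive loss over an image-text batch
#'
#' The InfoNCE-style objective used for emotion-aware fine-tuning: cosine
#' similarities between every image and every text embedding in the batch
#' are scaled by `exp(logit_scale)`; the loss is the mean of the image-to-
#' text and text-to-image cross-entropies with matched pairs on the
#' diagonal.
#'
#' @param image_emb,text_emb Numeric matrices `N x d` of paired embeddings
#'   (row i of each is a matched pair).
#' @param logit_scale Log of the inverse temperature.
#' @return Scalar loss (natural log units).
#' @export
contrastive_loss <- function(image_emb, text_emb, logit_scale = log(1 / 0.07)) {
  image_emb <- as.matrix(image_emb); text_emb <- as.matrix(text_emb)
  stopifnot(nrow(image_emb) == nrow(text_emb))
  S <- exp(logit_scale) * (normalize_rows(image_emb) %*%
                             t(normalize_rows(text_emb)))
  n <- nrow(S)
  # row-wise and column-wise log-softmax of the diagonal
  lse_rows <- apply(S, 1, function(r) max(r) + log(sum(exp(r - max(r)))))
  lse_cols <- apply(S, 2, function(cl) max(cl) + log(sum(exp(cl - max(cl)))))
  (sum(lse_rows - diag(S)) + sum(lse_cols - diag(S))) / (2 * n)
}

# Loss plus gradients w.r.t. the (unnormalized) embedding matrices and
# logit_scale; hand-derived backprop through L2 normalization and the
# temperature-scaled softmax.
contrastive_loss_grad <- function(U, V, logit_scale) {
  n <- nrow(U)
  nu <- sqrt(rowSums(U^2)); nu[nu == 0] <- 1
  nv <- sqrt(rowSums(V^2)); nv[nv == 0] <- 1
  Uh <- U / nu
  Vh <- V / nv
  s <- exp(logit_scale)
  S <- s * (Uh %*% t(Vh))
  softmax_rows <- function(M) {
    e <- exp(M - apply(M, 1, max))
    e / rowSums(e)
  }
  P <- softmax_rows(S)
  Q <- t(softmax_rows(t(S)))
  lse_rows <- apply(S, 1, function(r) max(r) + log(sum(exp(r - max(r)))))
  lse_cols <- apply(S, 2, function(cl) max(cl) + log(sum(exp(cl - max(cl)))))
  loss <- (sum(lse_rows - diag(S)) + sum(lse_cols - diag(S))) / (2 * n)
  dS <- ((P - diag(n)) + (Q - diag(n))) / (2 * n)
  g_scale <- sum(dS * S)
  gUh <- s * (dS %*% Vh)
  gVh <- s * (t(dS) %*% Uh)
  # backprop through row normalization: g_u = (g_uh - (g_uh . uh) uh) / |u|
  gU <- (gUh - Uh * rowSums(gUh * Uh)) / nu
  gV <- (gVh - Vh * rowSums(gVh * Vh)) / nv
  list(loss = loss, gU = gU, gV = gV, g_scale = g_scale)
}

#' Contrastive emotion fine-tuning of a paired image-text encoder
#'
#' Minimizes the symmetric cross-entropy over the temperature-scaled
#' cosine-similarity matrix between in-batch image and label embeddings
#' (matched pairs on the diagonal) by full fine-tuning: both encoder weight
#' matrices and the temperature are updated with Adam. Learning rate and
#' step count are configuration with documented-guess defaults, as no
#' canonical values exist for the toy setting.
#'
#' @param backend A trainable encoder from [make_toy_clip_backend()].
#' @param pairs Image-label pairs, e.g. from [gen_image_text_pairs()].
#' @param config List: `lr` (default 1e-3), `steps` (default 50),
#'   `batch_size` (default all pairs), `seed` (default 42), `train_temperature`
#'   (default TRUE).
#' @return List with `backend` (updated) and `loss_history` (numeric, one
#'   entry per step).
#' @export
contrastive_finetune <- function(backend, pairs, config = list()) {
  stopifnot(inherits(backend, "toy_clip_backend"), length(pairs) >= 1)
  lr <- config$lr %||% 1e-3
  steps <- config$steps %||% 50L
  batch_size <- min(config$batch_size %||% length(pairs), length(pairs))
  seed <- as.integer(config$seed %||% 42L)
  train_temp <- config$train_temperature %||% TRUE

  labels <- vapply(pairs, `[[`, character(1), "label")
  X_img <- t(vapply(pairs, function(p) as.numeric(p$image),
                    numeric(backend$image_pixels)))
  X_txt <- backend$featurize_text(labels)

  W_img <- backend$W_img; W_txt <- backend$W_txt
  logit_scale <- backend$logit_scale
  adam <- function(shape) list(m = array(0, shape), v = array(0, shape))
  st <- list(img = adam(dim(W_img)), txt = adam(dim(W_txt)),
             scale = adam(1))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step_adam <- function(state, g, t) {
    state$m <- b1 * state$m + (1 - b1) * g
    state$v <- b2 * state$v + (1 - b2) * g^2
    mhat <- state$m / (1 - b1^t)
    vhat <- state$v / (1 - b2^t)
    list(state = state, delta = lr * mhat / (sqrt(vhat) + eps))
  }
  history <- numeric(steps)
  with_local_seed(seed, {
    for (t in seq_len(steps)) {
      idx <- if (batch_size < length(pairs)) {
        sample(length(pairs), batch_size)
      } else seq_along(pairs)
      if (length(idx) > 1 && length(unique(labels[idx])) == 1L) {
        warnf("degenerate contrast: batch of %d pairs shares one label",
              length(idx))
      }
      U <- X_img[idx, , drop = FALSE] %*% t(W_img)
      V <- X_txt[idx, , drop = FALSE] %*% t(W_txt)
      g <- contrastive_loss_grad(U, V, logit_scale)
      if (!is.finite(g$loss)) {
        stopf("non-finite contrastive loss at step %d (logit_scale %.3f)",
              t, logit_scale)
      }
      history[t] <- g$loss
      gW_img <- t(g$gU) %*% X_img[idx, , drop = FALSE]
      gW_txt <- t(g$gV) %*% X_txt[idx, , drop = FALSE]
      up <- step_adam(st$img, gW_img, t); st$img <- up$state
      W_img <- W_img - up$delta
      up <- step_adam(st$txt, gW_txt, t); st$txt <- up$state
      W_txt <- W_txt - up$delta
      if (train_temp) {
        up <- step_adam(st$scale, g$g_scale, t); st$scale <- up$state
        logit_scale <- logit_scale - as.numeric(up$delta)
      }
    }
  })
  backend$W_img <- W_img
  backend$W_txt <- W_txt
  backend$logit_scale <- logit_scale
  backend <- refresh_toy_clip_embed(backend)
  list(backend = backend, loss_history = history)
}
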