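#' Construct an embedding backend
#'
#' An embedding backend maps tokens to fixed-dimensionality real vectors.
#' The package treats backends as pluggable contracts: any object created by
#' this constructor (a pretrained text encoder wrapped from another process,
#' or one of the synthetic backends shipped here) can serve as the base or
#' emotion half of the dual feature.
#'
#' @param name Backend identifier used for cache keys and bundle manifests.
#' @param embed Function `(tokens) -> matrix` of shape
#'   `length(tokens) x dim`; all entries finite.
#' @param dim Output dimensionality (default 512).
#' @param deterministic Logical; `TRUE` when the same token always yields the
#'   same vector.
#' @param embed_context Optional function `(token, sentence) -> vector` giving
#'   a context-sensitive embedding of `token` within `sentence`.
#' @return An object of class `embedding_backend`.
#' @export
embedding_backend <- function(name, embed, dim = 512, deterministic = TRUE,
                              embed_context = NULL) {
  stopifnot(is.character(name), is.function(embed), is_scalar_number(dim))
  structure(
    list(name = name, embed = embed, dim = as.integer(dim),
         deterministic = isTRUE(deterministic), embed_context = embed_context),
    class = "embedding_backend"
  )
}

#' @export
print.embedding_backend <- function(x, ...) {
  cat(sprintf("<embedding_backend '%s': dim=%d, deterministic=%s>\n",
              x$name, x$dim, x$deterministic))
  invisible(x)
}

#' Embed tokens through a backend, enforcing the contract
#'
#' @param backend An [embedding_backend()].
#' @param tokens Character vector of (already normalized/joined) tokens.
#' @return Numeric matrix `length(tokens) x backend$dim`.
#' @export
backend_embed <- function(backend, tokens) {
  stopifnot(inherits(backend, "embedding_backend"))
  out <- tryCatch(backend$embed(tokens), error = function(e) {
    stopf("backend '%s' failed on token '%s': %s", backend$name, tokens[1],
          conditionMessage(e), class = "concretr_backend")
  })
  out <- matrix(as.numeric(out), nrow = length(tokens))
  if (ncol(out) != backend$dim) {
    stopf("backend '%s' returned %d dimensions, contract says %d",
          backend$name, ncol(out), backend$dim, class = "concretr_backend")
  }
  if (!all(is.finite(out))) {
    stopf("backend '%s' returned non-finite values", backend$name,
          class = "concretr_backend")
  }
  out
}

#' Zero embedding backend
#'
#' Returns all-zero vectors; useful for exercising plumbing.
#' @param dim Dimensionality (default 512).
#' @return An [embedding_backend()].
#' @export
zero_backend <- function(dim = 512) {
  embedding_backend(
    name = sprintf("zero-%d", dim),
    embed = function(tokens) matrix(0, nrow = length(tokens), ncol = dim),
    dim = dim
  )
}

# Deterministic pseudo-random unit vector for a token under a salt.
token_unit_vector <- function(token, dim, salt) {
  unit_vector(token_normals(token, dim, salt))
}

#' Planted-signal synthetic embedding backends
#'
#' Builds a pair of deterministic 512-d text-embedding backends ("base" and
#' "emotion") in which every token's vector is a seeded pseudo-random unit
#' vector plus a planted concreteness signal along fixed directions. Each
#' token carries three latent standard-normal components `u`, `v`, `w`
#' (derived by hashing the token); its latent concreteness is
#' `clamp(3 + 0.8 * (u + v + w) / sqrt(3), 1, 5)` — an affine function of
#' the planted components (so of the feature itself), clipped to the Likert
#' range, making the regression target a noiseless deterministic function
#' of the embedding.
#' The base backend encodes `u` and `w`, the emotion backend `v` and `w`:
#' the signal directions are partially disjoint, so the concatenated 1024-d
#' feature is strictly more informative about the latent score than either
#' 512-d half alone. Context-sensitive embeddings add a small
#' sentence-keyed perturbation.
#'
#' @param spec A [synth_spec()]; uses `embedding_dim`, `signal_strength`,
#'   `context_scale` and `seed`.
#' @return A list with elements `base` and `emotion` (both
#'   [embedding_backend()]) and `latent`, a vectorized function
#'   `tokens -> latent concreteness scores`.
#' @export
make_planted_backend <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  dim <- spec$embedding_dim
  s <- spec$signal_strength
  seed <- spec$seed
  dirs <- with_local_seed(seed + 1013L, {
    m <- matrix(stats::rnorm(dim * 4), nrow = 4)
    normalize_rows(m)
  })
  comp <- function(tokens, which) {
    vapply(tokens, function(tk) {
      token_normals(tk, 1L, salt = sprintf("planted-%d-%s", seed, which))
    }, numeric(1), USE.NAMES = FALSE)
  }
  latent <- function(tokens) {
    z <- (comp(tokens, "u") + comp(tokens, "v") + comp(tokens, "w")) / sqrt(3)
    clamp(3 + 0.8 * z)
  }
  embed_with <- function(salt, d1, d2, c1, c2) {
    function(tokens) {
      eps <- t(vapply(tokens, token_unit_vector, numeric(dim),
                      dim = dim, salt = salt, USE.NAMES = FALSE))
      eps + s * (outer(c1(tokens), d1) + outer(c2(tokens), d2))
    }
  }
  ctx_with <- function(embed_fn) {
    function(token, sentence) {
      as.numeric(embed_fn(token)) +
        spec$context_scale *
          token_unit_vector(paste(token, sentence, sep = "\x1f"), dim,
                            salt = sprintf("planted-ctx-%d", seed))
    }
  }
  base_fn <- embed_with(sprintf("planted-base-%d", seed),
                        dirs[1, ], dirs[3, ],
                        function(tk) comp(tk, "u"), function(tk) comp(tk, "w"))
  emo_fn <- embed_with(sprintf("planted-emo-%d", seed),
                       dirs[2, ], dirs[4, ],
                       function(tk) comp(tk, "v"), function(tk) comp(tk, "w"))
  list(
    base = embedding_backend(sprintf("planted-base-%d", seed), base_fn,
                             dim = dim, embed_context = ctx_with(base_fn)),
    emotion = embedding_backend(sprintf("planted-emotion-%d", seed), emo_fn,
                                dim = dim, embed_context = ctx_with(emo_fn)),
    latent = latent
  )
}

#' Toy trainable image-text encoder pair
#'
#' A miniature two-tower encoder in the mold of contrastive vision-language
#' models: a linear image encoder over flattened pixels, a linear text
#' encoder over a deterministic label featurization, and a learnable
#' temperature (`logit_scale`). It exists so the contrastive fine-tuning
#' procedure can be exercised end-to-end on synthetic image-label pairs.
#'
#' @param seed Integer seed for weight initialization.
#' @param dim Embedding dimensionality (default 512).
#' @param image_pixels Number of pixels expected per image (default 256,
#'   i.e. 16 x 16).
#' @param text_features Dimensionality of the label featurization
#'   (default 64).
#' @return An object of class `c("toy_clip_backend", "embedding_backend")`
#'   with trainable fields `W_img`, `W_txt`, `logit_scale`.
#' @export
make_toy_clip_backend <- function(seed = 42, dim = 512, image_pixels = 256,
                                  text_features = 64) {
  featurize_text <- function(labels) {
    t(vapply(labels, token_normals, numeric(text_features),
             n = text_features, salt = "toyclip-text", USE.NAMES = FALSE))
  }
  weights <- with_local_seed(as.integer(seed), list(
    W_img = matrix(stats::rnorm(dim * image_pixels, sd = 1 / sqrt(image_pixels)),
                   nrow = dim),
    W_txt = matrix(stats::rnorm(dim * text_features, sd = 1 / sqrt(text_features)),
                   nrow = dim)
  ))
  backend <- embedding_backend(
    name = sprintf("toy-clip-%d", seed),
    embed = function(tokens) stop("placeholder"),  # replaced below
    dim = dim
  )
  backend$W_img <- weights$W_img
  backend$W_txt <- weights$W_txt
  backend$logit_scale <- log(1 / 0.07)
  backend$image_pixels <- image_pixels
  backend$featurize_text <- featurize_text
  class(backend) <- c("toy_clip_backend", "embedding_backend")
  refresh_toy_clip_embed(backend)
}

# (Re)binds the embed closure to the current weights; called after updates.
refresh_toy_clip_embed <- function(backend) {
  W_txt <- backend$W_txt
  featurize <- backend$featurize_text
  backend$embed <- function(tokens) featurize(tokens) %*% t(W_txt)
  backend
}

#' Encode images through a toy encoder
#'
#' @param backend A toy encoder from [make_toy_clip_backend()].
#' @param images List of numeric pixel matrices/vectors, each with
#'   `backend$image_pixels` entries.
#' @return Matrix `length(images) x dim` of image embeddings.
#' @export
toy_clip_encode_images <- function(backend, images) {
  stopifnot(inherits(backend, "toy_clip_backend"))
  X <- t(vapply(images, function(im) {
    v <- as.numeric(im)
    if (length(v) != backend$image_pixels) {
      stopf("image has %d pixels, encoder expects %d", length(v),
            backend$image_pixels)
    }
    v
  }, numeric(backend$image_pixels)))
  X %*% t(backend$W_img)
}
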