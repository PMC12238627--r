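#' Specification for synthetic concreteness data
#'
#' Collects every knob of the synthetic generators in one validated object.
#' The default rating distribution is the characteristic bimodal shape of
#' human concreteness norms: an equal-weight mixture of Gaussians centred at
#' 2.5 and 4.5 (component SD 0.6), truncated to the 1-5 Likert range, which
#' yields an overall mean near 3.5 and SD near 1.1.
#'
#' @param n_expressions Number of expressions to generate.
#' @param weights,means,sds Mixture weights (summing to 1), component means
#'   (within `[1, 5]`) and component SDs (> 0) of the rating distribution.
#' @param n_raters Simulated raters per expression.
#' @param rater_noise_sd SD of per-rater Gaussian noise (Likert units).
#' @param embedding_dim Backend dimensionality (512, matching the dual
#'   512+512 feature design).
#' @param signal_strength Scale of the planted concreteness signal in the
#'   synthetic backends, relative to unit-norm carrier vectors (default 4:
#'   the planted signal dominates the carrier noise, so the latent score is
#'   recoverable essentially noiselessly from the feature — the regime the
#'   recovery guarantees assume).
#' @param context_scale Size of the sentence-context perturbation in
#'   context-sensitive synthetic embeddings.
#' @param seed Integer seed; every generator is a pure function of
#'   (spec, seed).
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_expressions = 1000,
                       weights = c(0.5, 0.5),
                       means = c(2.5, 4.5),
                       sds = c(0.6, 0.6),
                       n_raters = 30,
                       rater_noise_sd = 1.0,
                       embedding_dim = 512,
                       signal_strength = 4,
                       context_scale = 0.1,
                       seed = 1) {
  stopifnot(length(weights) == length(means), length(means) == length(sds))
  if (abs(sum(weights) - 1) > 1e-8) stopf("mixture weights must sum to 1")
  if (any(means < 1 | means > 5)) stopf("mixture means must lie within [1, 5]")
  if (any(sds <= 0)) stopf("mixture SDs must be > 0")
  if (rater_noise_sd < 0) stopf("rater_noise_sd must be >= 0")
  structure(
    list(n_expressions = as.integer(n_expressions), weights = weights,
         means = means, sds = sds, n_raters = as.integer(n_raters),
         rater_noise_sd = rater_noise_sd,
         embedding_dim = as.integer(embedding_dim),
         signal_strength = signal_strength, context_scale = context_scale,
         seed = as.integer(seed)),
    class = "synth_spec"
  )
}

# Pronounceable pseudo-words: index encoded in consonant-vowel syllables.
# Deterministic, unique per index, and within the permitted character set.
pseudo_word <- function(index) {
  consonants <- strsplit("bdfgklmnprstv", "")[[1]]
  vowels <- strsplit("aeiou", "")[[1]]
  base <- length(consonants) * length(vowels)  # 65 syllables
  i <- as.integer(index)
  syl <- character(0)
  repeat {
    d <- i %% base
    syl <- c(consonants[d %/% length(vowels) + 1],
             vowels[d %% length(vowels) + 1], syl)
    i <- i %/% base
    if (i == 0) break
  }
  word <- paste(syl, collapse = "")
  if (nchar(word) < 6) word <- paste0(word, strrep("na", (6 - nchar(word)) %/% 2))
  word
}

pseudo_words <- function(n) vapply(seq_len(n) + 64L, pseudo_word, character(1))

# Draw from the truncated Gaussian mixture by component sampling + rejection.
sample_truncated_mixture <- function(n, weights, means, sds, lo = 1, hi = 5) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    comp <- sample.int(length(weights), length(need), replace = TRUE,
                       prob = weights)
    draw <- stats::rnorm(length(need), means[comp], sds[comp])
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic rating corpus
#'
#' Expressions are pronounceable pseudo-words; mean ratings are drawn from
#' the spec's truncated bimodal mixture; per-expression rating SDs are drawn
#' from a mild baseline distribution. The drawn mean rating is the hidden
#' true score, stored in the `true_score` attribute for test assertions.
#'
#' @param spec A [synth_spec()].
#' @return A [rating_corpus()] with attribute `true_score` (numeric vector,
#'   identical to `rating_mean`) and the spec recorded in attribute `spec`.
#' @export
gen_corpus <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_expressions
  dat <- with_local_seed(spec$seed, {
    list(
      rating = sample_truncated_mixture(n, spec$weights, spec$means, spec$sds),
      sd = abs(stats::rnorm(n, mean = 0.9, sd = 0.15)) + 0.05
    )
  })
  corpus <- rating_corpus(
    expression = pseudo_words(n),
    rating_mean = dat$rating,
    rating_sd = dat$sd,
    n_raters = rep(spec$n_raters, n),
    language = "xx-synth",
    provenance = sprintf("concretr synthetic corpus (seed %d)", spec$seed)
  )
  attr(corpus, "true_score") <- dat$rating
  attr(corpus, "spec") <- spec
  corpus
}

# Mean and variance of clamp(X, lo, hi) for X ~ N(t, sd^2), elementwise in t.
clamped_normal_moments <- function(t, sd, lo = 1, hi = 5) {
  if (sd == 0) return(list(mean = clamp(t, lo, hi), var = rep(0, length(t))))
  a <- (lo - t) / sd
  b <- (hi - t) / sd
  Pa <- stats::pnorm(a); Pb <- stats::pnorm(b)
  pa <- stats::dnorm(a); pb <- stats::dnorm(b)
  mid_p <- Pb - Pa
  ex1 <- t * mid_p + sd * (pa - pb)
  ex2 <- t^2 * mid_p + 2 * t * sd * (pa - pb) + sd^2 * (mid_p + a * pa - b * pb)
  m <- lo * Pa + hi * (1 - Pb) + ex1
  m2 <- lo^2 * Pa + hi^2 * (1 - Pb) + ex2
  list(mean = m, var = pmax(0, m2 - m^2))
}

# Expected split-half-corrected reliability and single-rating ICC of
# clamped noisy ratings around the given true scores.
analytic_reliability <- function(true_scores, noise_sd, n_raters) {
  mom <- clamped_normal_moments(true_scores, noise_sd)
  var_mu <- stats::var(mom$mean)
  mean_v <- mean(mom$var)
  k1 <- n_raters %/% 2L
  k2 <- n_raters - k1
  r_half <- var_mu / sqrt((var_mu + mean_v / k1) * (var_mu + mean_v / k2))
  list(
    split_half = 2 * r_half / (1 + r_half),
    icc = var_mu / (var_mu + mean_v),
    icc_no_clamp = stats::var(true_scores) /
      (stats::var(true_scores) + noise_sd^2)
  )
}

#' Simulate a long-format rater table with known reliability
#'
#' Each simulated rater's rating of an expression is the expression's hidden
#' true score plus Gaussian noise, clamped to `[1, 5]`. The closed-form
#' expected Spearman-Brown-corrected split-half reliability and single-rating
#' ICC — computed from clamped-normal moments, so the Likert truncation is
#' accounted for — are stored in the `analytic` attribute for assertions.
#'
#' @param corpus A corpus from [gen_corpus()] (or any `rating_corpus` with a
#'   `true_score` attribute).
#' @param n_raters Number of raters; defaults to the generating spec's value.
#' @param noise_sd Per-rater noise SD; defaults likewise.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `rater_id`, `expression`, `rating`
#'   (class `rater_table`), with attribute `analytic` (list: `split_half`,
#'   `icc`, `icc_no_clamp`).
#' @export
gen_raters <- function(corpus, n_raters = NULL, noise_sd = NULL, seed = 1) {
  truth <- attr(corpus, "true_score") %||% corpus$rating_mean
  spec <- attr(corpus, "spec")
  n_raters <- as.integer(n_raters %||% spec$n_raters %||% 30L)
  noise_sd <- noise_sd %||% spec$rater_noise_sd %||% 1.0
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  n <- nrow(corpus)
  tab <- with_local_seed(as.integer(seed), {
    rating <- clamp(rep(truth, times = n_raters) +
                      stats::rnorm(n * n_raters, 0, noise_sd))
    data.frame(
      rater_id = sprintf("r%03d", rep(seq_len(n_raters), each = n)),
      expression = rep(corpus$expression, times = n_raters),
      rating = rating,
      stringsAsFactors = FALSE
    )
  })
  attr(tab, "analytic") <- analytic_reliability(truth, noise_sd, n_raters)
  class(tab) <- c("rater_table", "data.frame")
  tab
}

#' Generate synthetic emotion-annotated image-label pairs
#'
#' Produces tiny (16 x 16) procedurally generated images whose pixel
#' statistics depend deterministically on the emotion label (a label-keyed
#' base pattern plus small seeded noise), so contrastive image-text
#' alignment is learnable from the pairs.
#'
#' @param n Number of pairs (>= 1).
#' @param seed Integer seed.
#' @param labels Pool of emotion labels to cycle through.
#' @return A list of `n` lists with elements `image` (16 x 16 numeric
#'   matrix) and `label` (character).
#' @export
gen_image_text_pairs <- function(n, seed = 1,
                                 labels = c("joy", "fear", "anger", "calm",
                                            "sadness", "surprise", "disgust",
                                            "awe")) {
  stopifnot(n >= 1)
  lab <- rep_len(labels, n)
  with_local_seed(as.integer(seed), {
    lapply(seq_len(n), function(i) {
      base <- matrix(token_normals(lab[i], 256L, salt = "emo-image"), 16, 16)
      list(image = base + matrix(stats::rnorm(256, sd = 0.05), 16, 16),
           label = lab[i])
    })
  })
}
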