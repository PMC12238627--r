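#' Regression evaluation metrics
#'
#' Computes the full evaluation report for predicted vs. true concreteness
#' scores: Pearson r with a 95% Fisher-z confidence interval, the
#' coefficient of determination `R^2 = 1 - SSres/SStot` (the
#' variance-explained form, deliberately not `r^2` — a biased predictor can
#' have `r = 0.93` with `R^2 = 0.82`), MAE, RMSE, and the two-tailed p-value
#' from `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param predicted,true Numeric vectors of equal length (>= 3), finite.
#' @return An object of class `eval_report`: list with `pearson_r`,
#'   `r_ci` (length-2), `r_squared`, `mae`, `rmse`, `p_value`, `n`.
#' @export
regression_metrics <- function(predicted, true) {
  predicted <- as.numeric(predicted); true <- as.numeric(true)
  n <- length(true)
  if (length(predicted) != n || n < 3) {
    stopf("`predicted` and `true` must have equal length >= 3")
  }
  if (!all(is.finite(predicted)) || !all(is.finite(true))) {
    stopf("inputs must be finite")
  }
  if (stats::var(true) == 0) {
    stopf("true scores have zero variance; R^2 undefined",
          class = "concretr_validation")
  }
  r <- stats::cor(predicted, true)
  z <- atanh(r)
  ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) / sqrt(n - 3))
  ss_res <- sum((true - predicted)^2)
  ss_tot <- sum((true - mean(true))^2)
  r2 <- 1 - ss_res / ss_tot
  mae <- mean(abs(predicted - true))
  rmse <- sqrt(mean((predicted - true)^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  structure(list(pearson_r = r, r_ci = ci, r_squared = r2, mae = mae,
                 rmse = rmse, p_value = p, n = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "r = %.3f [%.3f, %.3f], R^2 = %.3f, MAE = %.3f, RMSE = %.3f, p = %.3g (n = %d)\n",
    x$pearson_r, x$r_ci[1], x$r_ci[2], x$r_squared, x$mae, x$rmse,
    x$p_value, x$n))
  invisible(x)
}

#' Spearman-Brown correction
#'
#' Projects a half-test correlation to full length: `2r / (1 + r)`.
#'
#' @param r Half-test correlation.
#' @return Corrected reliability.
#' @export
spearman_brown <- function(r) 2 * r / (1 + r)

#' Split-half reliability of a rater table
#'
#' Over `iterations` random bipartitions of the raters (sizes `floor(n/2)`
#' and `ceiling(n/2)`), computes per-expression mean ratings within each
#' half, the Pearson correlation over expressions rated by both halves, and
#' finally applies the Spearman-Brown correction to the mean of the
#' per-iteration correlations.
#'
#' @param raters Long-format data.frame with columns `rater_id`,
#'   `expression`, `rating` (at least 4 raters).
#' @param iterations Number of random bipartitions (default 100).
#' @param seed Integer seed.
#' @return An object of class `reliability_result` with `method =
#'   "split-half"`, the corrected `estimate`, the per-iteration
#'   `correlations`, `iterations` and `seed`.
#' @export
split_half_reliability <- function(raters, iterations = 100, seed = 42) {
  stopifnot(all(c("rater_id", "expression", "rating") %in% names(raters)))
  ids <- sort(unique(raters$rater_id))  # row-order invariance
  if (length(ids) < 4) stopf("need at least 4 raters")
  by_rater <- split(raters[c("expression", "rating")], raters$rater_id)
  rs <- with_local_seed(as.integer(seed), {
    vapply(seq_len(iterations), function(i) {
      perm <- sample(ids)
      half1 <- perm[seq_len(length(ids) %/% 2)]
      half2 <- setdiff(perm, half1)
      mean_by_expr <- function(members) {
        sub <- do.call(rbind, by_rater[members])
        tapply(sub$rating, sub$expression, mean)
      }
      m1 <- mean_by_expr(half1)
      m2 <- mean_by_expr(half2)
      common <- intersect(names(m1), names(m2))
      if (length(common) < 3) {
        warnf("iteration %d has %d common expressions; skipped", i,
              length(common))
        return(NA_real_)
      }
      stats::cor(m1[common], m2[common])
    }, numeric(1))
  })
  rs <- rs[!is.na(rs)]
  if (length(rs) == 0) stopf("every split-half iteration was skipped")
  r_bar <- mean(rs)
  structure(list(method = "split-half", estimate = spearman_brown(r_bar),
                 mean_correlation = r_bar, correlations = rs,
                 iterations = iterations, seed = seed),
            class = "reliability_result")
}

#' Intraclass correlation of a rater table
#'
#' Estimates the one-way random-effects ICC: ratings are modelled with a
#' random intercept per expression (`rating ~ 1 + (1 | expression)` via
#' lme4) and the ICC is the between-expression variance divided by the
#' total (between + residual) variance — the proportion of rating variance
#' attributable to differences between expressions.
#'
#' @param raters Long-format data.frame with columns `rater_id`,
#'   `expression`, `rating`; at least 2 expressions and on average >= 2
#'   ratings per expression.
#' @return An object of class `reliability_result` with `method = "icc"`,
#'   the `estimate`, and `variance_components` (between, within).
#' @export
icc_reliability <- function(raters) {
  stopifnot(all(c("rater_id", "expression", "rating") %in% names(raters)))
  n_expr <- length(unique(raters$expression))
  if (n_expr < 2) {
    stopf("ICC needs at least 2 expressions", class = "concretr_validation")
  }
  if (nrow(raters) / n_expr < 2) {
    stopf("ICC needs on average >= 2 ratings per expression")
  }
  if (stats::var(raters$rating) == 0) {
    stopf("ratings have zero variance; ICC undefined",
          class = "concretr_validation")
  }
  fit <- lme4::lmer(rating ~ 1 + (1 | expression), data = raters,
                    REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  v_between <- vc$vcov[vc$grp == "expression"]
  v_within <- vc$vcov[vc$grp == "Residual"]
  structure(list(method = "icc",
                 estimate = v_between / (v_between + v_within),
                 variance_components = c(between = v_between,
                                         within = v_within)),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("<reliability (%s): estimate = %.4f>\n", x$method, x$estimate))
  invisible(x)
}

#' Mean signed prediction bias by rating band
#'
#' Partitions `[1, 5]` into bands of the true rating (default: very
#' abstract `< 2.0`, intermediate `[2.0, 4.5]`, highly concrete `> 4.5`)
#' and reports the mean of `predicted - true` within each band. Positive
#' bias means overprediction.
#'
#' @param predicted,true Equal-length numeric vectors.
#' @param edges Interior band edges (default `c(2, 4.5)`).
#' @return Data.frame of class `bias_band_report` with columns `band`,
#'   `n`, `bias` (NA for empty bands).
#' @export
bias_by_band <- function(predicted, true, edges = c(2, 4.5)) {
  stopifnot(length(predicted) == length(true))
  cuts <- c(1, edges, 5)
  labels <- c(sprintf("[1, %g)", edges[1]),
              sprintf("[%g, %g]", edges[1], edges[2]),
              sprintf("(%g, 5]", edges[2]))
  band <- ifelse(true < edges[1], 1L, ifelse(true <= edges[2], 2L, 3L))
  out <- data.frame(
    band = labels,
    n = vapply(1:3, function(b) sum(band == b), integer(1)),
    bias = vapply(1:3, function(b) {
      if (any(band == b)) mean(predicted[band == b] - true[band == b])
      else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("bias_band_report", "data.frame")
  out
}

#' Compare two rating distributions
#'
#' Quantifies agreement between the distributions of predicted and true
#' ratings: the two-sample Kolmogorov-Smirnov statistic and a histogram
#' overlap coefficient (shared area of the two normalized histograms on
#' common breaks over `[1, 5]`).
#'
#' @param predicted,true Numeric vectors (length >= 10 each).
#' @param bins Number of histogram bins for the overlap coefficient.
#' @return List with `ks_statistic` and `overlap` (both in `[0, 1]`).
#' @export
distribution_compare <- function(predicted, true, bins = 40) {
  stopifnot(length(predicted) >= 10, length(true) >= 10)
  ks <- suppressWarnings(
    stats::ks.test(predicted, true)$statistic
  )
  breaks <- seq(min(1, predicted, true), max(5, predicted, true),
                length.out = bins + 1)
  h1 <- graphics::hist(predicted, breaks = breaks, plot = FALSE)$counts
  h2 <- graphics::hist(true, breaks = breaks, plot = FALSE)$counts
  overlap <- sum(pmin(h1 / sum(h1), h2 / sum(h2)))
  list(ks_statistic = unname(ks), overlap = overlap)
}
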