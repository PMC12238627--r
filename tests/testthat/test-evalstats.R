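# Independent brute-force implementations used as oracles.
brute_metrics <- function(p, y) {
  n <- length(y)
  mp <- sum(p) / n; my <- sum(y) / n
  r <- sum((p - mp) * (y - my)) /
    sqrt(sum((p - mp)^2) * sum((y - my)^2))
  list(
    r = r,
    r2 = 1 - sum((y - p)^2) / sum((y - my)^2),
    mae = sum(abs(p - y)) / n,
    rmse = sqrt(sum((p - y)^2) / n),
    p_value = 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2),
    ci = tanh(atanh(r) + c(-1, 1) * qnorm(0.975) / sqrt(n - 3))
  )
}

test_that("regression metrics match the brute-force formulas on random vectors", {
  withr::with_seed(20, {
    for (i in 1:40) {
      n <- sample(5:60, 1)
      y <- runif(n, 1, 5)
      p <- y + rnorm(n, 0, runif(1, 0.05, 1))
      m <- regression_metrics(p, y)
      o <- brute_metrics(p, y)
      expect_equal(m$pearson_r, o$r, tolerance = 1e-10)
      expect_equal(m$r_squared, o$r2, tolerance = 1e-10)
      expect_equal(m$mae, o$mae, tolerance = 1e-10)
      expect_equal(m$rmse, o$rmse, tolerance = 1e-10)
      expect_equal(m$p_value, o$p_value, tolerance = 1e-10)
      expect_equal(m$r_ci, o$ci, tolerance = 1e-10)
    }
  })
})

test_that("identity and constant-shift cases behave as the definitions force", {
  y <- c(1, 2, 3, 4, 5)
  m <- regression_metrics(y, y)
  expect_equal(m$pearson_r, 1)
  expect_equal(m$r_squared, 1)
  expect_equal(m$mae, 0)
  expect_equal(m$rmse, 0)
  shifted <- regression_metrics(y + 0.5, y)
  expect_equal(shifted$pearson_r, 1)
  expect_equal(shifted$mae, 0.5)
  expect_lt(shifted$r_squared, 1)
  # R^2 is variance explained, not the squared correlation
  expect_equal(shifted$r_squared, 1 - 5 * 0.25 / 10)
  expect_error(regression_metrics(y, rep(3, 5)), class = "concretr_validation")
})

test_that("Spearman-Brown correction is exact, monotone, and above raw on (0,1)", {
  expect_equal(spearman_brown(0.5), 2 / 3)
  expect_equal(spearman_brown(1), 1)
  rs <- seq(0.05, 0.95, by = 0.05)
  corrected <- spearman_brown(rs)
  expect_true(all(diff(corrected) > 0))
  expect_true(all(corrected > rs))
})

test_that("perfectly agreeing raters give split-half reliability 1", {
  corpus <- gen_corpus(synth_spec(n_expressions = 30, seed = 2))
  tab <- gen_raters(corpus, n_raters = 6, noise_sd = 1e-12, seed = 1)
  res <- split_half_reliability(tab, iterations = 10, seed = 1)
  expect_equal(res$estimate, 1, tolerance = 1e-6)
  expect_true(all(res$correlations > 1 - 1e-9))
})

test_that("split-half reliability is invariant to rater relabeling and row order", {
  corpus <- gen_corpus(synth_spec(n_expressions = 60, seed = 3))
  tab <- gen_raters(corpus, n_raters = 9, noise_sd = 0.8, seed = 4)
  base <- split_half_reliability(tab, iterations = 20, seed = 9)
  relabeled <- tab
  relabeled$rater_id <- sub("^r", "rater-", relabeled$rater_id)
  expect_equal(split_half_reliability(relabeled, 20, seed = 9)$estimate,
               base$estimate, tolerance = 1e-12)
  shuffled <- tab[withr::with_seed(1, sample(nrow(tab))), ]
  expect_equal(split_half_reliability(shuffled, 20, seed = 9)$estimate,
               base$estimate, tolerance = 1e-12)
})

test_that("split-half requires enough raters and common expressions", {
  tab <- data.frame(rater_id = c("a", "b"), expression = c("x", "x"),
                    rating = c(3, 3))
  expect_error(split_half_reliability(tab), "at least 4 raters")
  # raters covering disjoint expression sets leave < 3 common items
  tab2 <- data.frame(
    rater_id = rep(c("a", "b", "c", "d"), each = 3),
    expression = paste0("w", 1:12),
    rating = runif(12, 1, 5)
  )
  suppressWarnings(
    expect_warning(expect_error(split_half_reliability(tab2, iterations = 2),
                                "skipped"),
                   "common expressions")
  )
})

test_that("the measured corrected reliability tracks the stored analytic value", {
  corpus <- gen_corpus(synth_spec(n_expressions = 300, seed = 6))
  tab <- gen_raters(corpus, n_raters = 40, noise_sd = 1.0, seed = 7)
  res <- split_half_reliability(tab, iterations = 60, seed = 8)
  expect_equal(res$estimate, attr(tab, "analytic")$split_half,
               tolerance = 0.02)
})

test_that("ICC equals 1 with zero within-expression variance and errors degenerately", {
  tab <- data.frame(
    rater_id = rep(c("a", "b", "c"), times = 10),
    expression = rep(paste0("w", 1:10), each = 3),
    rating = rep(seq(1, 5, length.out = 10), each = 3)
  )
  # a zero-residual fit sits on the variance boundary; lme4 may grumble
  res <- suppressWarnings(suppressMessages(icc_reliability(tab)))
  expect_equal(res$estimate, 1, tolerance = 1e-6)
  one_expr <- data.frame(rater_id = c("a", "b"), expression = "w",
                         rating = c(2, 3))
  expect_error(icc_reliability(one_expr), class = "concretr_validation")
  flat <- data.frame(rater_id = rep(c("a", "b"), 5),
                     expression = rep(paste0("w", 1:5), each = 2),
                     rating = rep(3, 10))
  expect_error(icc_reliability(flat), class = "concretr_validation")
})

test_that("ICC recovers the variance-component ratio from simulation", {
  corpus <- gen_corpus(synth_spec(n_expressions = 250, seed = 10))
  tab <- gen_raters(corpus, n_raters = 20, noise_sd = 1.0, seed = 11)
  res <- icc_reliability(tab)
  expect_equal(res$estimate, attr(tab, "analytic")$icc, tolerance = 0.06)
})

test_that("bias by band reproduces constructed band shifts", {
  y <- c(1.2, 1.8, 3.0, 3.5, 4.7, 4.9)
  expect_true(all(bias_by_band(y, y)$bias == 0))
  p <- y + ifelse(y < 2, 0.3, ifelse(y > 4.5, -0.2, 0))
  rep_bias <- bias_by_band(p, y)
  expect_equal(rep_bias$bias, c(0.3, 0, -0.2))
  expect_equal(rep_bias$n, c(2L, 2L, 2L))
  # hand-computed toy with mixed errors in one band
  p2 <- c(1.5, 2.1, 3.0, 3.5, 4.7, 4.9)
  expect_equal(bias_by_band(p2, y)$bias[1], mean(c(0.3, 0.3)))
  # empty band reported as NA
  empty <- bias_by_band(c(3, 3.2, 3.4), c(3.1, 3.2, 3.3))
  expect_true(is.na(empty$bias[1]) && is.na(empty$bias[3]))
})

test_that("distribution comparison matches brute-force KS and overlap", {
  brute_ks <- function(a, b) {
    pts <- sort(unique(c(a, b)))
    max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
  }
  brute_overlap <- function(a, b, breaks) {
    ha <- hist(a, breaks = breaks, plot = FALSE)$counts / length(a)
    hb <- hist(b, breaks = breaks, plot = FALSE)$counts / length(b)
    s <- 0
    for (i in seq_along(ha)) s <- s + min(ha[i], hb[i])
    s
  }
  withr::with_seed(22, {
    for (i in 1:25) {
      a <- runif(sample(10:80, 1), 1, 5)
      b <- runif(sample(10:80, 1), 1, 5)
      dc <- distribution_compare(a, b, bins = 20)
      expect_equal(dc$ks_statistic, brute_ks(a, b), tolerance = 1e-10)
      breaks <- seq(min(1, a, b), max(5, a, b), length.out = 21)
      expect_equal(dc$overlap, brute_overlap(a, b, breaks), tolerance = 1e-10)
    }
  })
})

test_that("distribution comparison degenerate cases are exact", {
  x <- runif(30, 1, 5)
  same <- distribution_compare(x, x)
  expect_equal(same$ks_statistic, 0)
  expect_equal(same$overlap, 1)
  lo <- runif(20, 1, 1.5); hi <- runif(20, 4.5, 5)
  apart <- distribution_compare(lo, hi)
  expect_equal(apart$overlap, 0)
  expect_equal(apart$ks_statistic, 1)
})

test_that("same-distribution samples rarely exceed the KS critical value", {
  reject <- withr::with_seed(23, {
    vapply(1:20, function(i) {
      draw <- function() {
        comp <- rbinom(500, 1, 0.5)
        pmin(5, pmax(1, rnorm(500, ifelse(comp == 1, 4.5, 2.5), 0.6)))
      }
      crit <- 1.358 * sqrt(2 / 500)  # 5% two-sample critical value
      distribution_compare(draw(), draw())$ks_statistic > crit
    }, logical(1))
  })
  expect_gte(mean(!reject), 0.9)
})
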