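#' Construct a rating corpus
#'
#' A rating corpus holds one row per expression with its human concreteness
#' statistics: the mean rating on the 1-5 Likert scale (1 = highly abstract,
#' 5 = highly concrete), optionally the inter-rater standard deviation and
#' the number of raters.
#'
#' @param expression Character vector of expressions.
#' @param rating_mean Numeric vector of mean ratings in `[1, 5]`.
#' @param rating_sd Optional numeric vector of inter-rater SDs (>= 0).
#' @param n_raters Optional integer vector of rater counts (>= 1).
#' @param language BCP-47-style language tag (default `"en"`).
#' @param provenance Free-text provenance note.
#' @return A `rating_corpus`: a data.frame with columns `expression`,
#'   `rating_mean`, `rating_sd`, `n_raters` and attributes `language` and
#'   `provenance`.
#' @export
rating_corpus <- function(expression, rating_mean, rating_sd = NULL,
                          n_raters = NULL, language = "en",
                          provenance = "unspecified") {
  expression <- as.character(expression)
  rating_mean <- as.numeric(rating_mean)
  if (length(expression) == 0L) {
    stopf("a rating corpus must contain at least one record",
          class = "concretr_empty_corpus")
  }
  if (length(rating_mean) != length(expression)) {
    stopf("`expression` and `rating_mean` lengths differ")
  }
  bad <- which(!is.finite(rating_mean) | rating_mean < 1 | rating_mean > 5)
  if (length(bad)) {
    stopf("rating_mean outside [1, 5] at row %d (value %s)",
          bad[1], format(rating_mean[bad[1]]), class = "concretr_validation")
  }
  if (any(!nzchar(trimws(expression)))) {
    stopf("empty expression at row %d", which(!nzchar(trimws(expression)))[1],
          class = "concretr_validation")
  }
  df <- data.frame(
    expression = expression,
    rating_mean = rating_mean,
    rating_sd = if (is.null(rating_sd)) NA_real_ else as.numeric(rating_sd),
    n_raters = if (is.null(n_raters)) NA_integer_ else as.integer(n_raters),
    stringsAsFactors = FALSE
  )
  if (any(!is.na(df$rating_sd) & df$rating_sd < 0)) {
    stopf("rating_sd must be >= 0", class = "concretr_validation")
  }
  structure(df, language = language, provenance = provenance,
            class = c("rating_corpus", "data.frame"))
}

#' @export
print.rating_corpus <- function(x, ...) {
  cat(sprintf("<rating_corpus: %d expressions, language=%s, provenance=%s>\n",
              nrow(x), attr(x, "language"), attr(x, "provenance")))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("... and %d more rows\n", nrow(x) - 5L))
  invisible(x)
}

#' Read a concreteness norm corpus from a delimited file
#'
#' Reads a UTF-8 CSV/TSV with a header row. Rows with missing mean ratings or
#' expressions containing non-standard characters (anything outside Unicode
#' letters, digits, space, hyphen, underscore, apostrophe) are dropped and
#' logged; duplicate expressions after normalization keep their first
#' occurrence. Homographs are ordinary distinct rows and are retained.
#'
#' @param path Path to the delimited file.
#' @param dialect List with optional entries `sep` (default `","`),
#'   `expression`, `rating_mean`, `rating_sd`, `n_raters` naming the columns.
#' @param language,provenance Corpus metadata.
#' @param log_path Optional path; dropped rows and reasons are written there
#'   as a tab-separated sidecar log.
#' @return A [rating_corpus()] with attribute `dropped` (data.frame of
#'   dropped rows and reasons).
#' @export
read_rating_corpus <- function(path, dialect = list(),
                               language = "en", provenance = path,
                               log_path = NULL) {
  if (!file.exists(path)) {
    stopf("cannot read corpus file '%s'", path, class = "concretr_io")
  }
  sep <- dialect$sep %||% ","
  raw <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                      stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                      check.names = FALSE, comment.char = ""),
    error = function(e) stopf("failed to parse '%s': %s", path,
                              conditionMessage(e), class = "concretr_io")
  )
  col_expr <- dialect$expression %||% "expression"
  col_mean <- dialect$rating_mean %||% "rating_mean"
  col_sd <- dialect$rating_sd %||% "rating_sd"
  col_n <- dialect$n_raters %||% "n_raters"
  for (cc in c(col_expr, col_mean)) {
    if (!cc %in% names(raw)) {
      stopf("required column '%s' not found in '%s'", cc, path,
            class = "concretr_io")
    }
  }
  expr <- as.character(raw[[col_expr]])
  mean_chr <- as.character(raw[[col_mean]])
  mean_num <- suppressWarnings(as.numeric(mean_chr))

  drop_reason <- rep(NA_character_, nrow(raw))
  missing_mean <- is.na(mean_chr) | !nzchar(trimws(mean_chr)) | is.na(mean_num)
  drop_reason[missing_mean] <- "missing rating"
  bad_expr <- is.na(expr) | !nzchar(trimws(expr)) |
    !has_only_allowed_chars(trimws(expr))
  drop_reason[is.na(drop_reason) & bad_expr] <- "non-standard characters"

  keep <- is.na(drop_reason)
  out_of_range <- keep & (mean_num < 1 | mean_num > 5)
  if (any(out_of_range)) {
    stopf("rating %s outside [1, 5] at data row %d of '%s'",
          format(mean_num[which(out_of_range)[1]]), which(out_of_range)[1],
          path, class = "concretr_validation")
  }

  # duplicates after normalization: keep first occurrence, log the rest
  norm <- vapply(expr, function(e) {
    if (is.na(e) || !nzchar(trimws(e))) "" else
      tolower(gsub("[[:space:]]+", " ", trimws(e)))
  }, character(1), USE.NAMES = FALSE)
  dup <- keep & duplicated(ifelse(keep, norm, paste0("\x01", seq_along(norm))))
  drop_reason[dup] <- "duplicate after normalization"
  keep <- is.na(drop_reason)

  dropped <- data.frame(
    row = which(!keep),
    expression = expr[!keep],
    reason = drop_reason[!keep],
    stringsAsFactors = FALSE
  )
  if (nrow(dropped) > 0) {
    warnf("dropped %d of %d rows while reading '%s'",
          nrow(dropped), nrow(raw), path)
  }
  if (!is.null(log_path)) {
    utils::write.table(dropped, log_path, sep = "\t", row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
  }
  if (!any(keep)) {
    stopf("no valid rows survive cleaning in '%s'", path,
          class = "concretr_empty_corpus")
  }
  sd_vec <- if (col_sd %in% names(raw)) {
    suppressWarnings(as.numeric(raw[[col_sd]]))[keep]
  } else NULL
  n_vec <- if (col_n %in% names(raw)) {
    suppressWarnings(as.integer(raw[[col_n]]))[keep]
  } else NULL
  corpus <- rating_corpus(trimws(expr[keep]), mean_num[keep],
                          rating_sd = sd_vec, n_raters = n_vec,
                          language = language, provenance = provenance)
  attr(corpus, "dropped") <- dropped
  corpus
}

#' Write a rating corpus to CSV
#'
#' @param corpus A [rating_corpus()].
#' @param path Output path (UTF-8 CSV with header).
#' @return `path`, invisibly.
#' @export
write_rating_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "rating_corpus"))
  utils::write.csv(as.data.frame(corpus), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Stratified train/test split of a rating corpus
#'
#' Partitions a corpus into train and test sets while preserving the
#' proportion of concrete (`rating_mean >= threshold`) and abstract
#' (`rating_mean < threshold`) expressions; the conventional boundary on the
#' 1-5 scale is 2.88, with the boundary value itself counted as concrete.
#' Test allocation per stratum is the rounded proportional share, so the
#' concrete fraction of the test set matches the corpus fraction within
#' `1/test_n`. The split is reproducible given `seed`.
#'
#' @param corpus A [rating_corpus()].
#' @param test_n Number of test records, `0 < test_n < nrow(corpus)`.
#' @param threshold Concrete/abstract boundary (default 2.88).
#' @param seed Integer seed.
#' @return A list with elements `train` and `test`, both `rating_corpus`.
#' @export
stratified_split <- function(corpus, test_n, threshold = 2.88, seed = 42) {
  stopifnot(inherits(corpus, "rating_corpus"))
  n <- nrow(corpus)
  if (!is_scalar_number(test_n) || test_n <= 0 || test_n >= n) {
    stopf("`test_n` must satisfy 0 < test_n < %d", n)
  }
  test_n <- as.integer(test_n)
  concrete <- corpus$rating_mean >= threshold
  idx_con <- which(concrete)
  idx_abs <- which(!concrete)
  n_con_test <- as.integer(round(test_n * length(idx_con) / n))
  n_abs_test <- test_n - n_con_test
  if (n_con_test > length(idx_con)) {
    stopf("concrete stratum (%d records) smaller than its allocation (%d)",
          length(idx_con), n_con_test)
  }
  if (n_abs_test > length(idx_abs) || n_abs_test < 0) {
    stopf("abstract stratum (%d records) smaller than its allocation (%d)",
          length(idx_abs), n_abs_test)
  }
  test_idx <- with_local_seed(as.integer(seed), {
    c(
      if (n_con_test > 0) sample(idx_con, n_con_test) else integer(0),
      if (n_abs_test > 0) sample(idx_abs, n_abs_test) else integer(0)
    )
  })
  test_idx <- sort(test_idx)
  subset_corpus <- function(i) {
    out <- corpus[i, , drop = FALSE]
    attributes(out)[c("language", "provenance")] <-
      attributes(corpus)[c("language", "provenance")]
    class(out) <- c("rating_corpus", "data.frame")
    rownames(out) <- NULL
    out
  }
  list(train = subset_corpus(setdiff(seq_len(n), test_idx)),
       test = subset_corpus(test_idx))
}

#' Exclude high-disagreement expressions
#'
#' Removes records whose inter-rater SD lies more than `k` standard
#' deviations above the corpus-wide mean of `rating_sd` (a single pass; the
#' mean and SD of `rating_sd` are computed once on the input). This mirrors
#' the usual post-hoc exclusion of items on which human raters disagreed
#' strongly.
#'
#' @param corpus A [rating_corpus()] in which every record carries
#'   `rating_sd`.
#' @param k Number of standard deviations (default 3).
#' @return The filtered `rating_corpus` with attributes `removed_n` and
#'   `removed` (the excluded rows).
#' @export
exclude_high_disagreement <- function(corpus, k = 3) {
  stopifnot(inherits(corpus, "rating_corpus"))
  if (any(is.na(corpus$rating_sd))) {
    stopf("every record must carry rating_sd", class = "concretr_validation")
  }
  mu <- mean(corpus$rating_sd)
  sigma <- stats::sd(corpus$rating_sd)
  if (nrow(corpus) < 2 || sigma == 0 || is.na(sigma)) {
    flagged <- rep(FALSE, nrow(corpus))
  } else {
    flagged <- (corpus$rating_sd - mu) / sigma > k
  }
  out <- corpus[!flagged, , drop = FALSE]
  attributes(out)[c("language", "provenance")] <-
    attributes(corpus)[c("language", "provenance")]
  class(out) <- c("rating_corpus", "data.frame")
  rownames(out) <- NULL
  attr(out, "removed_n") <- sum(flagged)
  attr(out, "removed") <- as.data.frame(corpus[flagged, , drop = FALSE])
  out
}
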