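test_that("reading a well-formed corpus preserves every record", {
  path <- write_corpus_csv(c(
    "expression,rating_mean,rating_sd,n_raters",
    "table,4.9,0.4,25",
    "freedom,1.4,0.9,25",
    "ice cream,4.6,0.5,25"
  ))
  corpus <- read_rating_corpus(path)
  expect_s3_class(corpus, "rating_corpus")
  expect_equal(nrow(corpus), 3L)
  expect_equal(corpus$expression, c("table", "freedom", "ice cream"))
  expect_equal(corpus$rating_mean, c(4.9, 1.4, 4.6))
})

test_that("rows with missing ratings or non-standard characters are dropped and logged", {
  log <- tempfile(fileext = ".tsv")
  path <- write_corpus_csv(c(
    "expression,rating_mean",
    "table,4.9",
    "freedom,",
    "we!rd,3.0",
    "self-esteem,2.1",
    "o'clock,3.4"
  ))
  expect_warning(
    corpus <- read_rating_corpus(path, log_path = log),
    "dropped 2 of 5"
  )
  # hyphen and apostrophe are permitted; '!' and a missing mean are not
  expect_equal(corpus$expression, c("table", "self-esteem", "o'clock"))
  dropped <- attr(corpus, "dropped")
  expect_setequal(dropped$reason, c("missing rating", "non-standard characters"))
  logged <- read.delim(log)
  expect_equal(nrow(logged), 2L)
})

test_that("ratings outside the 1-5 scale are a validation error naming the row", {
  path <- write_corpus_csv(c("expression,rating_mean", "table,4.9", "odd,6.0"))
  expect_error(read_rating_corpus(path), class = "concretr_validation")
  path2 <- write_corpus_csv(c("expression,rating_mean", "under,0.5"))
  expect_error(read_rating_corpus(path2), class = "concretr_validation")
})

test_that("duplicates after normalization keep the first occurrence", {
  path <- write_corpus_csv(c(
    "expression,rating_mean",
    "Table,4.9",
    "table,2.0",
    "TABLE ,3.0",
    "chair,4.1"
  ))
  expect_warning(corpus <- read_rating_corpus(path), "dropped 2")
  expect_equal(nrow(corpus), 2L)
  expect_equal(corpus$rating_mean[corpus$expression == "Table"], 4.9)
})

test_that("an unreadable file and an all-invalid file raise distinct errors", {
  expect_error(read_rating_corpus(tempfile()), class = "concretr_io")
  path <- write_corpus_csv(c("expression,rating_mean", "bad!,"))
  expect_error(suppressWarnings(read_rating_corpus(path)),
               class = "concretr_empty_corpus")
})

test_that("a corpus round-trips through write and read unchanged", {
  corpus <- tiny_corpus()
  path <- tempfile(fileext = ".csv")
  write_rating_corpus(corpus, path)
  back <- read_rating_corpus(path)
  expect_equal(back$expression, corpus$expression)
  expect_equal(back$rating_mean, corpus$rating_mean)
  expect_equal(back$rating_sd, corpus$rating_sd)
  expect_equal(back$n_raters, corpus$n_raters)
})

test_that("stratified split conserves records and hits stratum counts exactly", {
  corpus <- tiny_corpus()  # 5 concrete (>= 2.88), 5 abstract
  for (seed in 1:25) {
    sp <- stratified_split(corpus, test_n = 2, seed = seed)
    expect_equal(nrow(sp$test), 2L)
    expect_equal(sum(sp$test$rating_mean >= 2.88), 1L)
    expect_equal(sum(sp$test$rating_mean < 2.88), 1L)
    # multiset conservation
    expect_setequal(c(sp$train$expression, sp$test$expression),
                    corpus$expression)
    expect_equal(nrow(sp$train) + nrow(sp$test), nrow(corpus))
  }
})

test_that("the boundary value 2.88 counts as concrete", {
  corpus <- rating_corpus(sprintf("w%02d", 1:10),
                          c(rep(2.88, 5), rep(1.5, 5)))
  sp <- stratified_split(corpus, test_n = 2, seed = 1)
  expect_equal(sum(sp$test$rating_mean == 2.88), 1L)
})

test_that("stratified split is reproducible and validates test_n", {
  corpus <- tiny_corpus()
  a <- stratified_split(corpus, 3, seed = 99)
  b <- stratified_split(corpus, 3, seed = 99)
  expect_identical(a$test$expression, b$test$expression)
  expect_identical(a$train$expression, b$train$expression)
  expect_error(stratified_split(corpus, 10), "test_n")
  expect_error(stratified_split(corpus, 0), "test_n")
})

test_that("a stratum smaller than its allocation is reported", {
  corpus <- rating_corpus(sprintf("w%02d", 1:10), c(4.5, rep(1.5, 9)))
  # 8/10 of the corpus in the test set wants round(8 * 0.1) = 1 concrete,
  # which exists; force the failure with an all-abstract-but-one corpus and
  # a test_n demanding more concrete items than exist
  corpus2 <- rating_corpus(sprintf("w%02d", 1:4), c(4.5, 4.6, 1.5, 1.6))
  expect_silent(stratified_split(corpus2, 2, seed = 1))
  corpus3 <- rating_corpus(sprintf("w%02d", 1:4), c(4.5, 1.4, 1.5, 1.6))
  sp <- stratified_split(corpus3, 3, seed = 1)  # round(3/4 * 1) = 1 concrete
  expect_equal(nrow(sp$test), 3L)
})

test_that("high-disagreement exclusion matches a brute-force z-score oracle", {
  spec <- synth_spec(n_expressions = 400, seed = 21)
  corpus <- gen_corpus(spec)
  # inflate 5% of the SDs
  idx <- withr::with_seed(7, sample(400, 20))
  corpus$rating_sd[idx] <- corpus$rating_sd[idx] + 2.5
  filtered <- exclude_high_disagreement(corpus, k = 3)
  # independent brute-force z-scores on the input
  z <- (corpus$rating_sd - mean(corpus$rating_sd)) / sd(corpus$rating_sd)
  oracle_removed <- corpus$expression[z > 3]
  expect_setequal(attr(filtered, "removed")$expression, oracle_removed)
  expect_equal(attr(filtered, "removed_n"), length(oracle_removed))
  expect_equal(nrow(filtered), 400 - length(oracle_removed))
})

test_that("exclusion removes nothing when all SDs are identical and errors on missing SDs", {
  corpus <- rating_corpus(sprintf("w%02d", 1:6), rep(3, 6),
                          rating_sd = rep(0.8, 6))
  out <- exclude_high_disagreement(corpus)
  expect_equal(nrow(out), 6L)
  expect_equal(attr(out, "removed_n"), 0L)
  corpus_nosd <- rating_corpus(sprintf("w%02d", 1:6), rep(3, 6))
  expect_error(exclude_high_disagreement(corpus_nosd),
               class = "concretr_validation")
})

test_that("large-corpus exclusion yields a strict subset", {
  corpus <- gen_corpus(synth_spec(n_expressions = 4000, seed = 31))
  out <- exclude_high_disagreement(corpus, k = 3)
  expect_lt(nrow(out), nrow(corpus))
  expect_true(all(out$expression %in% corpus$expression))
})
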