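test_that("dual embedding concatenates 512 + 512 into 1024 in fixed order", {
  bk <- get_test_backends()
  f <- embed_pair("dog", bk$base, bk$emotion)
  expect_equal(dim(f), c(1L, 1024L))
  expect_equal(as.numeric(f[1, 1:512]), as.numeric(backend_embed(bk$base, "dog")))
  expect_equal(as.numeric(f[1, 513:1024]),
               as.numeric(backend_embed(bk$emotion, "dog")))
  # permuting the backends changes the feature: no silent symmetry
  swapped <- embed_pair("dog", bk$emotion, bk$base)
  expect_false(isTRUE(all.equal(as.numeric(f), as.numeric(swapped))))
})

test_that("zero backends concatenate to 1024 zeros", {
  f <- embed_pair("anything", zero_backend(), zero_backend())
  expect_equal(as.numeric(f), rep(0, 1024))
})

test_that("a backend violating the 512-d contract is rejected", {
  bad <- embedding_backend("bad", function(tokens) {
    matrix(1, nrow = length(tokens), ncol = 100)
  }, dim = 512)
  expect_error(embed_pair("x", bad, zero_backend()),
               class = "concretr_backend")
  failing <- embedding_backend("boom", function(tokens) stop("no"), dim = 512)
  expect_error(embed_pair("x", failing, zero_backend()),
               class = "concretr_backend")
})

test_that("the cache serves repeated tokens without recomputation, bit-identically", {
  bk <- get_test_backends()
  counted <- counting_backend(bk$base)
  cache <- embedding_cache()
  f1 <- embed_pair("dog", counted$backend, bk$emotion, cache = cache)
  n_after_first <- counted$counter$n
  f2 <- embed_pair("dog", counted$backend, bk$emotion, cache = cache)
  expect_identical(as.numeric(f1), as.numeric(f2))
  expect_equal(counted$counter$n, n_after_first)
  # mixed hit/miss batch embeds only the new token
  f3 <- embed_pair(c("dog", "cat"), counted$backend, bk$emotion, cache = cache)
  expect_equal(counted$counter$n, n_after_first + 1L)
  expect_identical(as.numeric(f3[1, ]), as.numeric(f1))
})

test_that("a persisted cache restores identical vectors", {
  bk <- get_test_backends()
  cache <- embedding_cache()
  f <- embed_pair(c("alpha", "beta"), bk$base, bk$emotion, cache = cache)
  dir <- tempfile()
  save_embedding_cache(cache, dir)
  back <- load_embedding_cache(dir)
  f3 <- embed_pair(c("alpha", "beta"), bk$base, bk$emotion, cache = back)
  expect_identical(as.numeric(f3), as.numeric(f))
})

test_that("the standardizer centres and scales, with unit scale for constant dims", {
  withr::with_seed(4, {
    X <- cbind(matrix(rnorm(300 * 3, mean = 2, sd = 3), 300), rep(7, 300))
  })
  sc <- fit_standardizer(X)
  expect_equal(sc$scale[4], 1)
  Z <- apply_standardizer(sc, X)
  expect_lt(max(abs(colMeans(Z))), 1e-10)
  expect_equal(as.numeric(Z[, 4]), rep(0, 300))
  expect_equal(apply(Z[, 1:3], 2, function(v) mean(v^2)), rep(1, 3),
               tolerance = 1e-8)
})

test_that("standardizer identities hold and small toy cases match hand arithmetic", {
  X <- rbind(c(1, 10), c(2, 20), c(3, 30))
  sc <- fit_standardizer(X)
  expect_equal(sc$mean, c(2, 20))
  expect_equal(sc$scale, c(sqrt(2 / 3), sqrt(200 / 3)))
  expect_equal(as.numeric(apply_standardizer(sc, sc$mean)), c(0, 0))
  expect_equal(as.numeric(apply_standardizer(sc, sc$mean + sc$scale)), c(1, 1))
  expect_error(fit_standardizer(X[1, , drop = FALSE]), "at least 2")
  expect_error(apply_standardizer(sc, c(1, 2, 3)), "dimensionality")
})

test_that("contrastive loss matches a brute-force softmax oracle", {
  brute <- function(U, V, ls) {
    n <- nrow(U)
    Uh <- t(apply(U, 1, function(x) x / sqrt(sum(x^2))))
    Vh <- t(apply(V, 1, function(x) x / sqrt(sum(x^2))))
    S <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) S[i, j] <- exp(ls) * sum(Uh[i, ] * Vh[j, ])
    tot <- 0
    for (i in 1:n) {
      tot <- tot - log(exp(S[i, i]) / sum(exp(S[i, ])))
      tot <- tot - log(exp(S[i, i]) / sum(exp(S[, i])))
    }
    tot / (2 * n)
  }
  withr::with_seed(11, {
    for (rep in 1:20) {
      n <- sample(2:6, 1); d <- sample(3:10, 1)
      U <- matrix(rnorm(n * d), n); V <- matrix(rnorm(n * d), n)
      ls <- runif(1, 0, 3)
      expect_equal(contrastive_loss(U, V, ls), brute(U, V, ls),
                   tolerance = 1e-10)
    }
  })
})

test_that("contrastive closed forms hold: single pair 0, identical batch ln N", {
  V <- matrix(rnorm(8), 1)
  expect_equal(contrastive_loss(V, V), 0)
  for (n in c(2, 5, 9)) {
    same <- matrix(rep(c(1, 2, 3), each = n), n)
    expect_equal(contrastive_loss(same, same), log(n), tolerance = 1e-10)
  }
})

test_that("contrastive gradients agree with numerical differentiation", {
  withr::with_seed(13, {
    U <- matrix(rnorm(4 * 5), 4); V <- matrix(rnorm(4 * 5), 4); ls <- 1.2
  })
  g <- concretr:::contrastive_loss_grad(U, V, ls)
  eps <- 1e-6
  for (k in sample(length(U), 5)) {
    U2 <- U; U2[k] <- U2[k] + eps
    U3 <- U; U3[k] <- U3[k] - eps
    num <- (contrastive_loss(U2, V, ls) - contrastive_loss(U3, V, ls)) / (2 * eps)
    expect_equal(g$gU[k], num, tolerance = 1e-5)
  }
  ls_num <- (contrastive_loss(U, V, ls + eps) -
               contrastive_loss(U, V, ls - eps)) / (2 * eps)
  expect_equal(g$g_scale, ls_num, tolerance = 1e-5)
})

test_that("fine-tuning on separable synthetic pairs drives the loss down", {
  pairs <- gen_image_text_pairs(8, seed = 2)
  bk <- make_toy_clip_backend(1)
  ft <- contrastive_finetune(bk, pairs, config = list(steps = 50))
  expect_length(ft$loss_history, 50L)
  expect_lt(ft$loss_history[50], ft$loss_history[1])
  expect_lt(mean(tail(ft$loss_history, 10)), mean(head(ft$loss_history, 10)))
  # the updated backend still honours the embedding contract
  emb <- backend_embed(ft$backend, c("joy", "fear"))
  expect_equal(dim(emb), c(2L, 512L))
})

test_that("a batch sharing a single label warns of degenerate contrast", {
  pairs <- gen_image_text_pairs(4, seed = 3, labels = "joy")
  bk <- make_toy_clip_backend(1)
  expect_warning(contrastive_finetune(bk, pairs, config = list(steps = 1)),
                 "degenerate contrast")
})
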