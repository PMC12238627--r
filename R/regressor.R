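#' Training configuration for the deep regressor
#'
#' Defaults follow the canonical training regime for this architecture:
#' Adam with initial learning rate 5e-4, batch size 50, dropout 0.2 after
#' each hidden layer, L2 weight decay 1e-5, a plateau scheduler that
#' multiplies the learning rate by 0.1 after 3 epochs without improvement,
#' early stopping after 5 epochs without a validation-loss decrease, a 10%
#' validation split, and seed 42. `max_epochs` (100) and the scheduler's
#' improvement threshold (absolute decrease of 1e-4) have no canonical
#' values and are documented defaults.
#'
#' @param learning_rate,batch_size,dropout,weight_decay Optimizer settings.
#' @param scheduler_factor,scheduler_patience,scheduler_threshold Plateau
#'   scheduler settings.
#' @param early_stop_patience Epochs without validation improvement before
#'   training halts.
#' @param validation_fraction Fraction of the training data held out for
#'   validation monitoring (stratified at the 2.88 concrete/abstract
#'   boundary).
#' @param max_epochs Upper bound on epochs.
#' @param seed Integer seed controlling initialization, splitting, shuffling
#'   and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-4, batch_size = 50,
                         dropout = 0.2, weight_decay = 1e-5,
                         scheduler_factor = 0.1, scheduler_patience = 3,
                         scheduler_threshold = 1e-4,
                         early_stop_patience = 5,
                         validation_fraction = 0.10,
                         max_epochs = 100, seed = 42) {
  cfg <- list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
              dropout = dropout, weight_decay = weight_decay,
              scheduler_factor = scheduler_factor,
              scheduler_patience = as.integer(scheduler_patience),
              scheduler_threshold = scheduler_threshold,
              early_stop_patience = as.integer(early_stop_patience),
              validation_fraction = validation_fraction,
              max_epochs = as.integer(max_epochs), seed = as.integer(seed))
  stopifnot(cfg$learning_rate > 0, cfg$batch_size > 0, cfg$dropout >= 0,
            cfg$dropout < 1, cfg$weight_decay >= 0,
            cfg$scheduler_factor > 0, cfg$scheduler_factor <= 1,
            cfg$validation_fraction > 0, cfg$validation_fraction < 1,
            cfg$max_epochs > 0)
  structure(cfg, class = "train_config")
}

#' Initialize the deep regressor
#'
#' The regressor is a feed-forward network mapping the standardized 1024-d
#' dual feature to a single concreteness score: two fully connected hidden
#' layers of 128 and 64 units with ReLU activations and a linear single-unit
#' output. Weights and biases use uniform fan-in initialization
#' (`U(-1/sqrt(fan_in), 1/sqrt(fan_in))`), except that the output-layer
#' bias starts at the Likert midpoint 3 — the standard regression-head
#' practice of initializing the head at the target scale's centre, so early
#' training fits deviations rather than spending steps climbing from 0 to
#' the rating mean. Initialization is deterministic given the seed.
#'
#' @param seed Integer seed.
#' @param input_dim Input dimensionality (default 1024; 512 when a single
#'   backend's features are regressed for comparison).
#' @param hidden Hidden layer widths (default `c(128, 64)`).
#' @return An object of class `mlp_regressor` with fields `W1, b1, W2, b2,
#'   W3, b3` and a `meta` list.
#' @export
init_regressor <- function(seed = 42, input_dim = 1024, hidden = c(128, 64)) {
  stopifnot(length(hidden) == 2)
  dims <- c(as.integer(input_dim), as.integer(hidden), 1L)
  layer <- function(fan_in, fan_out) {
    bound <- 1 / sqrt(fan_in)
    list(W = matrix(stats::runif(fan_in * fan_out, -bound, bound),
                    nrow = fan_in),
         b = stats::runif(fan_out, -bound, bound))
  }
  params <- with_local_seed(as.integer(seed), {
    l1 <- layer(dims[1], dims[2]); l2 <- layer(dims[2], dims[3])
    l3 <- layer(dims[3], dims[4])
    list(W1 = l1$W, b1 = l1$b, W2 = l2$W, b2 = l2$b, W3 = l3$W,
         b3 = l3$b + 3)
  })
  params$meta <- list(seed = as.integer(seed), input_dim = dims[1],
                      hidden = dims[2:3], dropout = 0,
                      epochs_run = NA_integer_, best_val_loss = NA_real_)
  class(params) <- "mlp_regressor"
  params
}

#' @export
print.mlp_regressor <- function(x, ...) {
  cat(sprintf(
    "<mlp_regressor %d-%d-%d-1: %s params, epochs=%s, best val MSE=%s>\n",
    x$meta$input_dim, x$meta$hidden[1], x$meta$hidden[2],
    format(n_parameters(x), big.mark = ","),
    x$meta$epochs_run, format(x$meta$best_val_loss, digits = 4)))
  invisible(x)
}

#' Number of trainable parameters in a regressor
#' @param params An `mlp_regressor`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(params) {
  length(params$W1) + length(params$b1) + length(params$W2) +
    length(params$b2) + length(params$W3) + length(params$b3)
}

relu <- function(m) {
  m[m < 0] <- 0
  m
}

# Forward pass. With training = TRUE, inverted dropout masks are drawn from
# the current RNG stream and hidden activations are scaled by 1/(1 - p).
mlp_forward <- function(params, X, dropout = 0, training = FALSE) {
  H1 <- relu(sweep(X %*% params$W1, 2, params$b1, "+"))
  if (training && dropout > 0) {
    M1 <- matrix(stats::rbinom(length(H1), 1, 1 - dropout), nrow = nrow(H1))
    H1d <- H1 * M1 / (1 - dropout)
  } else {
    M1 <- NULL; H1d <- H1
  }
  H2 <- relu(sweep(H1d %*% params$W2, 2, params$b2, "+"))
  if (training && dropout > 0) {
    M2 <- matrix(stats::rbinom(length(H2), 1, 1 - dropout), nrow = nrow(H2))
    H2d <- H2 * M2 / (1 - dropout)
  } else {
    M2 <- NULL; H2d <- H2
  }
  yhat <- as.numeric(H2d %*% params$W3 + params$b3)
  list(yhat = yhat, X = X, H1 = H1, H1d = H1d, H2 = H2, H2d = H2d,
       M1 = M1, M2 = M2)
}

# Backprop of the MSE loss through the forward cache.
mlp_backward <- function(params, fw, y, dropout = 0) {
  m <- length(y)
  d_y <- matrix(2 * (fw$yhat - y) / m, ncol = 1)
  gW3 <- t(fw$H2d) %*% d_y
  gb3 <- colSums(d_y)
  dH2d <- d_y %*% t(params$W3)
  if (!is.null(fw$M2)) dH2d <- dH2d * fw$M2 / (1 - dropout)
  dH2 <- dH2d * (fw$H2 > 0)
  gW2 <- t(fw$H1d) %*% dH2
  gb2 <- colSums(dH2)
  dH1d <- dH2 %*% t(params$W2)
  if (!is.null(fw$M1)) dH1d <- dH1d * fw$M1 / (1 - dropout)
  dH1 <- dH1d * (fw$H1 > 0)
  gW1 <- t(fw$X) %*% dH1
  gb1 <- colSums(dH1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

#' Train the deep regressor
#'
#' Mean-squared-error training with Adam, mini-batches with per-epoch
#' shuffling, inverted dropout after each hidden layer (training only), L2
#' weight decay, a reduce-on-plateau learning-rate scheduler, early stopping
#' on the validation loss, and restoration of the best-validation-epoch
#' weights. The validation split is stratified at the 2.88 threshold.
#'
#' @param features Numeric matrix of standardized features
#'   (rows = items).
#' @param targets Numeric vector of concreteness scores in `[1, 5]`, same
#'   length as `nrow(features)` and at least 20.
#' @param config A [train_config()].
#' @return List with `params` (the best-epoch `mlp_regressor`) and
#'   `history` (data.frame: epoch, train_loss, val_loss, lr).
#' @export
train_regressor <- function(features, targets, config = train_config()) {
  features <- as.matrix(features)
  targets <- as.numeric(targets)
  n <- nrow(features)
  if (n != length(targets) || n < 20) {
    stopf("need matching features/targets with at least 20 items")
  }
  if (any(targets < 1 - 1e-9 | targets > 5 + 1e-9)) {
    stopf("targets must lie within [1, 5]", class = "concretr_validation")
  }
  cfg <- config

  with_local_seed(cfg$seed, {
    # stratified validation split at the concrete/abstract boundary
    n_val <- max(2L, as.integer(round(n * cfg$validation_fraction)))
    conc <- which(targets >= 2.88)
    abst <- which(targets < 2.88)
    n_val_conc <- min(length(conc), as.integer(round(n_val * length(conc) / n)))
    n_val_abst <- min(length(abst), n_val - n_val_conc)
    val_idx <- sort(c(
      if (n_val_conc > 0) sample(conc, n_val_conc) else integer(0),
      if (n_val_abst > 0) sample(abst, n_val_abst) else integer(0)
    ))
    if (length(val_idx) < 2) stopf("validation split smaller than 2 items")
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xtr <- features[tr_idx, , drop = FALSE]; ytr <- targets[tr_idx]
    Xva <- features[val_idx, , drop = FALSE]; yva <- targets[val_idx]

    params <- init_regressor(cfg$seed, input_dim = ncol(features))
    opt <- lapply(params[c("W1", "b1", "W2", "b2", "W3", "b3")],
                  function(p) list(m = p * 0, v = p * 0))
    b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
    adam_t <- 0L
    lr <- cfg$learning_rate

    best <- list(val = Inf, params = params, epoch = 0L)
    sched_best <- Inf
    sched_wait <- 0L; stop_wait <- 0L
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0), lr = numeric(0))

    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample(length(tr_idx))
      batch_losses <- numeric(0)
      for (start in seq(1, length(perm), by = cfg$batch_size)) {
        bi <- perm[start:min(start + cfg$batch_size - 1L, length(perm))]
        fw <- mlp_forward(params, Xtr[bi, , drop = FALSE],
                          dropout = cfg$dropout, training = TRUE)
        loss <- mean((fw$yhat - ytr[bi])^2)
        if (!is.finite(loss)) stopf("non-finite training loss at epoch %d", epoch)
        batch_losses <- c(batch_losses, loss)
        gr <- mlp_backward(params, fw, ytr[bi], dropout = cfg$dropout)
        adam_t <- adam_t + 1L
        for (nm in names(gr)) {
          g <- gr[[nm]] + cfg$weight_decay * params[[nm]]
          opt[[nm]]$m <- b1m * opt[[nm]]$m + (1 - b1m) * g
          opt[[nm]]$v <- b2m * opt[[nm]]$v + (1 - b2m) * g^2
          mhat <- opt[[nm]]$m / (1 - b1m^adam_t)
          vhat <- opt[[nm]]$v / (1 - b2m^adam_t)
          params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
      val_loss <- mean((mlp_forward(params, Xva)$yhat - yva)^2)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = mean(batch_losses),
        val_loss = val_loss, lr = lr))

      if (val_loss < best$val) {
        best <- list(val = val_loss, params = params, epoch = epoch)
        stop_wait <- 0L
      } else {
        stop_wait <- stop_wait + 1L
      }
      # plateau scheduler: an "improvement" is an absolute decrease
      # exceeding the threshold
      if (val_loss < sched_best - cfg$scheduler_threshold) {
        sched_best <- val_loss
        sched_wait <- 0L
      } else {
        sched_wait <- sched_wait + 1L
      }
      if (sched_wait >= cfg$scheduler_patience) {
        lr <- lr * cfg$scheduler_factor
        sched_wait <- 0L
      }
      if (stop_wait >= cfg$early_stop_patience) break
    }

    out <- best$params
    out$meta$dropout <- cfg$dropout
    out$meta$epochs_run <- epoch
    out$meta$best_epoch <- best$epoch
    out$meta$best_val_loss <- best$val
    out$meta$seed <- cfg$seed
    list(params = out, history = history)
  })
}

#' Predict concreteness scores
#'
#' Runs the regressor with dropout disabled and reports both the raw network
#' output and the value clamped to the 1-5 Likert range.
#'
#' @param params A trained `mlp_regressor`.
#' @param features Standardized feature matrix (or single vector) with the
#'   training dimensionality.
#' @return List with numeric vectors `score` (clamped to `[1, 5]`) and
#'   `raw`.
#' @export
predict_scores <- function(params, features) {
  stopifnot(inherits(params, "mlp_regressor"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  features <- as.matrix(features)
  if (ncol(features) != params$meta$input_dim) {
    stopf("feature dimensionality %d does not match model input %d",
          ncol(features), params$meta$input_dim)
  }
  raw <- mlp_forward(params, features)$yhat
  list(score = clamp(raw), raw = raw)
}

#' Monte-Carlo dropout confidence
#'
#' Runs `n_passes` stochastic forward passes with dropout enabled and maps
#' the standard deviation of the outputs to a confidence in `(0, 1]` via
#' `1 / (1 + SD)`. With dropout 0 every pass is identical and the confidence
#' is 1. Deterministic given the seed.
#'
#' @param params A trained `mlp_regressor`.
#' @param features Feature matrix or single vector.
#' @param n_passes Number of stochastic passes (>= 2).
#' @param seed Integer seed.
#' @return Numeric vector of confidences, one per feature row.
#' @export
predict_confidence <- function(params, features, n_passes = 20, seed = 42) {
  stopifnot(inherits(params, "mlp_regressor"))
  if (n_passes < 2) stopf("`n_passes` must be >= 2")
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  features <- as.matrix(features)
  p <- params$meta$dropout %||% 0
  draws <- with_local_seed(as.integer(seed), {
    vapply(seq_len(n_passes), function(i) {
      mlp_forward(params, features, dropout = p, training = TRUE)$yhat
    }, numeric(nrow(features)))
  })
  if (nrow(features) == 1L) draws <- matrix(draws, nrow = 1)
  sds <- apply(draws, 1, stats::sd)
  1 / (1 + sds)
}
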