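# Internal helpers shared across modules.

# Polynomial rolling hash of a UTF-8 string onto [0, 2^31 - 2].
# Used to derive per-token RNG seeds; stable across sessions and platforms.
token_hash <- function(x, salt = "") {
  bytes <- utf8ToInt(enc2utf8(paste0(salt, "\x1f", x)))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG seed without touching the caller's
# RNG stream.
with_local_seed <- function(seed, expr) {
  withr::with_seed(seed, expr, .rng_kind = "Mersenne-Twister")
}

# Deterministic pseudo-random standard-normal draws keyed on a token.
token_normals <- function(token, n, salt = "") {
  with_local_seed(token_hash(token, salt), stats::rnorm(n))
}

clamp <- function(x, lo = 1, hi = 5) pmin(hi, pmax(lo, x))

unit_vector <- function(x) {
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) x else x / nrm
}

# Row-wise L2 normalization of a matrix, guarding zero rows.
normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  if (is.null(class)) stop(msg, call. = FALSE)
  stop(structure(
    class = c(class, "concretr_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
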