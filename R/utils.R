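# Internal helpers shared across modules.

# Deterministic per-subject / per-task substream seed, derived from a master
# seed so that adding subjects to a cohort never perturbs earlier subjects.
# Kept strictly below 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(master, subject = 0L, stream = 0L) {
  m <- 2147483629
  s <- (as.double(master) %% m)
  s <- (s * 48271 + as.double(subject) * 16807 + as.double(stream) * 69621) %% m
  as.integer(s)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) set.seed(seed)
  force(code)
}

# Draw n rows from a multivariate standard normal with correlation matrix R
# via its Cholesky factor (R is validated upstream to be positive definite).
rmvn_chol <- function(n, R) {
  L <- chol(R)
  z <- matrix(rnorm(n * ncol(R)), nrow = n)
  z %*% L
}

stop_cocktailr <- function(msg, class = "cocktailr_error") {
  rlang::abort(msg, class = c(class, "cocktailr_error"))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop_cocktailr(sprintf(
      "`%s` must be a single number in [%s, %s].", name,
      format(lower), format(upper)
    ), class = "cocktailr_config_error")
  }
  invisible(x)
}
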