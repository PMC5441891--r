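# L1-penalised least squares by cyclic coordinate descent.
#
# Objective: (1/(2n)) * sum((y - b0 - X b)^2) + lambda * sum(|b|), the
# intercept unpenalised. With this scaling lambda_max = max |x_j' y_c| / n
# (centred y, columns as given) shrinks every coefficient to zero, and for
# an orthonormal design (X'X/n = I) the solution is the soft-thresholded
# OLS coefficient exactly.

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

lasso_coord_descent <- function(X, y, lambda, beta0 = NULL,
                                tol = 1e-12, max_iter = 100000L) {
  n <- nrow(X)
  p <- ncol(X)
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  xss <- colSums(Xc^2) / n
  if (any(xss == 0)) {
    stop_cocktailr("Constant predictor column in the Lasso design.",
                   class = "cocktailr_domain_error")
  }
  beta <- if (is.null(beta0)) numeric(p) else beta0
  r <- yc - Xc %*% beta
  for (it in seq_len(max_iter)) {
    delta_max <- 0
    for (j in seq_len(p)) {
      bj_old <- beta[j]
      z <- sum(Xc[, j] * r) / n + xss[j] * bj_old
      bj <- soft_threshold(z, lambda) / xss[j]
      if (bj != bj_old) {
        r <- r - Xc[, j] * (bj - bj_old)
        delta_max <- max(delta_max, abs(bj - bj_old) * sqrt(xss[j]))
      }
      beta[j] <- bj
    }
    if (delta_max < tol) break
  }
  intercept <- ym - sum(xm * beta)
  list(intercept = intercept, beta = beta)
}

#' Lasso regression with k-fold cross-validated penalty selection
#'
#' Fits the full L1 path by cyclic coordinate descent over a log-spaced
#' grid of 100 penalties from lambda_max (the smallest penalty shrinking
#' every coefficient to zero) down to 1e-4 * lambda_max, assigns
#' observations to `k_folds` groups of approximately equal size by a seeded
#' random partition, computes the held-out mean squared error per penalty,
#' selects the penalty with the smallest cross-validation error, and
#' refits on all observations at that penalty. The intercept is never
#' penalised. Predictors are used as supplied (standardise them first when
#' comparing coefficients across predictors).
#'
#' @inheritParams fit_ols
#' @param k_folds Number of cross-validation folds (default 4).
#' @param lambda Optional penalty grid (decreasing); defaults to the
#'   documented 100-point grid.
#' @param seed Integer seed for the fold assignment (recorded in the
#'   result for exact reproducibility).
#' @return An object of class `lasso_cv_result`: `lambda` grid, `cvm`
#'   (CV mean squared errors), `lambda_min`, `coefficients` at
#'   `lambda_min` (with intercept), the coefficient `path` matrix, the
#'   recorded `folds`, and `seed`.
#' @export
#' @examples
#' d <- data.frame(y = rnorm(40), a = rnorm(40), b = rnorm(40))
#' d$y <- 2 * d$a + rnorm(40, 0, 0.5)
#' fit <- lasso_cv(d, "y", c("a", "b"), seed = 1)
#' tidy(fit)
lasso_cv <- function(data, response, predictors = NULL, k_folds = 4L,
                     lambda = NULL, seed = 1L) {
  data <- as.data.frame(data)
  if (is.null(predictors)) {
    predictors <- setdiff(
      names(data)[vapply(data, is.numeric, logical(1))],
      c(response, "subject_id")
    )
  }
  X <- as.matrix(data[predictors])
  y <- data[[response]]
  n <- nrow(X)
  if (k_folds > n) stop_cocktailr("More folds than observations.")
  if (k_folds < 2L) stop_cocktailr("Need at least 2 folds.")

  if (is.null(lambda)) {
    Xc <- sweep(X, 2, colMeans(X))
    lambda_max <- max(abs(crossprod(Xc, y - mean(y)))) / n
    lambda <- exp(seq(log(lambda_max), log(lambda_max * 1e-4), length.out = 100L))
  }
  lambda <- sort(lambda, decreasing = TRUE)

  set.seed(seed)
  folds <- sample(rep_len(seq_len(k_folds), n))

  cv_err <- matrix(NA_real_, nrow = k_folds, ncol = length(lambda))
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    beta <- NULL
    for (li in seq_along(lambda)) {
      fit <- lasso_coord_descent(X[tr, , drop = FALSE], y[tr], lambda[li],
                                 beta0 = beta)
      beta <- fit$beta
      pred <- fit$intercept + X[!tr, , drop = FALSE] %*% beta
      cv_err[f, li] <- mean((y[!tr] - pred)^2)
    }
  }
  cvm <- colMeans(cv_err)
  best <- which.min(cvm)

  path <- matrix(NA_real_, nrow = length(predictors), ncol = length(lambda),
                 dimnames = list(predictors, NULL))
  inter <- numeric(length(lambda))
  beta <- NULL
  for (li in seq_along(lambda)) {
    fit <- lasso_coord_descent(X, y, lambda[li], beta0 = beta)
    beta <- fit$beta
    path[, li] <- beta
    inter[li] <- fit$intercept
  }

  structure(
    list(
      lambda = lambda, cvm = cvm,
      lambda_min = lambda[best], index_min = best,
      intercept = inter[best],
      coefficients = setNames(path[, best], predictors),
      path = path, path_intercepts = inter,
      folds = folds, k_folds = k_folds, seed = seed,
      response = response, predictors = predictors, nobs = n
    ),
    class = "lasso_cv_result"
  )
}

#' Lasso fit at fixed penalty
#'
#' Single coordinate-descent fit at one penalty value (same objective and
#' scaling as [lasso_cv()]); exposed for closed-form checks and for
#' refitting at a chosen penalty.
#'
#' @inheritParams lasso_cv
#' @param lambda Single penalty value (>= 0).
#' @return A list: `intercept`, `beta` (named).
#' @export
lasso_fit <- function(data, response, predictors = NULL, lambda) {
  data <- as.data.frame(data)
  if (is.null(predictors)) {
    predictors <- setdiff(
      names(data)[vapply(data, is.numeric, logical(1))],
      c(response, "subject_id")
    )
  }
  assert_scalar_number(lambda, "lambda", lower = 0)
  fit <- lasso_coord_descent(as.matrix(data[predictors]), data[[response]],
                             lambda)
  list(intercept = fit$intercept, beta = setNames(fit$beta, predictors))
}

#' @export
print.lasso_cv_result <- function(x, ...) {
  sel <- names(x$coefficients)[x$coefficients != 0]
  cat(sprintf("<lasso_cv_result> %d-fold CV over %d penalties; lambda* = %.5g\n",
              x$k_folds, length(x$lambda), x$lambda_min))
  cat("  selected:", if (length(sel)) paste(sel, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' @method tidy lasso_cv_result
#' @export
tidy.lasso_cv_result <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients)),
    selected = c(TRUE, x$coefficients != 0)
  )
}

#' @method glance lasso_cv_result
#' @export
glance.lasso_cv_result <- function(x, ...) {
  tibble::tibble(lambda_min = x$lambda_min, cv_mse_min = min(x$cvm),
                 n_selected = sum(x$coefficients != 0), nobs = x$nobs,
                 k_folds = x$k_folds)
}

#' @describeIn lasso_cv Cross-validation error curve with the selected
#'   penalty marked.
#' @param object A `lasso_cv_result`.
#' @param ... Unused.
#' @method autoplot lasso_cv_result
#' @export
autoplot.lasso_cv_result <- function(object, ...) {
  d <- tibble::tibble(lambda = object$lambda, cvm = object$cvm)
  ggplot2::ggplot(d, ggplot2::aes(x = log10(.data$lambda), y = .data$cvm)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log10(object$lambda_min),
                        linetype = "dashed") +
    ggplot2::labs(x = "log10(lambda)", y = "CV mean squared error",
                  title = sprintf("%d-fold cross-validation", object$k_folds)) +
    ggplot2::theme_minimal()
}
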