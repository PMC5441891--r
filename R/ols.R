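#' z-standardise numeric columns
#'
#' Centres each selected column to mean 0 and scales it to sample SD 1
#' (n - 1 denominator). Constant columns are rejected by name.
#'
#' @param data A data frame (non-numeric columns pass through untouched) or
#'   a numeric matrix.
#' @param cols Columns to standardise; defaults to all numeric columns
#'   except `subject_id`.
#' @return Same shape as the input with the selected columns standardised.
#' @export
#' @examples
#' zstandardize(data.frame(x = 1:3))$x  # -1 0 1
zstandardize <- function(data, cols = NULL) {
  is_df <- is.data.frame(data)
  m <- if (is_df) data else as.data.frame(data)
  if (is.null(cols)) {
    cols <- names(m)[vapply(m, is.numeric, logical(1))]
    cols <- setdiff(cols, "subject_id")
  }
  sds <- vapply(m[cols], sd, numeric(1))
  if (any(!is.finite(sds) | sds <= 0)) {
    bad <- cols[!is.finite(sds) | sds <= 0]
    stop_cocktailr(sprintf("Cannot z-standardise constant column(s): %s.",
                           paste(bad, collapse = ", ")),
                   class = "cocktailr_domain_error")
  }
  for (cl in cols) m[[cl]] <- (m[[cl]] - mean(m[[cl]])) / sds[cl]
  if (is_df) tibble::as_tibble(m) else as.matrix(m)
}

#' Ordinary least-squares fit of a criterion on a predictor set
#'
#' Fits `response ~ predictors` (with intercept) by least squares via
#' [stats::lm()], returning a fitted object with broom-style [tidy()] and
#' [glance()] methods. Standard errors come from the usual
#' sigma^2 (X'X)^-1 estimator, and two-tailed p values from the t
#' distribution with n - p - 1 df.
#'
#' @param data A data frame containing the response and predictors.
#' @param response Name of the criterion column.
#' @param predictors Character vector of predictor columns; defaults to all
#'   numeric columns other than the response and `subject_id`.
#' @return An object of class `ols_fit`.
#' @export
#' @examples
#' d <- data.frame(y = c(1, 3, 2, 5, 4), x = 1:5)
#' tidy(fit_ols(d, "y", "x"))
fit_ols <- function(data, response, predictors = NULL) {
  data <- as.data.frame(data)
  if (is.null(predictors)) {
    predictors <- setdiff(
      names(data)[vapply(data, is.numeric, logical(1))],
      c(response, "subject_id")
    )
  }
  n <- nrow(data)
  p <- length(predictors)
  if (n <= p + 1L) {
    stop_cocktailr(sprintf("Need n > p + 1 observations (n = %d, p = %d).", n, p))
  }
  X <- as.matrix(data[predictors])
  M <- cbind(`(Intercept)` = 1, X)
  qx <- qr(M)
  if (qx$rank < p + 1L) {
    dep <- colnames(M)[qx$pivot[-seq_len(qx$rank)]]
    stop_cocktailr(sprintf("Design is rank deficient; dependent column(s): %s.",
                           paste(dep, collapse = ", ")),
                   class = "cocktailr_rank_error")
  }
  fm <- stats::reformulate(sprintf("`%s`", predictors),
                           response = sprintf("`%s`", response))
  fit <- lm(fm, data = data)
  structure(
    list(lm = fit, response = response, predictors = predictors,
         n = n, p = p),
    class = "ols_fit"
  )
}

#' @export
print.ols_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<ols_fit> %s ~ %d predictors, n = %d, R^2 = %.3f (p = %.3g)\n",
              x$response, x$p, x$n, g$r.squared, g$p.value))
  invisible(x)
}

#' @method tidy ols_fit
#' @export
tidy.ols_fit <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = unname(s[, 1]), std.error = unname(s[, 2]),
    statistic = unname(s[, 3]), p.value = unname(s[, 4])
  )
}

#' @method glance ols_fit
#' @export
glance.ols_fit <- function(x, ...) {
  s <- summary(x$lm)
  f <- s$fstatistic
  tibble::tibble(
    r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    statistic = unname(f[1]),
    p.value = stats::pf(f[1], f[2], f[3], lower.tail = FALSE),
    df = unname(f[2]), df.residual = unname(f[3]), nobs = x$n
  )
}

#' Residuals of an `ols_fit`
#' @param object An `ols_fit`.
#' @param ... Unused.
#' @export
residuals.ols_fit <- function(object, ...) unname(residuals(object$lm))

#' Outlier screen with externally studentized residuals and DFFITS
#'
#' Single-pass screen: fit on all observations, compute externally
#' studentized residuals (leave-one-out error variance) and DFFITS, flag
#' every observation whose |studentized residual| exceeds `resid_cut` or
#' whose |DFFITS| exceeds the DFFITS cut, and refit once on the retained
#' set. The default DFFITS cut follows the rule 2p/N (with N the number of
#' observations and p the number of predictors); the conventional
#' 2*sqrt(p/N) is available via `dffits_rule = "conventional"`.
#'
#' @inheritParams fit_ols
#' @param resid_cut Cut on |externally studentized residual| (default 1.96).
#' @param dffits_cut Explicit DFFITS cut; overrides `dffits_rule`.
#' @param dffits_rule "printed" (2p/N, default) or "conventional"
#'   (2*sqrt(p/N)).
#' @return An object of class `outlier_screen`: `full_fit` and
#'   `screened_fit` (`ols_fit`s), a per-observation `diagnostics` tibble
#'   (`row`, `rstudent`, `dffits`, `flagged`, `reason`), the `excluded`
#'   row indices, and the cuts used.
#' @export
outlier_screen <- function(data, response, predictors = NULL,
                           resid_cut = 1.96, dffits_cut = NULL,
                           dffits_rule = c("printed", "conventional")) {
  dffits_rule <- match.arg(dffits_rule)
  full <- fit_ols(data, response, predictors)
  n <- full$n
  p <- full$p
  if (is.null(dffits_cut)) {
    dffits_cut <- if (dffits_rule == "printed") 2 * p / n else 2 * sqrt(p / n)
  }
  rs <- unname(rstudent(full$lm))
  df_ <- unname(dffits(full$lm))
  flag_r <- abs(rs) > resid_cut
  flag_d <- abs(df_) > dffits_cut
  flagged <- flag_r | flag_d
  if (all(flagged)) {
    stop_cocktailr("All observations were flagged as outliers; check the cuts.",
                   class = "cocktailr_degenerate_error")
  }
  diagnostics <- tibble::tibble(
    row = seq_len(n),
    rstudent = rs, dffits = df_,
    flagged = flagged,
    reason = dplyr::case_when(
      flag_r & flag_d ~ "rstudent+dffits",
      flag_r ~ "rstudent",
      flag_d ~ "dffits",
      .default = NA_character_
    )
  )
  kept <- as.data.frame(data)[!flagged, , drop = FALSE]
  screened <- fit_ols(kept, response, full$predictors)
  structure(
    list(full_fit = full, screened_fit = screened,
         diagnostics = diagnostics, excluded = which(flagged),
         resid_cut = resid_cut, dffits_cut = dffits_cut,
         dffits_rule = dffits_rule),
    class = "outlier_screen"
  )
}

#' @export
print.outlier_screen <- function(x, ...) {
  cat(sprintf("<outlier_screen> %d of %d observations excluded (|r*| > %.3g or |DFFITS| > %.3g)\n",
              length(x$excluded), x$full_fit$n, x$resid_cut, x$dffits_cut))
  if (length(x$excluded)) cat("  rows:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Maximum condition index of a design matrix
#'
#' Appends an intercept column (unless `add_intercept = FALSE`), scales
#' every column to unit Euclidean length, and returns the ratio of the
#' largest to the smallest singular value. Values of 30 or more are
#' conventionally taken to signal worrying collinearity.
#'
#' @param X Numeric matrix or data frame of predictors.
#' @param add_intercept Prepend a column of ones before scaling.
#' @return The maximum condition index (>= 1).
#' @export
condition_index <- function(X, add_intercept = TRUE) {
  m <- as.matrix(X)
  if (add_intercept) m <- cbind(`(Intercept)` = 1, m)
  len <- sqrt(colSums(m^2))
  if (any(len == 0)) {
    bad <- colnames(m)[len == 0]
    stop_cocktailr(sprintf("Zero column(s) in design: %s.",
                           paste(bad, collapse = ", ")),
                   class = "cocktailr_domain_error")
  }
  sv <- svd(sweep(m, 2, len, "/"), nu = 0, nv = 0)$d
  if (min(sv) < max(sv) * 1e-12) {
    stop_cocktailr("Design is (numerically) rank deficient; the condition index is unbounded.",
                   class = "cocktailr_rank_error")
  }
  max(sv) / min(sv)
}
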