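#' Dominance analysis: general dominance weights
#'
#' Quantifies each predictor's relative importance by the increase in
#' variance accounted for, Delta R^2, that it brings to every possible
#' subset model. For predictor j and subset S (not containing j),
#' Delta R^2(S, j) = R^2(S + j) - R^2(S). The general dominance weight
#' (GDW) is the two-stage average: the mean Delta R^2 within each subset
#' size s = 0 .. p-1, averaged across sizes with equal weight. Under this
#' averaging the GDWs sum exactly to the full model's R^2.
#'
#' Subset R^2 values are computed from the cross-product (correlation)
#' matrix, so the 2^p model fits cost one small solve each; enumeration is
#' refused for p > 15 with the count of required fits.
#'
#' @inheritParams fit_ols
#' @return An object of class `dominance_result`: a `weights` tibble
#'   (`term`, `gdw`, `rank`), `r.squared` (full model), and the
#'   `by_size` matrix of size-conditional mean contributions.
#' @export
#' @examples
#' d <- data.frame(y = rnorm(50), a = rnorm(50), b = rnorm(50))
#' d$y <- d$a + rnorm(50)
#' tidy(dominance_analysis(d, "y"))
dominance_analysis <- function(data, response, predictors = NULL) {
  data <- as.data.frame(data)
  if (is.null(predictors)) {
    predictors <- setdiff(
      names(data)[vapply(data, is.numeric, logical(1))],
      c(response, "subject_id")
    )
  }
  p <- length(predictors)
  if (p < 1L) stop_cocktailr("Need at least one predictor.")
  if (p > 15L) {
    stop_cocktailr(sprintf(
      "Refusing to enumerate %d predictors: dominance analysis needs 2^%d = %s subset fits.",
      p, p, format(2^p, big.mark = ",")
    ), class = "cocktailr_domain_error")
  }

  vars <- c(response, predictors)
  Rm <- cor(data[vars])
  if (anyNA(Rm)) stop_cocktailr("Correlations are undefined (constant column or missing values).")
  rxy <- Rm[-1L, 1L]
  Rxx <- Rm[-1L, -1L, drop = FALSE]

  n_sets <- 2L^p
  r2 <- numeric(n_sets)               # R^2 of each subset, bitmask-indexed
  members <- lapply(seq_len(n_sets) - 1L, function(mask) {
    which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
  })
  for (i in seq_len(n_sets)) {
    S <- members[[i]]
    r2[i] <- if (length(S) == 0L) 0 else {
      b <- solve(Rxx[S, S, drop = FALSE], rxy[S])
      drop(crossprod(rxy[S], b))
    }
  }

  by_size <- matrix(0, nrow = p, ncol = p,
                    dimnames = list(predictors, paste0("size", 0:(p - 1L))))
  counts <- matrix(0L, nrow = p, ncol = p)
  for (i in seq_len(n_sets)) {
    S <- members[[i]]
    s <- length(S)
    if (s == p) next
    mask <- i - 1L
    for (j in setdiff(seq_len(p), S)) {
      delta <- r2[1L + bitwOr(mask, bitwShiftL(1L, j - 1L))] - r2[i]
      by_size[j, s + 1L] <- by_size[j, s + 1L] + delta
      counts[j, s + 1L] <- counts[j, s + 1L] + 1L
    }
  }
  by_size <- by_size / counts
  gdw <- rowMeans(by_size)

  structure(
    list(
      weights = tibble::tibble(term = predictors, gdw = unname(gdw),
                               rank = rank(-gdw, ties.method = "min")),
      r.squared = r2[n_sets],
      by_size = by_size
    ),
    class = "dominance_result"
  )
}

#' @export
print.dominance_result <- function(x, ...) {
  cat(sprintf("<dominance_result> full-model R^2 = %.4f (sum of GDWs = %.4f)\n",
              x$r.squared, sum(x$weights$gdw)))
  print(x$weights[order(x$weights$rank), ])
  invisible(x)
}

#' @method tidy dominance_result
#' @export
tidy.dominance_result <- function(x, ...) x$weights

#' @method glance dominance_result
#' @export
glance.dominance_result <- function(x, ...) {
  tibble::tibble(r.squared = x$r.squared, gdw_total = sum(x$weights$gdw),
                 n_predictors = nrow(x$weights))
}

#' @describeIn dominance_analysis Bar chart of the general dominance
#'   weights.
#' @param object A `dominance_result`.
#' @param ... Unused.
#' @method autoplot dominance_result
#' @export
autoplot.dominance_result <- function(object, ...) {
  w <- object$weights
  ggplot2::ggplot(w, ggplot2::aes(x = stats::reorder(.data$term, .data$gdw),
                                  y = .data$gdw)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "General dominance weight",
                  title = sprintf("Relative importance (sum = R² = %.3f)",
                                  object$r.squared)) +
    ggplot2::theme_minimal()
}
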