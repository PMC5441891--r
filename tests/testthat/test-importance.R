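test_that("z-standardisation centres, scales, and is idempotent", {
  d <- data.frame(x = c(1, 2, 3), y = c(10, 30, 20))
  z <- zstandardize(d)
  expect_equal(z$x, c(-1, 0, 1))
  expect_equal(vapply(z, mean, numeric(1)), c(x = 0, y = 0), tolerance = 1e-12)
  expect_equal(vapply(z, sd, numeric(1)), c(x = 1, y = 1), tolerance = 1e-12)
  expect_equal(zstandardize(z)$x, z$x, tolerance = 1e-12)

  d$flat <- 5
  err <- expect_error(zstandardize(d), class = "cocktailr_domain_error")
  expect_match(conditionMessage(err), "flat")
})

test_that("OLS fits match the closed-form normal equations", {
  d <- data.frame(y = c(2.1, 3.9, 6.2, 7.8, 10.1),
                  x1 = 1:5, x2 = c(0.3, -0.1, 0.4, 0.2, -0.3))
  fit <- fit_ols(d, "y", c("x1", "x2"))
  X <- cbind(1, d$x1, d$x2)
  beta_hand <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(tidy(fit)$estimate, drop(beta_hand), tolerance = 1e-10)
  expect_equal(tidy(fit)$statistic, tidy(fit)$estimate / tidy(fit)$std.error,
               tolerance = 1e-12)

  # perfect linear response
  d$y <- 2 + 3 * d$x1
  perfect <- fit_ols(d, "y", c("x1", "x2"))
  expect_equal(suppressWarnings(glance(perfect)$r.squared), 1)
  expect_equal(max(abs(residuals(perfect))), 0, tolerance = 1e-10)
  # residual orthogonality to the design
  expect_lt(max(abs(crossprod(X, residuals(fit)))), 1e-9)

  d$dup <- d$x1 * 2
  err <- expect_error(fit_ols(d, "y", c("x1", "x2", "dup")),
                      class = "cocktailr_rank_error")
  expect_match(conditionMessage(err), "dup")
  expect_error(fit_ols(d[1:3, ], "y", c("x1", "x2")), "n > p")
})

test_that("null regressions behave like the reference chi-square heuristic", {
  set.seed(31)
  n <- 2000; p <- 9
  d <- as.data.frame(matrix(rnorm(n * (p + 1)), n))
  names(d) <- c("y", paste0("x", 1:p))
  fit <- fit_ols(d, "y")
  expect_lt(abs(glance(fit)$r.squared - p / (n - 1)), 0.012)
  expect_lt(max(abs(tidy(fit)$statistic)), 4)
})

test_that("the outlier screen flags planted outliers and uses the printed cut", {
  set.seed(32)
  d <- data.frame(x = rnorm(40))
  d$y <- d$x + rnorm(40, 0, 0.5)
  clean <- outlier_screen(d, "y", "x", resid_cut = 10, dffits_cut = 10)
  expect_length(clean$excluded, 0)
  expect_equal(tidy(clean$screened_fit)$estimate,
               tidy(clean$full_fit)$estimate)

  d$y[17] <- d$y[17] + 8
  scr <- outlier_screen(d, "y", "x")
  expect_true(17 %in% scr$excluded)
  expect_match(scr$diagnostics$reason[17], "rstudent")
  # leave-one-out oracle for the externally studentized residual
  loo <- lm(y ~ x, data = d[-17, ])
  pred <- predict(loo, d[17, ], se.fit = TRUE)
  r_oracle <- (d$y[17] - pred$fit) /
    sqrt(pred$residual.scale^2 + pred$se.fit^2)
  expect_equal(scr$diagnostics$rstudent[17], unname(r_oracle),
               tolerance = 1e-10)

  # printed DFFITS rule at the study's size: 2 * 9 / 50 = 0.36
  set.seed(33)
  d9 <- as.data.frame(matrix(rnorm(50 * 10), 50))
  names(d9) <- c("y", paste0("x", 1:9))
  scr9 <- outlier_screen(d9, "y")
  expect_equal(scr9$dffits_cut, 0.36)
  conv <- outlier_screen(d9, "y", dffits_rule = "conventional")
  expect_equal(conv$dffits_cut, 2 * sqrt(9 / 50))
})

test_that("studentized residuals and DFFITS are invariant to column scaling", {
  set.seed(34)
  d <- data.frame(x1 = rnorm(30), x2 = rnorm(30))
  d$y <- d$x1 - d$x2 + rnorm(30)
  a <- outlier_screen(d, "y", c("x1", "x2"))
  d2 <- dplyr::mutate(d, x1 = x1 * 1000, x2 = x2 / 50)
  b <- outlier_screen(d2, "y", c("x1", "x2"))
  expect_equal(a$diagnostics$rstudent, b$diagnostics$rstudent,
               tolerance = 1e-10)
  expect_equal(a$diagnostics$dffits, b$diagnostics$dffits, tolerance = 1e-10)
})

test_that("the condition index matches an eigenvalue oracle and its limits", {
  Q <- orthonormal_design(40, 5, seed = 35)
  expect_equal(condition_index(Q, add_intercept = FALSE), 1, tolerance = 1e-10)

  set.seed(36)
  X <- matrix(rnorm(500), 50, 10)
  ci <- condition_index(X)
  Xs <- cbind(1, X)
  Xs <- sweep(Xs, 2, sqrt(colSums(Xs^2)), "/")
  ev <- eigen(crossprod(Xs), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ci, sqrt(max(ev) / min(ev)), tolerance = 1e-10)

  expect_error(condition_index(cbind(X, X[, 1])),
               class = "cocktailr_rank_error")
  expect_error(condition_index(cbind(X, 0)), class = "cocktailr_domain_error")
})

test_that("dominance analysis reduces to squared correlations in easy cases", {
  set.seed(37)
  d1 <- data.frame(x = rnorm(60))
  d1$y <- 0.5 * d1$x + rnorm(60)
  dom1 <- dominance_analysis(d1, "y", "x")
  expect_equal(dom1$weights$gdw, cor(d1$x, d1$y)^2, tolerance = 1e-12)

  # exactly orthogonal predictors: GDW_j = r_j^2 with y
  Q <- orthonormal_design(80, 4, seed = 38)
  d <- as.data.frame(Q)
  d$y <- Q %*% c(2, -1, 0.5, 0) + rnorm(80, 0, 0.5)
  dom <- dominance_analysis(d, "y", colnames(Q))
  r2 <- as.vector(cor(Q, d$y))^2
  expect_equal(dom$weights$gdw, r2, tolerance = 1e-10)
  expect_equal(sum(dom$weights$gdw), dom$r.squared, tolerance = 1e-12)

  err <- expect_error(
    dominance_analysis(as.data.frame(matrix(rnorm(40 * 17), 40)), "V1"),
    class = "cocktailr_domain_error"
  )
  expect_match(conditionMessage(err), "65,536")
})

test_that("general dominance weights always sum to the full-model R^2", {
  set.seed(39)
  for (p in 1:8) {
    n <- 60
    d <- as.data.frame(matrix(rnorm(n * (p + 1)), n))
    names(d) <- c("y", paste0("x", 1:p))
    d$y <- d$y + rowSums(d[-1] * rep(runif(p, -1, 1), each = n))
    dom <- dominance_analysis(d, "y")
    full_r2 <- glance(fit_ols(d, "y"))$r.squared
    expect_equal(sum(dom$weights$gdw), full_r2, tolerance = 1e-10)
    expect_equal(dom$r.squared, full_r2, tolerance = 1e-10)
  }
})

test_that("the Lasso reduces to OLS at zero penalty and soft-thresholding when orthonormal", {
  set.seed(40)
  d <- data.frame(x1 = rnorm(50), x2 = rnorm(50), x3 = rnorm(50))
  d$y <- 1 + 0.8 * d$x1 - 0.5 * d$x2 + rnorm(50, 0, 0.4)
  ols <- tidy(fit_ols(d, "y", c("x1", "x2", "x3")))
  at0 <- lasso_fit(d, "y", c("x1", "x2", "x3"), lambda = 0)
  expect_equal(unname(at0$beta), ols$estimate[-1], tolerance = 1e-8)
  expect_equal(at0$intercept, ols$estimate[1], tolerance = 1e-8)

  # full-shrinkage threshold
  X <- as.matrix(d[c("x1", "x2", "x3")])
  lam_max <- max(abs(crossprod(sweep(X, 2, colMeans(X)),
                               d$y - mean(d$y)))) / nrow(d)
  shrunk <- lasso_fit(d, "y", c("x1", "x2", "x3"), lambda = lam_max * 1.0001)
  expect_equal(unname(shrunk$beta), c(0, 0, 0))
  expect_equal(shrunk$intercept, mean(d$y))

  # orthonormal design: exact soft-thresholding of the OLS solution
  n <- 64
  Q <- orthonormal_design(n, 4, seed = 41) * sqrt(n)   # X'X / n = I
  od <- as.data.frame(Q)
  set.seed(42)
  od$y <- Q %*% c(0.6, -0.3, 0.1, 0) + rnorm(n, 0, 0.3)
  beta_ols <- drop(crossprod(Q, od$y)) / n
  for (lam in c(0.05, 0.2, 0.5)) {
    fit <- lasso_fit(od, "y", colnames(Q), lambda = lam)
    expect_equal(unname(fit$beta),
                 unname(sign(beta_ols) * pmax(abs(beta_ols) - lam, 0)),
                 tolerance = 1e-10)
  }
})

test_that("the Lasso path is monotone and cross-validation selects a stable model", {
  set.seed(43)
  d <- data.frame(x1 = rnorm(60), x2 = rnorm(60), x3 = rnorm(60),
                  x4 = rnorm(60))
  d$y <- 2 * d$x1 - 1.5 * d$x2 + rnorm(60, 0, 0.5)
  cv <- lasso_cv(d, "y", paste0("x", 1:4), seed = 7)
  l1 <- colSums(abs(cv$path))
  expect_true(all(diff(l1) >= -1e-10))       # lambda decreasing -> l1 grows
  expect_true(all(cv$coefficients[c("x1", "x2")] != 0))
  expect_equal(sort(unique(cv$folds)), 1:4)
  expect_lte(max(table(cv$folds)), 15.5)      # approx equal fold sizes

  # reproducible under the recorded seed
  cv2 <- lasso_cv(d, "y", paste0("x", 1:4), seed = 7)
  expect_identical(cv$folds, cv2$folds)
  expect_equal(cv$lambda_min, cv2$lambda_min)
  expect_error(lasso_cv(d[1:3, ], "y", paste0("x", 1:4), k_folds = 5), "folds")
})

test_that("the coordinate-descent Lasso agrees with glmnet on a shared grid", {
  skip_if_not_installed("glmnet")
  set.seed(44)
  n <- 80
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n))
  d$y <- 1 + 1.2 * d$x1 - 0.7 * d$x3 + rnorm(n, 0, 0.6)
  X <- as.matrix(d[paste0("x", 1:4)])
  lams <- c(0.4, 0.2, 0.1, 0.05, 0.01)
  g <- glmnet::glmnet(X, d$y, lambda = lams, standardize = FALSE,
                      thresh = 1e-14)
  for (lam in lams) {
    ours <- lasso_fit(d, "y", paste0("x", 1:4), lambda = lam)
    theirs <- as.vector(glmnet::coef.glmnet(g, s = lam, exact = TRUE,
                                            x = X, y = d$y))
    expect_equal(c(ours$intercept, unname(ours$beta)), theirs,
                 tolerance = 1e-6)
  }
})

test_that("partial correlations match the closed form and their edge cases", {
  set.seed(45)
  d <- data.frame(x = rnorm(40), z = rnorm(40))
  d$y <- 0.6 * d$x + 0.4 * d$z + rnorm(40, 0.5)
  res <- partial_correlation(d, "x", "y", "z")
  r <- cor(d)
  closed <- (r["x", "y"] - r["x", "z"] * r["z", "y"]) /
    sqrt((1 - r["x", "z"]^2) * (1 - r["z", "y"]^2))
  expect_equal(res$estimate, closed, tolerance = 1e-12)
  t_closed <- closed * sqrt((40 - 3) / (1 - closed^2))
  expect_equal(res$p.value, 2 * pt(-abs(t_closed), 37), tolerance = 1e-12)

  # control exactly uncorrelated with both: equals the plain Pearson r
  d$c0 <- residuals(lm(z ~ x + y, data = d))
  expect_equal(partial_correlation(d, "x", "y", "c0")$estimate,
               cor(d$x, d$y), tolerance = 1e-12)

  d$y2 <- d$x
  expect_equal(partial_correlation(d, "x", "y2", "z")$estimate, 1,
               tolerance = 1e-12)
  expect_error(partial_correlation(d, "z", "y", "z"),
               class = "cocktailr_degenerate_error")

  pm <- partial_correlation_matrix(d, c("x", "y"), "z")
  expect_equal(nrow(pm), 3L)  # one pair + two age-style control rows
})

test_that("power analysis reproduces its reference points and monotonicity", {
  expect_identical(min_sample_size(), 47L)
  expect_gte(regression_coef_power(50), 0.8)
  expect_lt(regression_coef_power(46), 0.8)

  sizes <- vapply(c(0.05, 0.10, 0.15, 0.25, 0.4), function(pr2) {
    min_sample_size(partial_r2 = pr2)
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))

  powers <- vapply(seq(20, 120, 10), regression_coef_power, numeric(1))
  expect_true(all(diff(powers) > 0))
  expect_error(regression_coef_power(10), "degrees of freedom")
  expect_error(min_sample_size(power = 0.999999, partial_r2 = 1e-6, n_max = 500),
               class = "cocktailr_domain_error")
})

test_that("computed power matches a Monte-Carlo regression experiment", {
  # fixed 9-predictor design; the tested coefficient is calibrated so the
  # noncentrality is exactly sqrt(f2 * N); 10,000 simulated t tests
  set.seed(46)
  N <- 47; p <- 9; pr2 <- 0.15
  f2 <- pr2 / (1 - pr2)
  X <- matrix(rnorm(N * p), N)
  M <- cbind(1, X)
  qrM <- qr(M[, -2])
  x1_res <- qr.resid(qrM, M[, 2])          # x1 partialled for the others
  ssr <- sum(x1_res^2)
  b1 <- sqrt(f2 * N) / sqrt(ssr)           # noncentrality = sqrt(f2 * N)
  reps <- 10000
  E <- matrix(rnorm(N * reps), N)
  Y <- b1 * M[, 2] + E
  # t statistic for beta1 via the partialled-out representation
  qr_full <- qr(M)
  bhat1 <- crossprod(x1_res, Y) / ssr
  rss <- colSums(qr.resid(qr_full, Y)^2)
  se1 <- sqrt(rss / (N - p - 1) / ssr)
  tstat <- drop(bhat1) / se1
  reject <- mean(abs(tstat) > qt(0.975, N - p - 1))
  expect_equal(reject, regression_coef_power(N, pr2, p), tolerance = 0.011)
})
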