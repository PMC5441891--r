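#' Default predictor set for the speech-identification regression
#'
#' The nine predictors of the transformed speech recognition score: age,
#' the masker-induced DL elevation, flanker interference, the
#' interaural-phase threshold, better-ear pure-tone average, interaural
#' asymmetry, the quiet DL, neutral-condition log RT, and the span score.
#'
#' @return Character vector of length 9.
#' @export
default_predictors <- function() {
  c("Age", "DL_elev", "Int_Flanker", "TFS_th", "PTA_BE", "HL_diff",
    "DL_quiet", "RT_neutral", "SS_Pcorr")
}

#' Inferential analysis of a scored cohort
#'
#' Runs the full inferential battery on a subject-by-measure score table:
#' z-standardises criterion and predictors, screens outliers (externally
#' studentized residuals against 1.96 and |DFFITS| against 2p/N), refits
#' the OLS model on the retained subjects, computes the maximum condition
#' index of the screened design, the general dominance weights, the Lasso
#' with k-fold cross-validation on the screened (standardised) data, and
#' the pairwise partial correlations controlling for age on all subjects.
#'
#' @param scores Score tibble from [score_cohort()] (or same shape).
#' @param criterion Criterion column (default "SRS").
#' @param predictors Predictor columns (default [default_predictors()]).
#' @param control Covariate partialled out of the pairwise correlations
#'   (default "Age").
#' @param k_folds Cross-validation folds for the Lasso.
#' @param lasso_seed Seed for the CV fold assignment.
#' @param counting_rule,resid_cut,dffits_rule Passed through to the screen.
#' @return An object of class `cocktail_analysis` with elements `screen`
#'   ([outlier_screen()]), `ols` (screened `ols_fit`), `dominance`,
#'   `lasso`, `partials`, `condition_index`, and bookkeeping fields.
#' @export
analyze_scores <- function(scores, criterion = "SRS",
                           predictors = default_predictors(),
                           control = "Age", k_folds = 4L, lasso_seed = 1L,
                           resid_cut = 1.96,
                           dffits_rule = c("printed", "conventional")) {
  dffits_rule <- match.arg(dffits_rule)
  scores <- tibble::as_tibble(scores)
  missing <- setdiff(c(criterion, predictors), names(scores))
  if (length(missing)) {
    stop_cocktailr(sprintf("Score table lacks column(s): %s.",
                           paste(missing, collapse = ", ")))
  }
  complete <- stats::complete.cases(scores[c(criterion, predictors)])
  n_incomplete <- sum(!complete)
  if (n_incomplete > 0L) {
    # subjects losing every track of a task (exclusion rules) lack that
    # measure; listwise deletion, with the count reported
    scores <- scores[complete, , drop = FALSE]
  }
  if (nrow(scores) < length(predictors) + 2L) {
    stop_cocktailr("Too few complete subjects for the regression analysis.",
                   class = "cocktailr_degenerate_error")
  }

  z <- zstandardize(scores, cols = c(criterion, predictors))
  screen <- outlier_screen(z, criterion, predictors,
                           resid_cut = resid_cut, dffits_rule = dffits_rule)
  kept <- z[-screen$excluded, , drop = FALSE]
  if (length(screen$excluded) == 0L) kept <- z

  # Re-standardise on the retained subjects so the reported coefficients
  # are in SD units of the analysed sample.
  kept_z <- zstandardize(kept, cols = c(criterion, predictors))
  ols <- fit_ols(kept_z, criterion, predictors)
  dom <- dominance_analysis(kept_z, criterion, predictors)
  las <- lasso_cv(kept_z, criterion, predictors, k_folds = k_folds,
                  seed = lasso_seed)
  ci <- condition_index(as.matrix(kept_z[predictors]))

  pvars <- c(criterion, setdiff(predictors, control),
             intersect(c("SSQ_speech", "SSQ_spatial", "SSQ_qualities"),
                       names(scores)))
  partials <- partial_correlation_matrix(scores, pvars, control)

  structure(
    list(
      screen = screen, ols = ols, dominance = dom, lasso = las,
      partials = partials, condition_index = ci,
      criterion = criterion, predictors = predictors, control = control,
      n_total = nrow(scores), n_analyzed = nrow(kept),
      n_incomplete = n_incomplete
    ),
    class = "cocktail_analysis"
  )
}

#' @export
print.cocktail_analysis <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

#' Run the complete simulation-and-analysis pipeline
#'
#' simulate -> score -> reliability -> analyze, with one master seed
#' expanded into per-stage substreams. Optionally writes `cohort.csv`,
#' `trials.csv`, `tracks.csv`, `scores.csv`, `reliability.csv` and
#' `report.json` into `out_dir`.
#'
#' @param config A [cohort_config()].
#' @param seed Master seed (defaults to `config$seed`).
#' @param out_dir Optional output directory (created if needed).
#' @param counting_rule Counting rule for the intensity DL estimator.
#' @return An object of class `cocktail_run`: `sim`, `scores`,
#'   `block_scores`, `reliability`, `analysis`, and a `manifest` tibble of
#'   stage seeds and sizes.
#' @export
#' @examples
#' \donttest{
#' run <- run_pipeline(cohort_config(n_subjects = 30), seed = 11)
#' run$analysis$ols
#' }
run_pipeline <- function(config = cohort_config(), seed = config$seed,
                         out_dir = NULL,
                         counting_rule = c("as_printed", "even_count")) {
  counting_rule <- match.arg(counting_rule)
  if (is.null(seed)) {
    stop_cocktailr("Supply a `seed` (or set it in the config).",
                   class = "cocktailr_config_error")
  }
  sim <- simulate_cohort(config, seed = seed)
  scores <- score_cohort(sim, counting_rule = counting_rule)
  block_scores <- score_blocks(sim, counting_rule = counting_rule)
  reliability <- reliability_report(block_scores)
  analysis <- analyze_scores(scores,
                             lasso_seed = substream_seed(seed, 0L, 99L))

  manifest <- tibble::tibble(
    stage = c("simulate", "score", "reliability", "analyze"),
    seed = c(seed, NA_integer_, NA_integer_, substream_seed(seed, 0L, 99L)),
    rows = c(nrow(sim$trials), nrow(scores), nrow(reliability),
             analysis$n_analyzed)
  )
  run <- structure(
    list(sim = sim, scores = scores, block_scores = block_scores,
         reliability = reliability, analysis = analysis,
         manifest = manifest, config = config, seed = seed),
    class = "cocktail_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.cocktail_run <- function(x, ...) {
  cat(sprintf("<cocktail_run> seed %s, %d subjects (%d analysed)\n",
              format(x$seed), nrow(x$scores), x$analysis$n_analyzed))
  cat(render_report(x$analysis), sep = "\n")
  invisible(x)
}

#' Write the pipeline outputs to disk
#'
#' CSV tables (UTF-8, '.' decimal separator, header row) for the cohort,
#' trials, track summaries, subject scores and reliability, plus a JSON
#' report of the inferential results at full precision.
#'
#' @param run A `cocktail_run`.
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_run <- function(run, out_dir) {
  stopifnot(inherits(run, "cocktail_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    cohort = file.path(out_dir, "cohort.csv"),
    trials = file.path(out_dir, "trials.csv"),
    tracks = file.path(out_dir, "tracks.csv"),
    scores = file.path(out_dir, "scores.csv"),
    reliability = file.path(out_dir, "reliability.csv"),
    report = file.path(out_dir, "report.json")
  )
  write.csv(run$sim$cohort, paths["cohort"], row.names = FALSE)
  write.csv(run$sim$trials, paths["trials"], row.names = FALSE)
  tracks_flat <- run$sim$tracks[setdiff(names(run$sim$tracks), "track")]
  write.csv(tracks_flat, paths["tracks"], row.names = FALSE)
  write.csv(run$scores, paths["scores"], row.names = FALSE)
  write.csv(run$reliability, paths["reliability"], row.names = FALSE)

  a <- run$analysis
  report <- list(
    criterion = a$criterion,
    predictors = a$predictors,
    n_total = a$n_total,
    n_analyzed = a$n_analyzed,
    excluded_rows = a$screen$excluded,
    resid_cut = a$screen$resid_cut,
    dffits_cut = a$screen$dffits_cut,
    condition_index = a$condition_index,
    ols = tidy(a$ols),
    r_squared = glance(a$ols)$r.squared,
    dominance = tidy(a$dominance),
    lasso = tidy(a$lasso),
    lasso_lambda = a$lasso$lambda_min,
    lasso_folds = a$lasso$folds,
    partial_correlations = a$partials,
    reliability = run$reliability,
    seed = run$seed
  )
  jsonlite::write_json(report, paths["report"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns")
  invisible(paths)
}

#' Render a human-readable analysis summary
#'
#' Tabulates the regression coefficients (beta, SE, t, p), general
#' dominance weights and Lasso coefficients in one table, followed by the
#' screening summary and the partial-correlation table.
#'
#' @param analysis A `cocktail_analysis` (or a `cocktail_run`).
#' @return A character vector of markdown lines.
#' @export
render_report <- function(analysis) {
  if (inherits(analysis, "cocktail_run")) analysis <- analysis$analysis
  if (!inherits(analysis, "cocktail_analysis")) {
    stop_cocktailr("`render_report()` expects a cocktail_analysis or cocktail_run.")
  }
  a <- analysis
  co <- tidy(a$ols)
  dom <- tidy(a$dominance)
  las <- tidy(a$lasso)
  tab <- co |>
    dplyr::left_join(dom, by = "term") |>
    dplyr::left_join(dplyr::select(las, "term", lasso = "estimate"),
                     by = "term")
  g <- glance(a$ols)
  lines <- c(
    sprintf("## Regression of %s on %d predictors (n = %d of %d)",
            a$criterion, length(a$predictors), a$n_analyzed, a$n_total),
    "",
    "| Predictor | beta | SE | t | p | GDW | beta_Lasso |",
    "|---|---|---|---|---|---|---|",
    sprintf("| %s | %.3f | %.3f | %.2f | %.3f | %s | %s |",
            tab$term, tab$estimate, tab$std.error, tab$statistic,
            tab$p.value,
            ifelse(is.na(tab$gdw), "", sprintf("%.3f", tab$gdw)),
            ifelse(is.na(tab$lasso) | tab$lasso == 0, "-",
                   sprintf("%.3f", tab$lasso))),
    "",
    sprintf("R^2 = %.3f (p = %.3g); sum of GDWs = %.3f%s",
            g$r.squared, g$p.value, sum(dom$gdw),
            if (abs(sum(dom$gdw) - g$r.squared) < 1e-8)
              " (equals R^2, as it must)" else ""),
    sprintf("%d subject(s) excluded by the outlier screen (|r*| > %.3g, |DFFITS| > %.3g)",
            length(a$screen$excluded), a$screen$resid_cut, a$screen$dffits_cut),
    sprintf("Maximum condition index: %.2f", a$condition_index),
    "",
    sprintf("## Partial correlations controlling for %s (n = %d)",
            a$control, a$n_total),
    "",
    "| x | y | rho | p |",
    "|---|---|---|---|",
    sprintf("| %s | %s | %.3f | %.3f |",
            a$partials$x, a$partials$y, a$partials$estimate,
            a$partials$p.value)
  )
  lines
}
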