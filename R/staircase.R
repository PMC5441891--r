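#' Specification of a transformed up-down adaptive staircase
#'
#' Encodes the 3-down-1-up rule used for the intensity-discrimination and
#' interaural-phase tasks: the level moves down one step after three
#' consecutive correct responses (counter reset on every level change and on
#' errors) and up one step after any error. Steps are additive in dB for the
#' intensity task (5 dB until the step change, then 2 dB) and multiplicative
#' for the phase task (factor 1.25^2, then 1.25). The track ends when
#' `total_reversals` reversals have been collected, or at `trial_cap`
#' trials, whichever comes first.
#'
#' Presets follow the three tasks: intensity in quiet (start 8 dB, step
#' change after the 3rd reversal, 9 reversals), intensity under backward
#' masking (step change after the 4th reversal, 12 reversals), and the
#' interaural-phase task (start 180 degrees, multiplicative steps, step
#' change after the 3rd reversal, 9 reversals or 70 trials, levels clamped
#' to 180 degrees). The intensity tasks have no printed trial cap; a safety
#' cap (default 200) prevents non-termination with pathological responders
#' and flags the track rather than silently truncating it.
#'
#' @param task Preset name: "intensity_quiet", "intensity_masked" or "tfs";
#'   individual fields can be overridden.
#' @param rule_down Number of consecutive correct responses required for a
#'   downward step (3).
#' @param step_mode "additive" (dB) or "multiplicative" (factor).
#' @param initial_level Starting level (dB or degrees).
#' @param large_step,small_step Step sizes before/after the step change
#'   (additive: dB > 0; multiplicative: factors > 1).
#' @param step_change_after_reversal Reversal count after which the small
#'   step applies (the move away from that reversal already uses it).
#' @param total_reversals Reversals collected before the track terminates.
#' @param trial_cap Maximum number of trials.
#' @param level_max Upper clamp on the level (180 degrees for the phase
#'   task, `Inf` otherwise).
#' @return An object of class `staircase_spec`.
#' @export
#' @examples
#' staircase_spec("tfs")
staircase_spec <- function(task = c("intensity_quiet", "intensity_masked", "tfs"),
                           rule_down = 3L,
                           step_mode = NULL,
                           initial_level = NULL,
                           large_step = NULL,
                           small_step = NULL,
                           step_change_after_reversal = NULL,
                           total_reversals = NULL,
                           trial_cap = NULL,
                           level_max = NULL) {
  task <- match.arg(task)
  preset <- switch(task,
    intensity_quiet = list(step_mode = "additive", initial_level = 8,
                           large_step = 5, small_step = 2,
                           step_change_after_reversal = 3L,
                           total_reversals = 9L, trial_cap = 200L,
                           level_max = Inf),
    intensity_masked = list(step_mode = "additive", initial_level = 8,
                            large_step = 5, small_step = 2,
                            step_change_after_reversal = 4L,
                            total_reversals = 12L, trial_cap = 200L,
                            level_max = Inf),
    tfs = list(step_mode = "multiplicative", initial_level = 180,
               large_step = 1.25^2, small_step = 1.25,
               step_change_after_reversal = 3L,
               total_reversals = 9L, trial_cap = 70L, level_max = 180)
  )
  override <- list(step_mode = step_mode, initial_level = initial_level,
                   large_step = large_step, small_step = small_step,
                   step_change_after_reversal = step_change_after_reversal,
                   total_reversals = total_reversals, trial_cap = trial_cap,
                   level_max = level_max)
  for (nm in names(override)) {
    if (!is.null(override[[nm]])) preset[[nm]] <- override[[nm]]
  }
  spec <- c(list(task = task, rule_down = as.integer(rule_down)), preset)

  min_step <- if (spec$step_mode == "multiplicative") 1 else 0
  if (spec$large_step <= min_step || spec$small_step <= min_step) {
    stop_cocktailr(sprintf(
      "Steps must be %s.", if (min_step == 1) "factors > 1" else "> 0"
    ), class = "cocktailr_config_error")
  }
  if (spec$total_reversals <= spec$step_change_after_reversal) {
    stop_cocktailr("`total_reversals` must exceed `step_change_after_reversal`.",
                   class = "cocktailr_config_error")
  }
  structure(spec, class = "staircase_spec")
}

#' @export
print.staircase_spec <- function(x, ...) {
  cat(sprintf("<staircase_spec: %s> %d-down-1-up, %s steps %g/%g, start %g, %d reversals (step change after %d), cap %d trials\n",
              x$task, x$rule_down, x$step_mode, x$large_step, x$small_step,
              x$initial_level, x$total_reversals,
              x$step_change_after_reversal, x$trial_cap))
  invisible(x)
}

#' Run one adaptive track
#'
#' Presents the staircase defined by `spec` to a responder function (stimulus
#' level in, logical correct out). A reversal is a trial at which the
#' direction of level change flips; the first movement defines the initial
#' direction. The reversal level is the level presented on the trial at
#' which the flip occurred. A track is valid when it terminated by reaching
#' `total_reversals`; tracks stopped by the trial cap are flagged, never
#' silently dropped.
#'
#' @param spec A [staircase_spec()].
#' @param responder A function `(level) -> logical(1)`, e.g. from
#'   [make_responder()].
#' @param seed Optional integer seed making the run reproducible.
#' @return An object of class `adaptive_track`: the spec, a `trials` tibble
#'   (`trial`, `level`, `correct`), a `reversals` tibble (`reversal`,
#'   `trial`, `level`), `terminated_by` ("reversals" or "trial_cap"),
#'   `valid`, and `reason`.
#' @export
#' @examples
#' step_responder <- function(level) level >= 0
#' tr <- run_track(staircase_spec("intensity_quiet"), step_responder)
#' tr$reversals
run_track <- function(spec, responder, seed = NULL) {
  stopifnot(inherits(spec, "staircase_spec"))
  if (!is.function(responder)) stop_cocktailr("`responder` must be a function.")
  if (!is.null(seed)) set.seed(seed)

  cap <- spec$trial_cap
  levels <- numeric(cap)
  corrects <- logical(cap)
  rev_trial <- integer(spec$total_reversals)
  rev_level <- numeric(spec$total_reversals)
  n_rev <- 0L
  level <- spec$initial_level
  direction <- 0L        # -1 descending, +1 ascending, 0 before first move
  n_correct <- 0L
  trial <- 0L

  while (n_rev < spec$total_reversals && trial < cap) {
    trial <- trial + 1L
    resp <- responder(level)
    if (!is.logical(resp) || length(resp) != 1L || is.na(resp)) {
      stop_cocktailr("Responder must return a single TRUE/FALSE.",
                     class = "cocktailr_contract_error")
    }
    levels[trial] <- level
    corrects[trial] <- resp

    move <- 0L
    if (resp) {
      n_correct <- n_correct + 1L
      if (n_correct == spec$rule_down) {
        move <- -1L
        n_correct <- 0L
      }
    } else {
      move <- 1L
      n_correct <- 0L
    }

    if (move != 0L) {
      if (direction != 0L && move != direction) {
        n_rev <- n_rev + 1L
        rev_trial[n_rev] <- trial
        rev_level[n_rev] <- level
      }
      direction <- move
      step <- if (n_rev < spec$step_change_after_reversal) spec$large_step
              else spec$small_step
      level <- if (spec$step_mode == "additive") level + move * step
               else { if (move < 0L) level / step else level * step }
      level <- min(level, spec$level_max)
    }
  }

  terminated_by <- if (n_rev >= spec$total_reversals) "reversals" else "trial_cap"
  ti <- seq_len(trial)
  ri <- seq_len(n_rev)
  structure(
    list(
      spec = spec,
      trials = tibble::new_tibble(list(trial = ti,
                                       level = levels[ti],
                                       correct = corrects[ti]),
                                  nrow = trial),
      reversals = tibble::new_tibble(list(reversal = ri,
                                          trial = rev_trial[ri],
                                          level = rev_level[ri]),
                                     nrow = n_rev),
      terminated_by = terminated_by,
      valid = terminated_by == "reversals" || spec$task == "tfs",
      reason = if (terminated_by == "reversals") NA_character_
               else sprintf("trial cap (%d) reached with %d reversals", cap, n_rev)
    ),
    class = "adaptive_track"
  )
}

#' @export
print.adaptive_track <- function(x, ...) {
  cat(sprintf("<adaptive_track: %s> %d trials, %d reversals, terminated by %s%s\n",
              x$spec$task, nrow(x$trials), nrow(x$reversals), x$terminated_by,
              if (isTRUE(x$valid)) "" else " [INVALID]"))
  invisible(x)
}

counting_reversal_indices <- function(track, condition, counting_rule) {
  n <- nrow(track$reversals)
  start <- if (condition == "quiet") 4L else 5L
  end <- if (counting_rule == "as_printed") 2L * (n %/% 2L) else n
  if (counting_rule == "even_count" && (end - start + 1L) %% 2L == 1L) {
    # extend to the track's final reversal so peaks and valleys balance
    end <- n
  }
  if (end < start) {
    stop_cocktailr(sprintf(
      "Track has too few reversals (%d) for the %s-condition estimator.", n, condition
    ), class = "cocktailr_track_error")
  }
  seq.int(start, end)
}

#' Estimate the intensity difference limen from an adaptive track
#'
#' Arithmetic mean of the track levels (10*log10(dI/I), dB) at the counting
#' reversals: from the fourth (quiet) or fifth (masked) reversal up to the
#' last even-numbered reversal (`counting_rule = "as_printed"`, the
#' default). For the quiet preset (9 reversals) the printed rule spans an
#' odd number of reversals (4-8); `counting_rule = "even_count"` instead
#' extends to the final reversal so that rising and falling reversals
#' balance.
#'
#' @param track An `adaptive_track` from [run_track()].
#' @param condition "quiet" or "masked".
#' @param counting_rule "as_printed" or "even_count".
#' @return A list: `estimate` (dB), `reversals_used` (indices), `levels`.
#' @export
#' @examples
#' # hand-checkable: reversals 4-8 of a 9-reversal quiet track
#' tr <- list(spec = staircase_spec("intensity_quiet"),
#'            reversals = tibble::tibble(reversal = 1:9,
#'              trial = 1:9, level = c(10, 5, 8, 4, 6, 4, 6, 4, 6)),
#'            terminated_by = "reversals", valid = TRUE)
#' class(tr) <- "adaptive_track"
#' estimate_intensity_dl(tr, "quiet")$estimate  # mean(c(4,6,4,6,4)) = 4.8
estimate_intensity_dl <- function(track, condition = c("quiet", "masked"),
                                  counting_rule = c("as_printed", "even_count")) {
  stopifnot(inherits(track, "adaptive_track"))
  condition <- match.arg(condition)
  counting_rule <- match.arg(counting_rule)
  if (!isTRUE(track$valid) || track$terminated_by != "reversals") {
    stop_cocktailr("Intensity DLs are only estimated from tracks that terminated by reversals.",
                   class = "cocktailr_track_error")
  }
  idx <- counting_reversal_indices(track, condition, counting_rule)
  lv <- track$reversals$level[idx]
  list(estimate = mean(lv), reversals_used = idx, levels = lv)
}

#' Estimate the interaural-phase threshold from an adaptive track
#'
#' Geometric mean of the interaural phase difference (degrees) at the last
#' six reversals.
#'
#' @param track An `adaptive_track` from [run_track()].
#' @return A list: `estimate` (degrees), `reversals_used`, `levels`.
#' @export
estimate_tfs_threshold <- function(track) {
  stopifnot(inherits(track, "adaptive_track"))
  n <- nrow(track$reversals)
  if (n < 6L) {
    stop_cocktailr(sprintf("Need at least 6 reversals for the phase threshold; track has %d.", n),
                   class = "cocktailr_track_error")
  }
  idx <- seq.int(n - 5L, n)
  lv <- track$reversals$level[idx]
  list(estimate = exp(mean(log(lv))), reversals_used = idx, levels = lv)
}

#' Apply the track-exclusion rules
#'
#' Intensity tracks are excluded when the sample SD of 10*log10(dI/I) at the
#' counting reversals exceeds 7 dB. Interaural-phase tracks are excluded
#' when the SD of the log10-transformed phase at the counting reversals
#' (the last six) exceeds 0.3, or when fewer than 4 reversals were
#' collected. The SD is always computed over the same reversal set the
#' estimators use.
#'
#' @param track An `adaptive_track`.
#' @param condition "quiet", "masked" or "tfs".
#' @param counting_rule Passed to the intensity estimator.
#' @return A list: `excluded` (logical) and machine-readable `reason`
#'   (`NA` when retained).
#' @export
track_is_excluded <- function(track,
                              condition = c("quiet", "masked", "tfs"),
                              counting_rule = c("as_printed", "even_count")) {
  stopifnot(inherits(track, "adaptive_track"))
  condition <- match.arg(condition)
  counting_rule <- match.arg(counting_rule)
  n <- nrow(track$reversals)

  if (condition == "tfs") {
    if (n < 4L) {
      return(list(excluded = TRUE,
                  reason = sprintf("fewer than 4 reversals (%d)", n)))
    }
    if (n < 6L) {
      return(list(excluded = TRUE,
                  reason = sprintf("too few reversals for the threshold estimate (%d)", n)))
    }
    lv <- track$reversals$level[seq.int(n - 5L, n)]
    s <- sd(log10(lv))
    if (s > 0.3) {
      return(list(excluded = TRUE,
                  reason = sprintf("SD of log10 phase at counting reversals %.3f > 0.3", s)))
    }
    return(list(excluded = FALSE, reason = NA_character_))
  }

  if (!isTRUE(track$valid) || track$terminated_by != "reversals") {
    return(list(excluded = TRUE, reason = track$reason))
  }
  idx <- counting_reversal_indices(track, condition, counting_rule)
  s <- sd(track$reversals$level[idx])
  if (s > 7) {
    return(list(excluded = TRUE,
                reason = sprintf("SD at counting reversals %.2f dB > 7 dB", s)))
  }
  list(excluded = FALSE, reason = NA_character_)
}

#' Replay a track's responses through its spec
#'
#' Deterministically re-derives the level sequence from the recorded
#' correct/incorrect responses. Used to audit that a stored track obeys its
#' step schedule exactly.
#'
#' @param track An `adaptive_track`.
#' @return Numeric vector of levels, one per trial.
#' @export
replay_track <- function(track) {
  stopifnot(inherits(track, "adaptive_track"))
  responses <- track$trials$correct
  i <- 0L
  replayed <- run_track(track$spec, function(level) {
    i <<- i + 1L
    responses[i]
  })
  replayed$trials$level
}

#' @describeIn run_track Plot the level trace of a track with its reversals
#'   marked.
#' @param object An `adaptive_track`.
#' @param ... Unused.
#' @method autoplot adaptive_track
#' @export
autoplot.adaptive_track <- function(object, ...) {
  ggplot2::ggplot(object$trials, ggplot2::aes(x = .data$trial, y = .data$level)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$correct)) +
    ggplot2::geom_point(data = object$reversals, colour = "red", size = 3,
                        shape = 1) +
    ggplot2::labs(
      x = "Trial",
      y = if (object$spec$step_mode == "additive") "Level (dB)" else "Level (deg)",
      shape = "Correct",
      title = sprintf("%s track (%s)", object$spec$task, object$terminated_by)
    ) +
    ggplot2::theme_minimal()
}

#' Summarise adaptive tracks into one row per track
#'
#' @param tracks A list of `adaptive_track` objects.
#' @param subject_id,task,block Vectors parallel to `tracks` (recycled if
#'   length 1) identifying each track.
#' @param counting_rule Counting rule for the intensity estimators.
#' @return A tibble: identifiers, `threshold`, `n_reversals`,
#'   `terminated_by`, `excluded`, `reason`.
#' @export
summarise_tracks <- function(tracks, subject_id, task, block,
                             counting_rule = c("as_printed", "even_count")) {
  counting_rule <- match.arg(counting_rule)
  n <- length(tracks)
  subject_id <- rep_len(subject_id, n)
  task <- rep_len(task, n)
  block <- rep_len(block, n)
  threshold <- rep(NA_real_, n)
  n_reversals <- integer(n)
  terminated_by <- character(n)
  excluded <- logical(n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    tr <- tracks[[i]]
    cond <- switch(task[i],
                   intensity_quiet = "quiet",
                   intensity_masked = "masked",
                   tfs = "tfs")
    excl <- track_is_excluded(tr, cond, counting_rule)
    if (!excl$excluded) {
      threshold[i] <- if (cond == "tfs") estimate_tfs_threshold(tr)$estimate
                      else estimate_intensity_dl(tr, cond, counting_rule)$estimate
    }
    n_reversals[i] <- nrow(tr$reversals)
    terminated_by[i] <- tr$terminated_by
    excluded[i] <- excl$excluded
    reason[i] <- excl$reason
  }
  tibble::new_tibble(list(
    subject_id = subject_id, task = task, block = block,
    threshold = threshold, n_reversals = n_reversals,
    terminated_by = terminated_by, excluded = excluded, reason = reason
  ), nrow = n)
}
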