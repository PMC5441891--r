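#' Simulate the full test battery for a cohort
#'
#' Generates the latent cohort, then simulates every task for every subject:
#' the three-block sentence task, the adaptive intensity tracks (2 in quiet,
#' 3 under backward masking), the two interaural-phase tracks, the
#' three-block flanker task, the ten span lists, the SSQ ratings and the
#' audiograms. Each (subject, task) pair draws from its own seed substream
#' derived from the master seed, so adding subjects never perturbs the data
#' of existing ones.
#'
#' @param config A [cohort_config()].
#' @param seed Master integer seed (defaults to `config$seed`).
#' @param keep_tracks Keep the full `adaptive_track` objects in a
#'   list-column of the `tracks` table (default TRUE).
#' @return An object of class `cohort_sim`: a list with tibbles `cohort`
#'   (latent truths), `trials` (long trial table for sentence, flanker and
#'   span), `tracks` (one row per adaptive track, with the track objects in
#'   `track` when kept), `audiograms` and `ssq`, plus the `config` and
#'   `seed`.
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_config(n_subjects = 2), seed = 7)
#' dplyr::count(sim$trials, task)
simulate_cohort <- function(config = cohort_config(), seed = config$seed,
                            keep_tracks = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(seed)) {
    stop_cocktailr("Supply a `seed` (or set it in the config).",
                   class = "cocktailr_config_error")
  }
  cohort <- generate_cohort(config, seed = seed)
  td <- config$task_design

  track_plan <- dplyr::bind_rows(
    tibble::tibble(task = "intensity_quiet", block = seq_len(td$dl_quiet_blocks)),
    tibble::tibble(task = "intensity_masked", block = seq_len(td$dl_masked_blocks)),
    tibble::tibble(task = "tfs", block = seq_len(td$tfs_blocks))
  )

  per_subject <- purrr::map(seq_len(nrow(cohort)), function(i) {
    listener <- cohort[i, ]
    sid <- listener$subject_id
    sentence <- simulate_sentence_task(listener, config,
                                       seed = substream_seed(seed, sid, 2L))
    flanker <- simulate_flanker(listener, config,
                                seed = substream_seed(seed, sid, 3L))
    span <- simulate_span_task(listener, config,
                               seed = substream_seed(seed, sid, 4L))
    ssq <- simulate_ssq(listener, config,
                        seed = substream_seed(seed, sid, 5L))
    tracks <- purrr::map(seq_len(nrow(track_plan)), function(j) {
      responder <- make_responder(listener, track_plan$task[j], config)
      run_track(staircase_spec(track_plan$task[j]), responder,
                seed = substream_seed(seed, sid, 10L + j))
    })
    list(sentence = sentence, flanker = flanker, span = span, ssq = ssq,
         tracks = tracks)
  })

  trials <- dplyr::bind_rows(
    purrr::map_dfr(per_subject, "sentence"),
    purrr::map_dfr(per_subject, "flanker"),
    purrr::map_dfr(per_subject, "span")
  )
  all_tracks <- purrr::flatten(purrr::map(per_subject, "tracks"))
  track_tbl <- summarise_tracks(
    all_tracks,
    rep(cohort$subject_id, each = nrow(track_plan)),
    rep(track_plan$task, nrow(cohort)),
    rep(track_plan$block, nrow(cohort))
  )
  if (keep_tracks) track_tbl$track <- all_tracks

  structure(
    list(
      cohort = cohort,
      trials = trials,
      tracks = track_tbl,
      audiograms = simulate_audiograms(cohort),
      ssq = purrr::map_dfr(per_subject, "ssq"),
      config = config,
      seed = seed
    ),
    class = "cohort_sim"
  )
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("<cohort_sim> %d subjects, %d trials, %d adaptive tracks (seed %s)\n",
              nrow(x$cohort), nrow(x$trials), nrow(x$tracks),
              format(x$seed)))
  invisible(x)
}

#' Score a simulated cohort into one row of measures per subject
#'
#' Applies the full scoring battery: the transformed speech recognition
#' score from sentence blocks 2-3; intensity DLs in quiet and under masking
#' from the retained adaptive tracks (per-condition mean of the per-track
#' reversal means) with the elevation `DL_elev = DL_masked - DL_quiet`; the
#' interaural-phase threshold (mean of the per-track geometric means,
#' degrees); audiogram summaries; flanker processing speed and
#' interference; the span score; SSQ subscales; and age.
#'
#' @param sim A `cohort_sim` from [simulate_cohort()].
#' @param counting_rule Counting rule for the intensity DL estimator.
#' @return A tibble with one row per subject and the measure columns
#'   `SRS`, `DL_quiet`, `DL_masked`, `DL_elev`, `TFS_th`, `PTA_BE`,
#'   `HL_diff`, `RT_neutral`, `Int_Flanker`, `SS_Pcorr`, `Age`,
#'   `SSQ_speech`, `SSQ_spatial`, `SSQ_qualities`, plus the per-subject
#'   count of excluded tracks.
#' @export
score_cohort <- function(sim, counting_rule = c("as_printed", "even_count")) {
  stopifnot(inherits(sim, "cohort_sim"))
  counting_rule <- match.arg(counting_rule)

  srs <- compute_srs(sim$trials)
  flank <- compute_flanker_measures(sim$trials)
  span <- compute_span_score(sim$trials)
  audio <- compute_audiogram_measures(sim$audiograms)

  dls <- sim$tracks |>
    dplyr::filter(!.data$excluded) |>
    dplyr::summarise(m = mean(.data$threshold), .by = c("subject_id", "task")) |>
    tidyr::pivot_wider(names_from = "task", values_from = "m") |>
    dplyr::rename(DL_quiet = "intensity_quiet", DL_masked = "intensity_masked",
                  TFS_th = "tfs")

  excl <- sim$tracks |>
    dplyr::summarise(n_excluded_tracks = sum(.data$excluded), .by = "subject_id")

  sim$cohort |>
    dplyr::select("subject_id", Age = "age") |>
    dplyr::left_join(srs, by = "subject_id") |>
    dplyr::left_join(dls, by = "subject_id") |>
    dplyr::mutate(DL_elev = .data$DL_masked - .data$DL_quiet) |>
    dplyr::left_join(audio, by = "subject_id") |>
    dplyr::left_join(flank, by = "subject_id") |>
    dplyr::left_join(span, by = "subject_id") |>
    dplyr::left_join(
      dplyr::rename(sim$ssq, SSQ_speech = "ssq_speech",
                    SSQ_spatial = "ssq_spatial", SSQ_qualities = "ssq_qualities"),
      by = "subject_id"
    ) |>
    dplyr::left_join(excl, by = "subject_id") |>
    dplyr::relocate("SRS", .after = "subject_id")
}

#' Per-block scores for reliability analysis
#'
#' Returns the block-wise (or track-wise) values of the repeatable measures,
#' one column per block, ready for [icc_absolute_agreement()]: the
#' transformed speech score on blocks 2 and 3; the quiet DL on its two
#' tracks; the masked DL on its three tracks; the phase threshold on its
#' two tracks; the neutral log RT and the flanker interference on flanker
#' blocks 2 and 3. Subjects with an excluded track have `NA` in that cell.
#'
#' @param sim A `cohort_sim`.
#' @param counting_rule Counting rule for the intensity DL estimator.
#' @return A named list of subjects x blocks tibbles (first column
#'   `subject_id`), one per measure.
#' @export
score_blocks <- function(sim, counting_rule = c("as_printed", "even_count")) {
  stopifnot(inherits(sim, "cohort_sim"))
  counting_rule <- match.arg(counting_rule)
  word_cols <- grep("^word\\d+$", names(sim$trials), value = TRUE)

  srs_b <- sim$trials |>
    dplyr::filter(.data$task == "sentence", .data$block %in% c(2L, 3L)) |>
    dplyr::select("subject_id", "block", dplyr::all_of(word_cols)) |>
    tidyr::pivot_longer(dplyr::all_of(word_cols), values_to = "ok") |>
    dplyr::summarise(v = arcsin_sqrt(mean(.data$ok)),
                     .by = c("subject_id", "block")) |>
    tidyr::pivot_wider(names_from = "block", values_from = "v",
                       names_prefix = "block")

  track_b <- function(task_name) {
    sim$tracks |>
      dplyr::filter(.data$task == task_name) |>
      dplyr::mutate(threshold = ifelse(.data$excluded, NA_real_, .data$threshold)) |>
      dplyr::select("subject_id", "block", "threshold") |>
      tidyr::pivot_wider(names_from = "block", values_from = "threshold",
                         names_prefix = "block")
  }

  fl <- sim$trials |>
    dplyr::filter(.data$task == "flanker", .data$block %in% c(2L, 3L),
                  .data$correct, .data$rt_ms >= 200, .data$rt_ms <= 3000)
  rt_b <- fl |>
    dplyr::filter(.data$distractor == "neutral") |>
    dplyr::summarise(v = mean(log(.data$rt_ms)), .by = c("subject_id", "block")) |>
    tidyr::pivot_wider(names_from = "block", values_from = "v",
                       names_prefix = "block")
  int_b <- fl |>
    dplyr::summarise(m = mean(log(.data$rt_ms)),
                     .by = c("subject_id", "block", "distractor", "object")) |>
    tidyr::pivot_wider(names_from = "distractor", values_from = "m") |>
    dplyr::mutate(int = .data$incompatible - .data$neutral) |>
    dplyr::summarise(v = mean(.data$int), .by = c("subject_id", "block")) |>
    tidyr::pivot_wider(names_from = "block", values_from = "v",
                       names_prefix = "block")

  list(
    SRS = srs_b,
    DL_quiet = track_b("intensity_quiet"),
    DL_masked = track_b("intensity_masked"),
    TFS_th = track_b("tfs"),
    RT_neutral = rt_b,
    Int_Flanker = int_b
  )
}
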