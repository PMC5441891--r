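test_that("configuration validation rejects bad inputs before any simulation", {
  bad <- default_trait_correlations()
  bad["speech", "dl_elev"] <- bad["dl_elev", "speech"] <- -0.999
  bad["speech", "tfs"] <- bad["tfs", "speech"] <- -0.999
  bad["dl_elev", "tfs"] <- bad["tfs", "dl_elev"] <- -0.999
  err <- expect_error(cohort_config(trait_correlations = bad),
                      class = "cocktailr_config_error")
  expect_match(conditionMessage(err), "eigenvalue")

  asym <- default_trait_correlations()
  asym[1, 2] <- 0.5
  expect_error(cohort_config(trait_correlations = asym), "symmetric")

  sc <- default_trait_scales()
  sc$sd[sc$trait == "dl_quiet"] <- 0
  expect_error(cohort_config(trait_scales = sc), "dl_quiet")

  td <- default_task_design()
  td$sentence_blocks <- NULL
  expect_error(cohort_config(task_design = td), "sentence_blocks")

  expect_error(cohort_config(n_subjects = 0), class = "cocktailr_config_error")
})

test_that("cohorts are reproducible and obey their support invariants", {
  cfg <- tiny_config(n = 40)
  a <- generate_cohort(cfg, seed = 7)
  b <- generate_cohort(cfg, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(cfg, seed = 8)))

  expect_true(all(a$word_intelligibility >= 0.1 & a$word_intelligibility <= 1))
  expect_true(all(a$ipd_threshold_true > 0 & a$ipd_threshold_true <= 180))
  expect_true(all(a$dl_masked_true >= a$dl_quiet_true))
  expect_true(all(a$dl_elev_true > 0))
  expect_true(all(a$flanker_effect_true > 0))
  expect_true(all(a$span_recall_prob >= 0 & a$span_recall_prob <= 1))
  expect_true(all(a$age >= 18 & a$age <= 30))
  expect_true(all(a$ssq_speech_true >= 0 & a$ssq_speech_true <= 10))

  aud <- simulate_audiograms(a)
  expect_true(all(aud$threshold_db < 20))
  expect_equal(nrow(aud), 40 * 12)
})

test_that("the copula reproduces the requested trait correlations", {
  # independence under an identity matrix
  cfg0 <- cohort_config(n_subjects = 5000, trait_correlations = diag(13))
  coh0 <- generate_cohort(cfg0, seed = 21)
  pick <- coh0[c("word_intelligibility", "dl_elev_true", "ipd_threshold_true",
                 "span_recall_prob", "base_log_rt", "age")]
  cors <- cor(pick)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.05)

  # the default speech/DL-elevation association, on the link scale where the
  # copula correlation is exact
  coh <- generate_cohort(cohort_config(n_subjects = 5000), seed = 22)
  link_speech <- qlogis((coh$word_intelligibility - 0.1) / 0.9)
  link_elev <- log(coh$dl_elev_true)
  expect_equal(cor(link_speech, link_elev), -0.374, tolerance = 0.03 / 0.374)
})

test_that("sentence-task simulation is calibrated, with a block-1 practice penalty", {
  td <- default_task_design()
  td$sentence_trials <- 1000L
  cfg <- cohort_config(n_subjects = 1, task_design = td,
                       sentence_practice_penalty = 0.1)

  perfect <- one_listener()
  perfect$word_intelligibility <- 1
  # at ceiling (no practice penalty) every word in every block is correct
  cfg_nopen <- cohort_config(n_subjects = 1, task_design = td,
                             sentence_practice_penalty = 0)
  tr <- simulate_sentence_task(perfect, cfg_nopen, seed = 1)
  expect_true(all(tr$word1 & tr$word2 & tr$word3 & tr$word4 & tr$word5))

  # at the 10-alternative guessing floor the practice penalty cannot bite
  chance <- perfect
  chance$word_intelligibility <- 0.1
  tr <- simulate_sentence_task(chance, cfg, seed = 2)
  words <- as.matrix(tr[paste0("word", 1:5)])
  expect_equal(mean(words), 0.10, tolerance = 0.02 / 0.10)

  mid <- perfect
  mid$word_intelligibility <- 0.7
  tr <- simulate_sentence_task(mid, cfg, seed = 3)
  words <- as.matrix(tr[paste0("word", 1:5)])
  p_b1 <- mean(words[tr$block == 1, ])
  p_rest <- mean(words[tr$block > 1, ])
  expect_equal(p_b1, 0.6, tolerance = 0.02 / 0.6)
  expect_equal(p_rest, 0.7, tolerance = 0.02 / 0.7)

  bad <- perfect
  bad$word_intelligibility <- 0.05
  expect_error(simulate_sentence_task(bad, cfg), "0.1")
})

test_that("2AFC responders have the logistic form with a 0.5 guessing floor", {
  cfg <- cohort_config()
  li <- one_listener()
  resp <- make_responder(li, "intensity_quiet", cfg)
  at <- function(level, n = 4000) {
    mean(vapply(seq_len(n), function(i) resp(level), logical(1)))
  }
  set.seed(11)
  expect_equal(at(li$dl_quiet_true), 0.75, tolerance = 0.03 / 0.75)
  expect_equal(at(li$dl_quiet_true - 60), 0.5, tolerance = 0.03 / 0.5)
  expect_equal(at(li$dl_quiet_true + 60), 1.0, tolerance = 0.01)
  expect_error(make_responder(li, "nonsense"), "arg")

  # sigma -> 0: certainty above threshold, pure guessing (0.5) below it --
  # the 2AFC guessing floor never vanishes
  step_cfg <- cohort_config(sigma_intensity = 1e-9)
  step <- make_responder(li, "intensity_quiet", step_cfg)
  set.seed(12)
  expect_true(all(vapply(1:200, function(i) step(li$dl_quiet_true + 0.01),
                         logical(1))))
  below <- mean(vapply(1:4000, function(i) step(li$dl_quiet_true - 0.01),
                       logical(1)))
  expect_equal(below, 0.5, tolerance = 0.03 / 0.5)
})

test_that("flanker simulation recovers the generating interference effect", {
  td <- default_task_design()
  td$flanker_reps <- 300L   # 4800 trials/condition over blocks 2-3
  cfg <- cohort_config(n_subjects = 1, task_design = td,
                       flanker_error_rate = 0, rt_sigma = 0.15)
  li <- one_listener()

  li$flanker_effect_true <- 0
  m0 <- compute_flanker_measures(simulate_flanker(li, cfg, seed = 4))
  expect_equal(m0$Int_Flanker, 0, tolerance = 0.01)

  li$flanker_effect_true <- 0.05
  m1 <- compute_flanker_measures(simulate_flanker(li, cfg, seed = 5))
  expect_equal(m1$Int_Flanker, 0.05, tolerance = 0.01 / 0.05)
  expect_equal(m1$RT_neutral, unname(li$base_log_rt), tolerance = 0.01)

  # the printed design: 16 conditions x 4 repetitions = 64 trials per block
  default_tr <- simulate_flanker(li, cohort_config(), seed = 6)
  expect_equal(as.vector(table(default_tr$block)), rep(64L, 3L))
  counts <- dplyr::count(default_tr, block, distractor, object, target, colour)
  expect_true(all(counts$n == 4L))
})

test_that("span and SSQ simulation respect the printed design and scales", {
  cfg <- cohort_config()
  li <- one_listener()

  li$span_recall_prob <- 1
  sp <- simulate_span_task(li, cfg, seed = 7)
  expect_equal(compute_span_score(sp)$span_prop, 1)
  expect_equal(length(unique(sp$block)), 10L)
  expect_equal(nrow(sp), 50L)
  expect_equal(sort(unique(sp$list_length)), 3:7)

  li$span_recall_prob <- 0
  sp0 <- simulate_span_task(li, cfg, seed = 8)
  expect_true(all(sp0$recalled != sp0$presented))

  quiet_cfg <- cohort_config(ssq_noise_sd = 0)
  li$ssq_speech_true <- 10; li$ssq_spatial_true <- 10; li$ssq_qualities_true <- 10
  ssq <- simulate_ssq(li, quiet_cfg, seed = 9)
  expect_equal(ssq$ssq_speech + ssq$ssq_spatial + ssq$ssq_qualities, 30)
})

test_that("full-cohort simulation is deterministic and subject-stable", {
  cfg <- tiny_config(n = 4)
  s1 <- simulate_cohort(cfg, seed = 31)
  s2 <- simulate_cohort(cfg, seed = 31)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$tracks$threshold, s2$tracks$threshold)

  # adding subjects must not perturb the data of existing ones
  s6 <- simulate_cohort(tiny_config(n = 6), seed = 31)
  expect_identical(dplyr::filter(s6$trials, subject_id <= 4), s1$trials)

  # every configured (subject, task, block) cell is present
  cells <- dplyr::distinct(s1$trials, subject_id, task, block)
  expect_equal(nrow(dplyr::filter(cells, task == "sentence")), 4 * 3)
  expect_equal(nrow(dplyr::filter(cells, task == "flanker")), 4 * 3)
  expect_equal(nrow(dplyr::filter(cells, task == "span")), 4 * 10)
  expect_true(all(s1$trials$rt_ms > 0, na.rm = TRUE))
})

test_that("config files round-trip through the YAML/JSON reader", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_subjects: 7",
    "seed: 5",
    "sigma_intensity: 4",
    "task_design:",
    "  sentence_trials: 10"
  ), path)
  cfg <- read_cohort_config(path)
  expect_s3_class(cfg, "cohort_config")
  expect_equal(cfg$n_subjects, 7L)
  expect_equal(cfg$task_design$sentence_trials, 10)
  expect_equal(cfg$task_design$flanker_blocks, 3L)  # defaults filled in

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("no_such_field: 1", bad)
  expect_error(read_cohort_config(bad), "no_such_field")
})
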