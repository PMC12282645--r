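# Synthetic-study generator.

small_config <- function(..., nights_per_participant = 3L) {
  study_config(
    cohorts = tibble::tibble(name = c("HV", "Moderate AD"),
                             n_participants = c(2L, 3L),
                             median_freq = c(2.4, 4.64),
                             median_dur = c(13.1, 30.0),
                             pro = c(FALSE, TRUE)),
    nights_per_participant = nights_per_participant, ...)
}

test_that("simulate_study produces the configured counts and is reproducible", {
  st <- simulate_study(study_config(seed = 99L))
  expect_equal(nrow(st$participants), 28)
  expect_equal(nrow(st$nights), 224)
  expect_equal(sum(st$events$source == "Truth" & st$events$kind == "tso"), 224)
  st2 <- simulate_study(study_config(seed = 99L))
  expect_identical(st$events, st2$events)
  expect_identical(st$pro, st2$pro)
  st3 <- simulate_study(study_config(seed = 100L))
  expect_false(identical(st$events, st3$events))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(1)
  before <- runif(1)
  set.seed(1)
  invisible(simulate_study(small_config(seed = 7L)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(study_config(cohorts = tibble::tibble(
    name = "X", n_participants = 2L, median_freq = -1,
    median_dur = 10, pro = FALSE)), "cohorts")
  expect_error(study_config(vc = list(
    frequency = c(participant = -0.1, night = 0.1, residual = 0.1),
    duration = c(participant = 0.1, night = 0.1, residual = 0.1))), "vc")
  expect_error(simulate_study(list()), "study_config")
})

test_that("a zero-noise rater model reproduces truth; miss_prob 1 erases it", {
  st <- simulate_study(small_config(seed = 3L))
  truth <- dplyr::filter(st$events, source == "Truth", kind == "scratch")
  tso <- dplyr::filter(st$events, source == "Truth", kind == "tso")
  win <- dplyr::select(tso, participant_id, night_id, start_s, end_s)
  ident <- apply_rater_model(truth, rater_model(0, 0, 0), win, source = "RX",
                             seed = 1)
  expect_equal(nrow(ident), nrow(truth))
  expect_equal(ident$start_s, truth$start_s)
  expect_equal(ident$end_s, truth$end_s)
  gone <- apply_rater_model(truth, rater_model(0, miss_prob = 1,
                                               false_bout_rate_per_h = 0),
                            win, source = "RX", seed = 1)
  expect_equal(nrow(gone), 0)
})

test_that("moderate rater noise lands in a plausible IoU band against truth", {
  st <- simulate_study(study_config(seed = 17L))
  truth <- dplyr::filter(st$events, source == "Truth", kind == "scratch")
  tso <- dplyr::filter(st$events, source == "Truth", kind == "tso")
  win <- dplyr::select(tso, participant_id, night_id, start_s, end_s)
  noisy <- apply_rater_model(truth, rater_model(boundary_jitter_sd_s = 1,
                                                miss_prob = 0.05,
                                                false_bout_rate_per_h = 0.2),
                             win, source = "RX", seed = 2)
  per_night <- iou(truth, noisy)
  med <- median(per_night$iou)
  expect_gt(med, 0.6)
  expect_lt(med, 0.98)
})

test_that("an identity device reproduces truth including its TSO", {
  st <- simulate_study(small_config(seed = 4L))
  truth <- dplyr::filter(st$events, source == "Truth", kind == "scratch")
  tso <- dplyr::filter(st$events, source == "Truth", kind == "tso")
  win <- dplyr::select(tso, participant_id, night_id, start_s, end_s)
  obs <- apply_device_model(truth, device_preset("identity"), win,
                            source = "DX", seed = 5)
  expect_equal(obs$scratch$start_s, truth$start_s)
  expect_equal(nrow(obs$sleep), nrow(win))
  expect_equal(obs$sleep$start_s, win$start_s)
  expect_equal(obs$sleep$end_s, win$end_s)
})

test_that("device TSO endpoint biases add up to the expected duration bias", {
  st <- simulate_study(small_config(seed = 8L, nights_per_participant = 40L))
  truth <- dplyr::filter(st$events, source == "Truth", kind == "scratch")
  tso <- dplyr::filter(st$events, source == "Truth", kind == "tso")
  win <- dplyr::select(tso, participant_id, night_id, start_s, end_s)
  m <- device_model(detect_intercept = 30, detect_slope = 0,
                    false_bout_rate_per_h = 0, boundary_jitter_sd_s = 0,
                    tso_start_bias_s = -0.2 * 3600, tso_end_bias_s = 0.2 * 3600)
  obs <- apply_device_model(truth, m, win, source = "DX", seed = 6)
  dur_err <- (obs$sleep$end_s - obs$sleep$start_s) - (win$end_s - win$start_s)
  expect_equal(mean(dur_err) / 3600, 0.4, tolerance = 1e-9)
})

test_that("analytic_icc reflects the configured components", {
  cfg <- study_config(vc = list(
    frequency = c(participant = 1, night = 0.5, residual = 0.5),
    duration = c(participant = 1, night = 0.5, residual = 0)))
  out <- analytic_icc(cfg)
  expect_equal(out$icc[out$outcome == "norm_frequency"], 0.75)
  expect_equal(out$icc[out$outcome == "norm_duration"], 1)
})

test_that("pipeline ICC on directly simulated outcomes matches the analytic value", {
  set.seed(64)
  iccs <- vapply(1:10, function(i) {
    dat <- simulate_vc_data(n_participants = 28, n_nights = 8,
                            var_participant = 1, var_night = 0.5,
                            var_residual = 0.5)
    icc_from_components(fit_variance_components(dat))
  }, numeric(1))
  expect_equal(mean(iccs), 0.75, tolerance = 0.05)
})

test_that("PRO responses exist only for PRO cohorts and itch tracks scratch rate", {
  st <- simulate_study(study_config(seed = 12L))
  pro_cohorts <- st$participants$cohort[match(unique(st$pro$participant_id),
                                              st$participants$participant_id)]
  expect_false("HV" %in% pro_cohorts)
  morning <- dplyr::filter(st$pro, administration == "morning")
  joined <- dplyr::inner_join(morning,
                              st$nights[c("participant_id", "night_id", "true_rate_per_h")],
                              by = c("participant_id", "night_id"))
  lo <- median(joined$true_rate_per_h[joined$itch_nrs == 0])
  hi <- median(joined$true_rate_per_h[joined$itch_nrs >= 4])
  expect_lt(lo, hi)
})
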