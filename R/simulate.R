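# Synthetic-study generator.
#
# Emulates the structure of an in-home nocturnal scratch validation study:
# three cohorts (healthy volunteers, mild AD, moderate AD) of participants
# who each contribute ~8 video-recorded nights; ground-truth scratching as a
# homogeneous Poisson bout process over the night's true TSO with lognormal
# participant and night random effects on rate and bout duration; five human
# rater streams and two device streams derived from truth through explicit
# error models; and morning itch ratings coupled monotonically to the
# night's true scratch rate. Everything is deterministic given the
# config seed, and generation leaves the caller's RNG state untouched.

#' Human-rater error model
#'
#' Raters miss a bout with probability `miss_prob`, jitter the endpoints of
#' kept bouts (Gaussian, resampled if the jittered interval inverts), and
#' add spurious bouts as a Poisson process over the night at
#' `false_bout_rate_per_h`, with lognormal durations. `tso_jitter_sd_s`
#' applies to the rater's TSO start/end labels.
#'
#' @param boundary_jitter_sd_s,miss_prob,false_bout_rate_per_h Error
#'   magnitudes; zero for a perfect rater.
#' @param false_bout_meanlog,false_bout_sdlog Lognormal parameters of
#'   spurious-bout durations (seconds).
#' @param tso_jitter_sd_s SD of Gaussian error on each TSO endpoint label.
#' @return A list of class `rater_model`.
#' @export
rater_model <- function(boundary_jitter_sd_s = 0.2, miss_prob = 0.02,
                        false_bout_rate_per_h = 0.1,
                        false_bout_meanlog = 1.0, false_bout_sdlog = 0.4,
                        tso_jitter_sd_s = 20) {
  stopifnot(miss_prob >= 0, miss_prob <= 1, false_bout_rate_per_h >= 0,
            boundary_jitter_sd_s >= 0, tso_jitter_sd_s >= 0)
  structure(as.list(environment()), class = "rater_model")
}

#' Device error model
#'
#' Per-bout detection is Bernoulli with a logistic probability in bout
#' duration, `plogis(detect_intercept + detect_slope * duration_s)`;
#' detected bouts are jittered and spurious bouts added as in
#' [rater_model()]. The device's sleep periods are the true TSO with
#' Gaussian endpoint errors (`tso_*_bias_s`, `tso_*_sd_s`) and, with
#' probability `sleep_split_prob`, a mid-night split into two periods
#' separated by a uniform gap — exercising the <30 min sleep-period merge
#' rule downstream.
#'
#' @param detect_intercept,detect_slope Logistic detection parameters.
#' @param false_bout_rate_per_h,boundary_jitter_sd_s,false_bout_meanlog,false_bout_sdlog
#'   As in [rater_model()].
#' @param tso_start_bias_s,tso_start_sd_s,tso_end_bias_s,tso_end_sd_s
#'   Gaussian error on the sleep-period endpoints, seconds.
#' @param sleep_split_prob Probability a night's sleep period is split.
#' @param split_gap_min_min,split_gap_max_min Uniform bounds of the split
#'   gap, minutes.
#' @return A list of class `device_model`.
#' @export
device_model <- function(detect_intercept = 0, detect_slope = 0.35,
                         false_bout_rate_per_h = 1,
                         boundary_jitter_sd_s = 1,
                         false_bout_meanlog = 1.0, false_bout_sdlog = 0.5,
                         tso_start_bias_s = 0, tso_start_sd_s = 0,
                         tso_end_bias_s = 0, tso_end_sd_s = 0,
                         sleep_split_prob = 0, split_gap_min_min = 5,
                         split_gap_max_min = 45) {
  stopifnot(false_bout_rate_per_h >= 0, boundary_jitter_sd_s >= 0,
            sleep_split_prob >= 0, sleep_split_prob <= 1)
  structure(as.list(environment()), class = "device_model")
}

#' Device model presets
#'
#' `"emerald"`: a touchless RF-style device with balanced errors and a TSO
#' duration bias of +0.44 h. `"philips"`: a wrist-actigraphy-style device
#' that is oversensitive — high spurious-bout rate, so precision falls below
#' sensitivity — with a TSO duration bias of +0.42 h. `"identity"`: a
#' noise-free device that reproduces truth exactly.
#'
#' @param preset One of `"emerald"`, `"philips"`, `"identity"`.
#' @return A `device_model`.
#' @export
device_preset <- function(preset = c("emerald", "philips", "identity")) {
  preset <- match.arg(preset)
  switch(preset,
    emerald = device_model(
      detect_intercept = -0.3, detect_slope = 0.35,
      false_bout_rate_per_h = 0.6, boundary_jitter_sd_s = 1,
      tso_start_bias_s = -792, tso_start_sd_s = 2970,
      tso_end_bias_s = 792, tso_end_sd_s = 2970,
      sleep_split_prob = 0.15, split_gap_max_min = 25),
    philips = device_model(
      detect_intercept = 0.4, detect_slope = 0.35,
      false_bout_rate_per_h = 3, boundary_jitter_sd_s = 1.5,
      tso_start_bias_s = -756, tso_start_sd_s = 3378,
      tso_end_bias_s = 756, tso_end_sd_s = 3378,
      sleep_split_prob = 0.1, split_gap_max_min = 25),
    identity = device_model(
      detect_intercept = 30, detect_slope = 0,
      false_bout_rate_per_h = 0, boundary_jitter_sd_s = 0))
}

#' Synthetic-study configuration
#'
#' Defaults reproduce the validation study's structure: cohorts of 5 healthy
#' volunteers (HV), 9 mild AD and 14 moderate AD participants, 8 nights
#' each, with cohort median normalized scratch frequency / duration
#' calibrated to 2.4/13.1 (HV), 3.51/17.4 (mild) and 4.64/30.0 (moderate)
#' bouts per hour / seconds per hour. Bout durations are `bout$min_s` plus a
#' lognormal excess whose mean is set so that median duration / median
#' frequency matches the cohort targets. Log-scale participant and night
#' variance components control the between-participant and between-night
#' spread of the true outcomes; the `residual` entries describe the intended
#' source-level disagreement and drive [analytic_icc()].
#'
#' @param cohorts Tibble with `name`, `n_participants`, `median_freq`
#'   (bouts/h), `median_dur` (s/h), `pro` (does the cohort complete the
#'   morning itch PRO).
#' @param nights_per_participant Nights of recording per participant.
#' @param vc Named list (`frequency`, `duration`) of log-scale variance
#'   components `c(participant=, night=, residual=)`.
#' @param bout List: `min_s` (minimum true bout duration, seconds) and
#'   `sdlog` of the lognormal excess.
#' @param tso List: mean TSO start (seconds after the noon night origin;
#'   39600 = 23:00), its SD, mean duration (h), duration SD (h), and a
#'   truncation floor `min_dur_h`.
#' @param rater Default [rater_model()] shared by the five rater streams.
#' @param rater_overrides Named list of per-rater `rater_model` overrides.
#' @param devices Named list of [device_model()]s (default Emerald- and
#'   Philips-like presets).
#' @param itch List: `intercept`, `slope`, `sd` of the latent itch score,
#'   a monotone noisy map of the night's realized bout rate.
#' @param pro_time List: mean and SD (seconds after midnight) of the
#'   morning PRO completion clock time.
#' @param start_date,night_spacing_days Calendar layout of nights.
#' @param seed Integer seed governing the whole study.
#' @return A list of class `study_config`.
#' @export
study_config <- function(
    cohorts = tibble::tibble(
      name = c("HV", "Mild AD", "Moderate AD"),
      n_participants = c(5L, 9L, 14L),
      median_freq = c(2.4, 3.51, 4.64),
      median_dur = c(13.1, 17.4, 30.0),
      pro = c(FALSE, TRUE, TRUE)),
    nights_per_participant = 8L,
    vc = list(frequency = c(participant = 0.09, night = 0.04, residual = 0.06),
              duration = c(participant = 0.12, night = 0.05, residual = 0.08)),
    bout = list(min_s = 2, sdlog = 0.6),
    tso = list(mean_start_s = 39600, start_sd_s = 2700,
               mean_dur_h = 8, dur_sd_h = 0.6, min_dur_h = 2),
    rater = rater_model(),
    rater_overrides = list(),
    devices = list(Emerald = device_preset("emerald"),
                   Philips = device_preset("philips")),
    itch = list(intercept = -2, slope = 2.6, sd = 1.5),
    pro_time = list(mean_s = 28800, sd_s = 2700),
    start_date = "2022-03-01",
    night_spacing_days = 3L,
    seed = 1234L) {
  cfg <- as.list(environment())
  if (any(cohorts$median_freq <= 0) || any(cohorts$median_dur <= 0)) {
    stop_scratchval("cohort medians must be positive (field: cohorts).")
  }
  if (any(cohorts$median_dur / cohorts$median_freq <= bout$min_s)) {
    stop_scratchval("implied mean bout duration must exceed bout$min_s (field: cohorts).")
  }
  for (f in c("frequency", "duration")) {
    if (any(cfg$vc[[f]] < 0)) stop_scratchval("negative variance component (field: vc$%s).", f)
  }
  # the duration outcome is rate x mean bout length, so its participant and
  # night components must dominate the frequency components
  for (cmp in c("participant", "night")) {
    if (vc$duration[[cmp]] < vc$frequency[[cmp]]) {
      stop_scratchval("vc$duration['%s'] must be >= vc$frequency['%s'] (field: vc).",
                      cmp, cmp)
    }
  }
  if (nights_per_participant < 1) stop_scratchval("nights_per_participant must be >= 1.")
  structure(cfg, class = "study_config")
}

#' Remove all observation noise from a study configuration
#'
#' Raters reproduce truth exactly, devices detect every bout with no
#' spurious events, and device sleep periods equal the true TSO. Under this
#' configuration the entire pipeline must return perfect scores.
#'
#' @param config A [study_config()].
#' @return The modified config.
#' @export
noise_free <- function(config) {
  config$rater <- rater_model(boundary_jitter_sd_s = 0, miss_prob = 0,
                              false_bout_rate_per_h = 0, tso_jitter_sd_s = 0)
  config$rater_overrides <- list()
  config$devices <- lapply(config$devices, function(m) device_preset("identity"))
  config
}

# --- observation models ------------------------------------------------------

jitter_intervals <- function(s, e, sd) {
  if (sd <= 0 || length(s) == 0L) return(list(s = s, e = e))
  out_s <- s + stats::rnorm(length(s), 0, sd)
  out_e <- e + stats::rnorm(length(e), 0, sd)
  bad <- which(out_e <= out_s) # inverted draws are resampled, not clipped
  while (length(bad)) {
    out_s[bad] <- s[bad] + stats::rnorm(length(bad), 0, sd)
    out_e[bad] <- e[bad] + stats::rnorm(length(bad), 0, sd)
    bad <- bad[out_e[bad] <= out_s[bad]]
  }
  list(s = out_s, e = out_e)
}

false_bouts <- function(rate_per_h, window, meanlog, sdlog) {
  hours <- (window[2] - window[1]) / 3600
  n <- stats::rpois(1, rate_per_h * hours)
  if (n == 0L) return(list(s = numeric(), e = numeric()))
  dur <- stats::rlnorm(n, meanlog, sdlog)
  dur <- pmin(dur, window[2] - window[1])
  s <- window[1] + stats::runif(n) * (window[2] - window[1] - dur)
  list(s = s, e = s + dur)
}

# Observe one truth track (vectors) through a rater model.
observe_rater <- function(s, e, model, window) {
  keep <- stats::runif(length(s)) >= model$miss_prob
  obs <- jitter_intervals(s[keep], e[keep], model$boundary_jitter_sd_s)
  fp <- false_bouts(model$false_bout_rate_per_h, window,
                    model$false_bout_meanlog, model$false_bout_sdlog)
  coalesce_intervals(c(obs$s, fp$s), c(obs$e, fp$e))
}

observe_device <- function(s, e, model, window) {
  p_det <- stats::plogis(model$detect_intercept + model$detect_slope * (e - s))
  keep <- stats::runif(length(s)) < p_det
  obs <- jitter_intervals(s[keep], e[keep], model$boundary_jitter_sd_s)
  fp <- false_bouts(model$false_bout_rate_per_h, window,
                    model$false_bout_meanlog, model$false_bout_sdlog)
  coalesce_intervals(c(obs$s, fp$s), c(obs$e, fp$e))
}

device_sleep_periods <- function(window, model) {
  s <- window[1] + model$tso_start_bias_s +
    stats::rnorm(1, 0, max(model$tso_start_sd_s, 0))
  e <- window[2] + model$tso_end_bias_s +
    stats::rnorm(1, 0, max(model$tso_end_sd_s, 0))
  if (e - s < 600) e <- s + 600 # a device never reports a <10 min rest
  if (stats::runif(1) < model$sleep_split_prob) {
    mid <- s + (0.25 + 0.5 * stats::runif(1)) * (e - s)
    gap <- 60 * stats::runif(1, model$split_gap_min_min, model$split_gap_max_min)
    if (mid - gap / 2 > s && mid + gap / 2 < e) {
      return(list(s = c(s, mid + gap / 2), e = c(mid - gap / 2, e)))
    }
  }
  list(s = s, e = e)
}

#' Observe a truth track through a rater error model
#'
#' @param truth Events table of true scratch bouts (one or more tracks).
#' @param model A [rater_model()].
#' @param tso Table with the night windows (`start_s`, `end_s` and the same
#'   identifier columns as `truth`) over which spurious bouts may fall.
#' @param source Source label for the output.
#' @param seed Optional seed.
#' @return An events tibble of the rater's annotation, normalized.
#' @export
apply_rater_model <- function(truth, model, tso, source = "R1", seed = NULL) {
  with_seed(seed, observe_tracks(truth, tso, source,
                                 function(s, e, w) observe_rater(s, e, model, w)))
}

#' Observe a truth track through a device error model
#'
#' @inheritParams apply_rater_model
#' @param model A [device_model()].
#' @return A list: `scratch` (events tibble, `kind = "scratch"`) and
#'   `sleep` (events tibble of device sleep periods,
#'   `kind = "sleep_period"`).
#' @export
apply_device_model <- function(truth, model, tso, source = "Device", seed = NULL) {
  with_seed(seed, {
    scratch <- observe_tracks(truth, tso, source,
                              function(s, e, w) observe_device(s, e, model, w))
    keys <- intersect(c("participant_id", "night_id"), names(tso))
    sleep <- dplyr::bind_rows(lapply(seq_len(nrow(tso)), function(i) {
      sp <- device_sleep_periods(c(tso$start_s[i], tso$end_s[i]), model)
      dplyr::bind_cols(tso[rep(i, length(sp$s)), keys, drop = FALSE],
                       tibble::tibble(source = source, kind = "sleep_period",
                                      start_s = sp$s, end_s = sp$e))
    }))
    list(scratch = scratch, sleep = sleep)
  })
}

# Shared per-night iteration for the observation models.
observe_tracks <- function(truth, tso, source, fn) {
  keys <- intersect(c("participant_id", "night_id"), names(tso))
  truth_key <- if (length(keys)) {
    as.character(interaction(truth[keys], drop = FALSE, lex.order = TRUE))
  } else rep("", nrow(truth))
  tso_key <- if (length(keys)) {
    as.character(interaction(tso[keys], drop = FALSE, lex.order = TRUE))
  } else rep("", nrow(tso))
  rows <- lapply(seq_len(nrow(tso)), function(i) {
    tr <- truth[truth_key == tso_key[i], , drop = FALSE]
    out <- fn(tr$start_s, tr$end_s, c(tso$start_s[i], tso$end_s[i]))
    n <- length(out$start)
    dplyr::bind_cols(tso[rep(i, n), keys, drop = FALSE],
                     tibble::tibble(source = source, kind = "scratch",
                                    start_s = out$start, end_s = out$end))
  })
  dplyr::bind_rows(rows)
}

# --- full study --------------------------------------------------------------

#' Simulate a complete synthetic validation study
#'
#' Generates ground-truth scratching, five rater annotation streams
#' (scratch bouts for R1-R5; TSO labels for R1, R2 and the adjudicator R3),
#' device scratch and sleep-period streams for every configured device, and
#' morning/evening itch PRO responses for the PRO-completing cohorts.
#'
#' @param config A [study_config()].
#' @return A list of class `scratch_study`: `participants`, `nights`,
#'   `events` (long events table over all sources), `pro`, and the `config`.
#'   Byte-identical across calls with the same config.
#' @export
simulate_study <- function(config = study_config()) {
  if (!inherits(config, "study_config")) stop_scratchval("`config` must be a study_config().")
  with_seed(config$seed, {
    co <- config$cohorts
    participants <- tibble::tibble(
      participant_id = sprintf("P%02d", seq_len(sum(co$n_participants))),
      cohort = rep(co$name, co$n_participants))
    n_nights <- config$nights_per_participant
    nights <- tidyr::crossing(participants,
                              night = seq_len(n_nights))
    nights <- dplyr::mutate(
      nights,
      night_id = sprintf("N%02d", .data$night),
      date = as.Date(config$start_date) +
        (.data$night - 1L) * config$night_spacing_days)
    nights <- dplyr::arrange(nights, .data$participant_id, .data$night_id)

    # The duration outcome is rate x mean bout length: its log-scale
    # components are the frequency components plus independent bout-length
    # components sized as the difference, so each outcome's total
    # participant/night variance matches the config.
    vcf <- config$vc$frequency; vcd <- config$vc$duration
    a_f <- stats::rnorm(nrow(participants), 0, sqrt(vcf[["participant"]]))
    a_d <- stats::rnorm(nrow(participants), 0,
                        sqrt(vcd[["participant"]] - vcf[["participant"]]))
    pidx <- match(nights$participant_id, participants$participant_id)
    b_f <- stats::rnorm(nrow(nights), 0, sqrt(vcf[["night"]]))
    b_d <- stats::rnorm(nrow(nights), 0,
                        sqrt(vcd[["night"]] - vcf[["night"]]))
    cidx <- match(participants$cohort[pidx], co$name)

    tso_cfg <- config$tso
    tso_start <- stats::rnorm(nrow(nights), tso_cfg$mean_start_s, tso_cfg$start_sd_s)
    tso_dur_h <- pmax(tso_cfg$min_dur_h,
                      stats::rnorm(nrow(nights), tso_cfg$mean_dur_h, tso_cfg$dur_sd_h))
    nights$tso_start_s <- tso_start
    nights$tso_end_s <- tso_start + tso_dur_h * 3600

    mean_excess <- co$median_dur / co$median_freq - config$bout$min_s
    sdlog <- config$bout$sdlog
    meanlog_c <- log(mean_excess) - sdlog^2 / 2

    rate <- co$median_freq[cidx] * exp(a_f[pidx] + b_f)
    nights$true_rate_per_h <- rate

    truth_rows <- lapply(seq_len(nrow(nights)), function(i) {
      n_b <- stats::rpois(1, rate[i] * tso_dur_h[i])
      if (n_b == 0L) return(NULL)
      dur <- config$bout$min_s +
        stats::rlnorm(n_b, meanlog_c[cidx[i]] + a_d[pidx[i]] + b_d[i], sdlog)
      dur <- pmin(dur, tso_dur_h[i] * 3600)
      s <- nights$tso_start_s[i] +
        stats::runif(n_b) * (tso_dur_h[i] * 3600 - dur)
      out <- coalesce_intervals(s, s + dur)
      tibble::tibble(participant_id = nights$participant_id[i],
                     night_id = nights$night_id[i],
                     source = "Truth", kind = "scratch",
                     start_s = out$start, end_s = out$end)
    })
    truth <- dplyr::bind_rows(truth_rows)
    truth_tso <- dplyr::transmute(nights, .data$participant_id, .data$night_id,
                                  source = "Truth", kind = "tso",
                                  start_s = .data$tso_start_s,
                                  end_s = .data$tso_end_s)
    windows <- dplyr::select(truth_tso, "participant_id", "night_id",
                             "start_s", "end_s")

    rater_of <- function(r) config$rater_overrides[[r]] %||% config$rater
    rater_scratch <- dplyr::bind_rows(lapply(paste0("R", 1:5), function(r) {
      apply_rater_model(truth, rater_of(r), windows, source = r)
    }))
    rater_tso <- dplyr::bind_rows(lapply(paste0("R", 1:3), function(r) {
      sd <- rater_of(r)$tso_jitter_sd_s
      tibble::tibble(participant_id = nights$participant_id,
                     night_id = nights$night_id,
                     source = r, kind = "tso",
                     start_s = nights$tso_start_s + stats::rnorm(nrow(nights), 0, max(sd, 0)),
                     end_s = nights$tso_end_s + stats::rnorm(nrow(nights), 0, max(sd, 0)))
    }))

    device_rows <- lapply(names(config$devices), function(dn) {
      obs <- apply_device_model(truth, config$devices[[dn]], windows, source = dn)
      dplyr::bind_rows(obs$scratch, obs$sleep)
    })

    pro_participants <- participants$participant_id[
      co$pro[match(participants$cohort, co$name)]]
    pro_nights <- nights[nights$participant_id %in% pro_participants, ]
    pro <- if (nrow(pro_nights)) {
      latent <- config$itch$intercept +
        config$itch$slope * log1p(pro_nights$true_rate_per_h) +
        stats::rnorm(nrow(pro_nights), 0, config$itch$sd)
      nrs <- pmin(10L, pmax(0L, as.integer(round(latent))))
      tod <- pmin(11.9 * 3600,
                  pmax(4.1 * 3600,
                       stats::rnorm(nrow(pro_nights), config$pro_time$mean_s,
                                    config$pro_time$sd_s)))
      fmt <- function(sec) sprintf("%02d:%02d:%02d", sec %/% 3600,
                                   (sec %% 3600) %/% 60, round(sec %% 60))
      morning <- tibble::tibble(
        participant_id = pro_nights$participant_id,
        night_id = pro_nights$night_id,
        date = as.character(pro_nights$date + 1L),
        administration = "morning",
        timestamp = fmt(tod),
        itch_nrs = nrs)
      evening <- dplyr::mutate(morning,
                               date = as.character(pro_nights$date),
                               administration = "evening",
                               timestamp = fmt(rep(20.5 * 3600, nrow(morning))),
                               itch_nrs = pmin(10L, pmax(0L, nrs +
                                 sample(c(-1L, 0L, 1L), nrow(morning), replace = TRUE))))
      dplyr::bind_rows(morning, evening)
    } else {
      tibble::tibble(participant_id = character(), night_id = character(),
                     date = character(), administration = character(),
                     timestamp = character(), itch_nrs = integer())
    }

    events <- dplyr::bind_rows(c(list(truth, truth_tso, rater_scratch, rater_tso),
                                 device_rows))
    structure(
      list(participants = participants,
           nights = dplyr::select(nights, "participant_id", "cohort",
                                  "night_id", "date", "true_rate_per_h"),
           events = events,
           pro = pro,
           config = config),
      class = "scratch_study")
  })
}

#' @export
print.scratch_study <- function(x, ...) {
  cat(sprintf("Synthetic scratch study: %d participants, %d nights, %d event rows\n",
              nrow(x$participants), nrow(x$nights), nrow(x$events)))
  invisible(x)
}

#' Expected ICC implied by a study configuration
#'
#' The closed-form counterpart of the mixed-model ICC:
#' `(participant + night) / (participant + night + residual)` straight from
#' the config's log-scale variance components, per outcome.
#'
#' @param config A [study_config()].
#' @return Tibble with `outcome` (`norm_frequency`, `norm_duration`) and
#'   `icc`.
#' @export
analytic_icc <- function(config) {
  one <- function(v) unname((v[["participant"]] + v[["night"]]) /
                              (v[["participant"]] + v[["night"]] + v[["residual"]]))
  tibble::tibble(outcome = c("norm_frequency", "norm_duration"),
                 icc = c(one(config$vc$frequency), one(config$vc$duration)))
}

#' Simulate a long outcome table with known variance components
#'
#' Direct outcome-level simulator used for parameter-recovery checks of the
#' agreement machinery: `y = mu + source effect + participant effect +
#' night-within-participant effect + residual`, all Gaussian on the log
#' scale.
#'
#' @param n_participants,n_nights Study dimensions.
#' @param sources Character vector of source labels.
#' @param mu Grand mean.
#' @param fixed_effects Numeric per-source offsets (recycled; first source
#'   conventionally 0).
#' @param var_participant,var_night,var_residual True variance components.
#' @param seed Optional seed.
#' @return Long tibble with `participant_id`, `night_id`, `source`, `y`.
#' @export
simulate_vc_data <- function(n_participants = 28, n_nights = 8,
                             sources = c("Reference", "DHT"), mu = 3,
                             fixed_effects = 0,
                             var_participant = 1, var_night = 0.5,
                             var_residual = 0.5, seed = NULL) {
  with_seed(seed, {
    S <- length(sources)
    fe <- rep_len(fixed_effects, S)
    grid <- tidyr::crossing(participant_id = sprintf("P%02d", seq_len(n_participants)),
                            night_id = sprintf("N%02d", seq_len(n_nights)),
                            source = sources)
    a <- stats::rnorm(n_participants, 0, sqrt(var_participant))
    b <- stats::rnorm(n_participants * n_nights, 0, sqrt(var_night))
    pi <- as.integer(factor(grid$participant_id))
    ci <- as.integer(factor(paste(grid$participant_id, grid$night_id)))
    si <- match(grid$source, sources)
    dplyr::mutate(grid, y = mu + fe[si] + a[pi] + b[ci] +
                    stats::rnorm(nrow(grid), 0, sqrt(var_residual)))
  })
}
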