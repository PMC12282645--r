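# End-to-end analysis pipeline: consensus -> TSO -> bout merge/filter ->
# epoch scoring -> night outcomes -> agreement statistics.

#' Pipeline configuration
#'
#' Every analysis constant in one place. The defaults are the study's
#' values: 10 s epochs (1 s for the sensitivity analysis), <3 s bout
#' merging, >=2 s minimum bout duration, <30 min sleep-period merging,
#' <3.5 h TSO exclusion, 0.765 IoU consensus threshold, 60 s TSO consensus
#' tolerance, log offset 1, and 500 bootstrap resamples.
#'
#' @param epoch_s Epoch length in seconds (10 or 1).
#' @param merge_gap_s Bout merge gap (strict upper bound), seconds.
#' @param min_bout_s Minimum bout duration (inclusive), seconds.
#' @param tso_merge_gap_min Sleep-period merge gap, minutes.
#' @param tso_min_hours Short-TSO exclusion threshold (strict), hours.
#' @param iou_threshold Consensus IoU threshold (strictly exceeded).
#' @param tso_tolerance_s TSO consensus endpoint tolerance, seconds.
#' @param delta Offset for logs and geometric means, original units.
#' @param n_boot Bootstrap resamples for agreement CIs.
#' @param seed Seed for all pipeline randomness (the bootstraps).
#' @param itch_bands Band definition tibble, see [itch_bands()].
#' @param pro_window Morning PRO validity clock window (inclusive).
#' @param rater_sources Scratch-consensus rater streams, round order.
#' @param tso_rater_sources,tso_adjudicator TSO consensus raters.
#' @param reference_source Label of the consensus reference stream.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(epoch_s = 10, merge_gap_s = 3, min_bout_s = 2,
                            tso_merge_gap_min = 30, tso_min_hours = 3.5,
                            iou_threshold = 0.765, tso_tolerance_s = 60,
                            delta = 1, n_boot = 500, seed = 1L,
                            itch_bands = scratchval::itch_bands(),
                            pro_window = c("04:00", "12:00"),
                            rater_sources = c("R1", "R2", "R3", "R4", "R5"),
                            tso_rater_sources = c("R1", "R2"),
                            tso_adjudicator = "R3",
                            reference_source = "Reference") {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full validation analysis
#'
#' Takes a study bundle — either the output of [simulate_study()] or a list
#' with `events`, `pro`, `nights`, `participants` tibbles read from disk —
#' and runs every stage in order: rater consensus for scratch bouts and
#' TSO, device TSO derivation, short-TSO exclusion, bout merging and
#' filtering, epoch-level classification scoring against the Reference,
#' night-level outcome computation with participant and group summaries,
#' itch stratification, and the agreement statistics (repeated-measures
#' Bland-Altman of TSO duration; bootstrap ICC of both log-scale scratch
#' outcomes for Reference vs each device and rater vs rater).
#'
#' @param study Study bundle (see above). Device sources are discovered as
#'   the sources contributing `sleep_period` events.
#' @param config A [pipeline_config()].
#' @return A list of class `scratch_report` whose elements are tibbles (see
#'   Details) plus the echoed `config`. Deterministic given `study` +
#'   `config`.
#' @export
run_pipeline <- function(study, config = pipeline_config()) {
  events <- study$events
  participants <- study$participants
  nights_tbl <- study$nights
  validate_events(events)
  ref <- config$reference_source
  devices <- sort(unique(events$source[events$kind == "sleep_period"]))
  cohort_of <- if (!is.null(participants)) {
    dplyr::select(participants, "participant_id", dplyr::any_of("cohort"))
  }

  # --- stage 1: consensus ----------------------------------------------------
  rater_scratch <- dplyr::filter(events, .data$kind == "scratch",
                                 .data$source %in% config$rater_sources)
  cons <- bout_consensus(rater_scratch, threshold = config$iou_threshold,
                         rater_sources = config$rater_sources,
                         reference_source = ref)
  rater_tso <- dplyr::filter(events, .data$kind == "tso",
                             .data$source %in% c(config$tso_rater_sources,
                                                 config$tso_adjudicator))
  ref_tso <- tso_consensus(rater_tso, tolerance_s = config$tso_tolerance_s,
                           rater_sources = config$tso_rater_sources,
                           adjudicator_source = config$tso_adjudicator,
                           reference_source = ref)

  # --- stage 2: TSO derivation and exclusion ---------------------------------
  sleep <- dplyr::filter(events, .data$kind == "sleep_period")
  dev_tso <- derive_device_tso(sleep, merge_gap_min = config$tso_merge_gap_min)
  all_tso <- dplyr::bind_rows(
    dplyr::select(ref_tso, -"adjudicated"), dev_tso)
  tso_flagged <- exclude_short_tso(all_tso, min_hours = config$tso_min_hours)
  tso_log <- tso_exclusion_log(tso_flagged)
  kept_tso <- dplyr::filter(tso_flagged, !.data$excluded)

  # --- stage 3: bout merging and filtering -----------------------------------
  raw_scratch <- dplyr::bind_rows(
    cons$reference,
    dplyr::filter(events, .data$kind == "scratch",
                  .data$source %in% c(devices, config$tso_rater_sources)))
  bouts <- filter_min_duration(
    merge_gaps(raw_scratch, max_gap_s = config$merge_gap_s),
    min_dur_s = config$min_bout_s)

  # --- stage 4: epoch-level scoring ------------------------------------------
  ref_kept <- dplyr::filter(kept_tso, .data$source == ref)
  ref_bouts <- dplyr::filter(bouts, .data$source == ref)
  confusion <- dplyr::bind_rows(lapply(devices, function(dn) {
    dht_kept <- dplyr::filter(kept_tso, .data$source == dn)
    windows <- paired_overlap_window(ref_kept, dht_kept)
    epoch_confusion(windows, ref_bouts,
                    dplyr::filter(bouts, .data$source == dn),
                    epoch_s = config$epoch_s)
  }))
  if (!is.null(cohort_of) && nrow(confusion)) {
    confusion <- dplyr::left_join(confusion, cohort_of, by = "participant_id")
  }
  has_cohort <- "cohort" %in% names(confusion)
  metrics_cohort <- if (nrow(confusion)) {
    pool_and_score(confusion, by = c("source", if (has_cohort) "cohort"))
  }
  metrics_overall <- if (nrow(confusion)) pool_and_score(confusion, by = "source")
  metrics_participant <- if (nrow(confusion)) {
    pool_and_score(confusion, by = c("source", "participant_id"))
  }

  # --- stage 5: night outcomes -----------------------------------------------
  # Reference TSO also hosts the single-rater outcome tracks (raters label
  # scratching within the same consensus window).
  tso_for <- function(src) {
    d <- dplyr::mutate(ref_kept, source = src)
    d
  }
  outcome_tso <- dplyr::bind_rows(
    lapply(c(ref, config$tso_rater_sources), tso_for),
    dplyr::filter(kept_tso, .data$source %in% devices))
  night_sum <- night_summary(bouts, outcome_tso)
  if (!is.null(nights_tbl) && all(c("participant_id", "night_id") %in% names(nights_tbl))) {
    night_sum <- dplyr::left_join(
      night_sum,
      dplyr::select(nights_tbl, "participant_id", "night_id",
                    dplyr::any_of(c("cohort", "date"))),
      by = c("participant_id", "night_id"))
  }
  part_sum <- participant_summary(night_sum, delta = config$delta)
  ref_part <- dplyr::filter(part_sum, .data$source == ref)
  cohort_sum <- if ("cohort" %in% names(ref_part)) {
    group_summary(ref_part, by = "cohort")
  }

  pro <- study$pro
  itch_sum <- NULL
  itch_nights <- NULL
  if (!is.null(pro) && nrow(pro)) {
    valid <- filter_pro_responses(pro, window = config$pro_window)
    ref_nights <- dplyr::filter(night_sum, .data$source == ref)
    itch_nights <- stratify_by_itch(ref_nights, valid, bands = config$itch_bands)
    if (nrow(itch_nights)) {
      itch_sum <- group_summary(itch_nights, by = "itch_band")
    }
  }

  # --- stage 6: agreement ----------------------------------------------------
  ref_dur <- dplyr::transmute(ref_kept, .data$participant_id, .data$night_id,
                              ref_tso_hours = .data$duration_h)
  ba <- purrr::imap(
    stats::setNames(devices, devices), function(dn, nm) {
      dht_dur <- dplyr::transmute(
        dplyr::filter(kept_tso, .data$source == dn),
        .data$participant_id, .data$night_id,
        dht_tso_hours = .data$duration_h)
      pairs <- dplyr::inner_join(ref_dur, dht_dur,
                                 by = c("participant_id", "night_id"))
      bland_altman_repeated(pairs, n_boot = config$n_boot,
                            seed = config$seed + match(dn, devices))
    })
  ba_table <- dplyr::bind_rows(purrr::imap(ba, function(b, dn) {
    tibble::tibble(source = dn, bias = b$bias, loa_low = b$loa_low,
                   loa_high = b$loa_high, n_pairs = b$n_pairs,
                   n_participants = b$n_participants)
  }))

  comparisons <- c(lapply(devices, function(d) c(ref, d)),
                   list(config$tso_rater_sources))
  icc_fits <- list()
  icc_rows <- list()
  k <- 0L
  for (cmp in comparisons) {
    for (oc in c("norm_duration", "norm_frequency")) {
      k <- k + 1L
      sub <- dplyr::filter(night_sum, .data$source %in% cmp)
      # complete pairs only
      cnt <- dplyr::add_count(sub, .data$participant_id, .data$night_id)
      sub <- dplyr::filter(cnt, .data$n == length(cmp))
      dat <- dplyr::transmute(sub, .data$participant_id, .data$night_id,
                              .data$source,
                              y = log(.data[[oc]] + config$delta))
      fit <- bootstrap_icc(dat, n_boot = config$n_boot,
                           seed = config$seed + 100L + k)
      nm <- paste(paste(cmp, collapse = " vs "), oc, sep = " / ")
      icc_fits[[nm]] <- fit
      icc_rows[[nm]] <- dplyr::mutate(fit$estimates,
                                      comparison = paste(cmp, collapse = " vs "),
                                      outcome = oc, .before = 1)
    }
  }
  icc_table <- dplyr::bind_rows(icc_rows)

  structure(
    list(consensus_provenance = cons$provenance,
         tso = tso_flagged,
         tso_exclusions = tso_log,
         confusion_nights = confusion,
         metrics_cohort = metrics_cohort,
         metrics_overall = metrics_overall,
         metrics_participant = metrics_participant,
         night_summaries = night_sum,
         participant_summaries = part_sum,
         cohort_summaries = cohort_sum,
         itch_nights = itch_nights,
         itch_summaries = itch_sum,
         bland_altman = ba,
         bland_altman_table = ba_table,
         icc = icc_fits,
         icc_table = icc_table,
         config = config),
    class = "scratch_report")
}

#' @export
print.scratch_report <- function(x, ...) {
  cat("Nocturnal scratch validation report\n")
  cat(sprintf("  nights analysed: %d (excluded: %d)\n",
              sum(!x$tso$excluded[x$tso$source == x$config$reference_source]),
              sum(x$tso$excluded)))
  if (!is.null(x$metrics_cohort)) {
    cat("  epoch metrics (cohort level):\n")
    print(dplyr::select(x$metrics_cohort, dplyr::any_of(
      c("source", "cohort", "sensitivity", "precision", "f1",
        "balanced_accuracy", "prevalence"))))
  }
  cat("  Bland-Altman TSO duration:\n")
  print(x$bland_altman_table)
  cat("  ICC (night-level outcomes):\n")
  print(x$icc_table)
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits the report's tables as CSVs plus a provenance JSON carrying the
#' full configuration.
#'
#' @param report A `scratch_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- c("consensus_provenance", "tso", "tso_exclusions",
            "metrics_cohort", "metrics_overall", "metrics_participant",
            "night_summaries", "participant_summaries", "cohort_summaries",
            "itch_summaries", "bland_altman_table", "icc_table")
  for (nm in tabs) {
    if (!is.null(report[[nm]])) {
      readr::write_csv(report[[nm]], file.path(dir, paste0(nm, ".csv")))
    }
  }
  write_provenance(report$config, file.path(dir, "provenance.json"))
  invisible(dir)
}
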