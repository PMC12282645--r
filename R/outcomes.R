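# Night-level scratch outcomes, participant summaries, and itch
# stratification.
#
# The two primary outcomes are normalized to the TSO window so that changes
# in sleep time do not drive them: scratch duration in seconds of scratch
# per hour of TSO, and scratch frequency in bouts per hour of TSO. Both are
# right-skewed, so participant-level summaries use geometric means and
# model-based agreement works on the log scale.

#' Night-level normalized scratch outcomes
#'
#' Joins merged + filtered scratch tracks to their kept TSO windows and
#' computes, per (participant, night, source): total scratch seconds, bout
#' count, TSO hours, normalized duration (s of scratch per h of TSO) and
#' normalized frequency (bouts per h of TSO). Nights present in `tso` but
#' with no scratch rows score zero on both outcomes.
#'
#' @param scratch Events table of scratch bouts, already passed through
#'   [merge_gaps()] and [filter_min_duration()].
#' @param tso TSO table (one row per participant-night-source). Rows flagged
#'   `excluded = TRUE` are rejected: excluded nights are never summarized.
#' @return A tibble with one row per TSO row: identifiers, `tso_hours`,
#'   `scratch_seconds`, `bout_count`, `norm_duration`, `norm_frequency`.
#' @export
night_summary <- function(scratch, tso) {
  validate_events(tso)
  if ("excluded" %in% names(tso) && any(tso$excluded)) {
    stop_scratchval("`tso` contains excluded nights; filter them out first.")
  }
  keys <- intersect(c("participant_id", "night_id", "source"), names(tso))
  per_night <- if (nrow(scratch) > 0) {
    validate_events(scratch)
    dplyr::summarise(
      dplyr::group_by(scratch, dplyr::across(dplyr::all_of(intersect(keys, names(scratch))))),
      scratch_seconds = sum(.data$end_s - .data$start_s),
      bout_count = dplyr::n(),
      .groups = "drop")
  } else {
    tibble::tibble(scratch_seconds = numeric(), bout_count = integer())
  }
  tso_sel <- dplyr::select(tibble::as_tibble(tso), dplyr::all_of(keys),
                           dplyr::any_of(c("cohort", "date")), "start_s", "end_s")
  join_keys <- intersect(keys, names(per_night))
  out <- if (length(join_keys)) {
    dplyr::left_join(tso_sel, per_night, by = join_keys)
  } else {
    dplyr::mutate(tso_sel, scratch_seconds = NA_real_, bout_count = NA_integer_)
  }
  dplyr::transmute(
    out,
    dplyr::across(dplyr::all_of(intersect(c(keys, "cohort", "date"), names(out)))),
    tso_hours = (.data$end_s - .data$start_s) / 3600,
    scratch_seconds = dplyr::coalesce(.data$scratch_seconds, 0),
    bout_count = dplyr::coalesce(.data$bout_count, 0L),
    norm_duration = .data$scratch_seconds / .data$tso_hours,
    norm_frequency = .data$bout_count / .data$tso_hours)
}

#' Offset geometric mean
#'
#' `exp(mean(log(x + delta))) - delta`: the geometric mean after shifting by
#' `delta`, which keeps zero-valued observations in the summary. `delta = 0`
#' gives the plain geometric mean.
#'
#' @param x Non-negative numeric vector.
#' @param delta Non-negative offset in original units (default 1).
#' @return A single number.
#' @export
geometric_mean <- function(x, delta = 1) {
  check_number(delta, "delta", min = 0)
  if (length(x) == 0L) stop_scratchval("empty input to geometric_mean().")
  if (any(x + delta <= 0)) stop_scratchval("x + delta must be positive.")
  exp(mean(log(x + delta))) - delta
}

#' Participant-level geometric-mean summaries
#'
#' Summarizes night-level outcomes to one row per participant (and source,
#' if present) using the offset geometric mean of each normalized outcome
#' over that participant's nights.
#'
#' @param nights Output of [night_summary()].
#' @param delta Offset applied inside the log (see [geometric_mean()]);
#'   default 1 in original units.
#' @return One row per participant (x source): `n_nights`, `norm_duration`,
#'   `norm_frequency` (geometric means); `cohort` carried through when
#'   present.
#' @export
participant_summary <- function(nights, delta = 1) {
  if (nrow(nights) == 0L) stop_scratchval("no nights to summarize.")
  keys <- intersect(c("participant_id", "source", "cohort"), names(nights))
  dplyr::summarise(
    dplyr::group_by(nights, dplyr::across(dplyr::all_of(keys))),
    n_nights = dplyr::n(),
    norm_duration = geometric_mean(.data$norm_duration, delta),
    norm_frequency = geometric_mean(.data$norm_frequency, delta),
    .groups = "drop")
}

#' Group medians and IQRs of the scratch outcomes
#'
#' Distribution summaries on the linear scale in original units, one row per
#' group and outcome.
#'
#' @param summaries Participant- or night-level summaries carrying
#'   `norm_duration` and `norm_frequency`.
#' @param by Character vector of grouping columns (e.g. `"cohort"` or an
#'   itch band).
#' @return A tibble: grouping columns, `outcome`, `n`, `median`, `q1`, `q3`.
#' @export
group_summary <- function(summaries, by = "cohort") {
  miss <- setdiff(by, names(summaries))
  if (length(miss)) stop_scratchval("grouping column(s) not found: %s.",
                                    paste(miss, collapse = ", "))
  long <- tidyr::pivot_longer(
    dplyr::select(summaries, dplyr::all_of(by), "norm_duration", "norm_frequency"),
    cols = c("norm_duration", "norm_frequency"),
    names_to = "outcome", values_to = "value")
  dplyr::summarise(
    dplyr::group_by(long, dplyr::across(dplyr::all_of(c(by, "outcome")))),
    n = dplyr::n(),
    median = stats::median(.data$value),
    q1 = unname(stats::quantile(.data$value, 0.25)),
    q3 = unname(stats::quantile(.data$value, 0.75)),
    .groups = "drop")
}

#' Filter patient-reported itch responses to valid morning administrations
#'
#' Keeps morning administrations whose timestamp falls inside the validity
#' window (default 4 AM to 12 PM, inclusive at both ends). If a participant
#' recorded more than one morning response on the same day, all of that
#' day's responses are dropped.
#'
#' @param responses Tibble with `participant_id`, `date`, `administration`
#'   (`"morning"`/`"evening"`), `timestamp` (clock time `"HH:MM[:SS]"`, or a
#'   datetime whose time part is used) and `itch_nrs` (0-10).
#' @param window Length-2 clock times bounding validity (default
#'   `c("04:00", "12:00")`).
#' @return The valid morning responses.
#' @export
filter_pro_responses <- function(responses, window = c("04:00", "12:00")) {
  need <- c("participant_id", "date", "administration", "timestamp", "itch_nrs")
  miss <- setdiff(need, names(responses))
  if (length(miss)) stop_scratchval("PRO table missing column(s): %s.",
                                    paste(miss, collapse = ", "))
  if (any(responses$itch_nrs < 0 | responses$itch_nrs > 10, na.rm = TRUE)) {
    stop_scratchval("itch_nrs outside 0-10.")
  }
  bounds <- clock_to_seconds(window)
  ts <- sub("^.*[T ]", "", as.character(responses$timestamp))
  tod <- clock_to_seconds(ts)
  morning <- responses$administration == "morning"
  # duplicate-day rule first: >1 morning response on a participant-day voids
  # the whole day
  day_key <- paste(responses$participant_id, responses$date)
  n_morning <- stats::ave(as.integer(morning), day_key, FUN = sum)
  keep <- morning & n_morning == 1L & !is.na(tod) &
    tod >= bounds[1] & tod <= bounds[2]
  responses[keep, , drop = FALSE]
}

#' Default itch severity bands
#'
#' Conventional numeric-rating-scale severity bands: 0 no itch, 1-3 mild,
#' 4-6 moderate, 7-10 severe. Integer edges, inclusive on both sides.
#'
#' @return A tibble with `band`, `lo`, `hi`.
#' @export
itch_bands <- function() {
  tibble::tibble(band = c("no itch", "mild", "moderate", "severe"),
                 lo = c(0, 1, 4, 7),
                 hi = c(0, 3, 6, 10))
}

#' Stratify night summaries by reported itch
#'
#' Assigns each night to the itch band of the valid morning response that
#' refers to it. The morning response on date D reports on the preceding
#' night, so it joins to the night whose (evening) `date` is D minus one
#' day; when both tables carry `night_id`, the join uses
#' (`participant_id`, `night_id`) directly. Nights without a valid PRO are
#' unassigned and dropped from the stratified view.
#'
#' @param nights Night-level summaries (see [night_summary()]); for the
#'   date join they must carry a `date` column (the evening date the night
#'   began).
#' @param valid_pros Output of [filter_pro_responses()].
#' @param bands Band definition tibble (`band`, `lo`, `hi`); must partition
#'   without overlap. Default [itch_bands()].
#' @return `nights` restricted to assigned nights, with `itch_nrs` and
#'   `itch_band` added (`itch_band` is a factor in band order).
#' @export
stratify_by_itch <- function(nights, valid_pros, bands = itch_bands()) {
  if (any(bands$hi < bands$lo)) stop_scratchval("band with hi < lo.")
  o <- order(bands$lo)
  if (any(bands$lo[o][-1] <= bands$hi[o][-nrow(bands)])) {
    stop_scratchval("itch bands overlap.")
  }
  use_night_id <- all(c("night_id") %in% names(valid_pros)) &&
    "night_id" %in% names(nights)
  if (use_night_id) {
    pro <- dplyr::select(valid_pros, "participant_id", "night_id", "itch_nrs")
    joined <- dplyr::inner_join(nights, pro, by = c("participant_id", "night_id"))
  } else {
    if (!"date" %in% names(nights)) {
      stop_scratchval("`nights` needs a `date` column (or both tables a `night_id`) to join PROs.")
    }
    pro <- dplyr::mutate(
      dplyr::select(valid_pros, "participant_id", "date", "itch_nrs"),
      date = as.Date(.data$date) - 1)
    joined <- dplyr::inner_join(
      dplyr::mutate(nights, date = as.Date(.data$date)), pro,
      by = c("participant_id", "date"))
  }
  band_of <- function(v) {
    i <- vapply(v, function(z) {
      hit <- which(z >= bands$lo & z <= bands$hi)
      if (length(hit) == 1L) hit else NA_integer_
    }, integer(1))
    factor(bands$band[i], levels = bands$band)
  }
  out <- dplyr::mutate(joined, itch_band = band_of(.data$itch_nrs))
  dplyr::filter(out, !is.na(.data$itch_band))
}
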