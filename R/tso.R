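# Total sleep opportunity (TSO) derivation and exclusion rules.

#' Derive a device TSO window from detected sleep periods
#'
#' Per (participant, night, source) track of device sleep periods, merges
#' periods separated by a gap strictly shorter than `merge_gap_min` minutes
#' and returns the longest merged period as the night's TSO. Nights with no
#' sleep periods simply produce no row (the night is unusable for that
#' source).
#'
#' @param sleep_periods Events table of device sleep periods
#'   (`kind = "sleep_period"`).
#' @param merge_gap_min Gap threshold in minutes; gaps strictly below it are
#'   merged (default 30).
#' @return A tibble with one TSO row per track: identifier columns,
#'   `kind = "tso"`, `start_s`, `end_s`.
#' @export
derive_device_tso <- function(sleep_periods, merge_gap_min = 30) {
  check_number(merge_gap_min, "merge_gap_min", min = 0)
  merged <- merge_gaps(sleep_periods, max_gap_s = 60 * merge_gap_min)
  keys <- event_keys(merged, exclude = "kind")
  if (length(keys) == 0L) {
    if (nrow(merged) == 0L) {
      return(tibble::tibble(kind = character(), start_s = numeric(), end_s = numeric()))
    }
    best <- which.max(merged$end_s - merged$start_s)
    return(tibble::tibble(kind = "tso",
                          start_s = merged$start_s[best],
                          end_s = merged$end_s[best]))
  }
  out <- dplyr::slice_max(
    dplyr::group_by(merged, dplyr::across(dplyr::all_of(keys))),
    .data$end_s - .data$start_s, n = 1, with_ties = FALSE)
  out <- dplyr::ungroup(out)
  out$kind <- "tso"
  dplyr::select(out, dplyr::all_of(keys), "kind", "start_s", "end_s")
}

#' Flag short TSO windows for exclusion
#'
#' Any TSO with a duration strictly below `min_hours` (default 3.5 h) is not
#' considered representative of a nightly sleep period and is flagged
#' excluded. A window of exactly `min_hours` is kept. Exclusion is applied
#' independently per source, so a night can be kept for the Reference but
#' dropped for one device.
#'
#' @param tso Table of TSO windows (`start_s`, `end_s` plus identifiers).
#' @param min_hours Minimum TSO duration in hours (strict lower bound for
#'   exclusion; default 3.5).
#' @return The input with `duration_h`, `excluded` and `exclusion_reason`
#'   columns added. Use [tso_exclusion_log()] for per-source counts and
#'   `dplyr::filter(!excluded)` for the analysis set.
#' @export
exclude_short_tso <- function(tso, min_hours = 3.5) {
  check_number(min_hours, "min_hours", min = 0)
  validate_events(tso)
  out <- dplyr::mutate(
    tibble::as_tibble(tso),
    duration_h = (.data$end_s - .data$start_s) / 3600,
    excluded = .data$duration_h < min_hours,
    exclusion_reason = dplyr::if_else(
      .data$excluded, sprintf("TSO < %.4g h", min_hours), NA_character_))
  out
}

#' Per-source TSO exclusion counts
#'
#' @param tso_flagged Output of [exclude_short_tso()].
#' @return A tibble per source: nights in, nights excluded, nights kept, and
#'   the excluded proportion.
#' @export
tso_exclusion_log <- function(tso_flagged) {
  if (!all(c("excluded") %in% names(tso_flagged))) {
    stop_scratchval("`tso_flagged` must come from exclude_short_tso().")
  }
  keys <- intersect("source", names(tso_flagged))
  dplyr::summarise(
    dplyr::group_by(tso_flagged, dplyr::across(dplyr::all_of(keys))),
    n_nights = dplyr::n(),
    n_excluded = sum(.data$excluded),
    n_kept = sum(!.data$excluded),
    prop_excluded = .data$n_excluded / .data$n_nights,
    .groups = "drop")
}

#' Paired TSO overlap window for within-night comparison
#'
#' Joins the Reference and a DHT's kept TSO windows by night and returns the
#' interval intersection — the window over which epoch-level comparison is
#' performed. Nights where the windows do not overlap (or where either side
#' is missing or excluded) produce no row.
#'
#' @param ref,dht TSO tables (rows flagged `excluded` must be filtered out
#'   first; rows with `excluded = TRUE` raise an error).
#' @return A tibble keyed by the shared identifiers with the intersection
#'   window in `start_s`, `end_s` and the DHT's `source`.
#' @export
paired_overlap_window <- function(ref, dht) {
  for (d in list(ref, dht)) {
    if ("excluded" %in% names(d) && any(d$excluded)) {
      stop_scratchval("excluded TSO rows must be removed before pairing.")
    }
  }
  validate_events(ref)
  validate_events(dht)
  keys <- intersect(c("participant_id", "night_id"), intersect(names(ref), names(dht)))
  sel <- function(d) dplyr::select(d, dplyr::all_of(keys),
                                   dplyr::any_of("source"), "start_s", "end_s")
  joined <- dplyr::inner_join(sel(ref), sel(dht), by = keys,
                              suffix = c("_ref", "_dht"))
  inter <- interval_intersect(joined$start_s_ref, joined$end_s_ref,
                              joined$start_s_dht, joined$end_s_dht)
  out <- dplyr::bind_cols(joined[keys],
                          if ("source_dht" %in% names(joined)) {
                            tibble::tibble(source = joined$source_dht)
                          },
                          inter)
  dplyr::filter(out, !is.na(.data$start_s))
}
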