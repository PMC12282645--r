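# Interval algebra on half-open event intervals.
#
# Every time in the package is expressed in real-valued seconds from a
# per-night origin (noon of the evening the night begins), so times within a
# night are positive and increase monotonically across midnight. Intervals
# are half-open [start_s, end_s): adjacency and duration arithmetic are then
# unambiguous and a touching pair carries no shared time.

# ---- low-level vector kernels (single track) --------------------------------

# Sort intervals and coalesce. With `strict = FALSE` intervals that overlap
# or touch (gap <= `gap`) are fused; with `strict = TRUE` fusion requires
# gap strictly < `gap` (the bout-merging rule).
coalesce_intervals <- function(start, end, gap = 0, strict = FALSE) {
  n <- length(start)
  if (n == 0L) return(list(start = numeric(), end = numeric()))
  ord <- order(start, end)
  s <- start[ord]
  e <- end[ord]
  prev_end <- c(-Inf, cummax(e)[-n])
  brk <- if (strict) (s - prev_end) >= gap else (s - prev_end) > gap
  brk[1L] <- TRUE
  grp <- cumsum(brk)
  list(start = s[brk],
       end = as.numeric(tapply(e, grp, max)))
}

# Interval-set intersection of two normalized tracks (all pairs; tracks are
# short so the quadratic sweep is cheap and stays exact).
intersect_sets <- function(s1, e1, s2, e2) {
  if (length(s1) == 0L || length(s2) == 0L) {
    return(list(start = numeric(), end = numeric()))
  }
  os <- outer(s1, s2, pmax)
  oe <- outer(e1, e2, pmin)
  keep <- oe > os
  out <- coalesce_intervals(os[keep], oe[keep])
  out
}

track_duration <- function(start, end) sum(end - start)

# IoU of two normalized tracks; 1 when both are empty (shared "no event"
# annotation is perfect agreement, not undefined).
iou_pair <- function(s1, e1, s2, e2) {
  d1 <- track_duration(s1, e1)
  d2 <- track_duration(s2, e2)
  if (d1 == 0 && d2 == 0) return(1)
  inter <- intersect_sets(s1, e1, s2, e2)
  di <- track_duration(inter$start, inter$end)
  di / (d1 + d2 - di)
}

# ---- validation -------------------------------------------------------------

#' Validate an events table
#'
#' Checks that `x` carries numeric, finite `start_s`/`end_s` columns and that
#' every interval has strictly positive length (intervals are half-open
#' `[start_s, end_s)`, so zero-length intervals are invalid).
#'
#' @param x A data frame with `start_s` and `end_s` columns (identifier
#'   columns `participant_id`, `night_id`, `source`, `kind` are optional and
#'   passed through).
#' @return `x`, invisibly, if valid; otherwise an error naming the offending
#'   rows.
#' @export
validate_events <- function(x) {
  if (!is.data.frame(x)) stop_scratchval("events must be a data frame.")
  miss <- setdiff(c("start_s", "end_s"), names(x))
  if (length(miss)) {
    stop_scratchval("events table is missing column(s): %s.",
                    paste(miss, collapse = ", "))
  }
  if (!is.numeric(x$start_s) || !is.numeric(x$end_s)) {
    stop_scratchval("`start_s` and `end_s` must be numeric.")
  }
  bad <- which(!is.finite(x$start_s) | !is.finite(x$end_s) |
                 x$end_s <= x$start_s)
  if (length(bad)) {
    stop_scratchval(
      "invalid interval(s) (end_s <= start_s or non-finite) at row(s): %s.",
      paste(utils::head(bad, 10), collapse = ", "))
  }
  invisible(x)
}

# Apply a per-track kernel over a long events table, preserving key columns.
map_tracks <- function(x, fn) {
  keys <- event_keys(x)
  if (length(keys) == 0L) {
    out <- fn(x$start_s, x$end_s)
    return(tibble::tibble(start_s = out$start, end_s = out$end))
  }
  dplyr::reframe(
    dplyr::group_by(x, dplyr::across(dplyr::all_of(keys))),
    {
      out <- fn(.data$start_s, .data$end_s)
      tibble::tibble(start_s = out$start, end_s = out$end)
    }
  )
}

# ---- exported verbs ---------------------------------------------------------

#' Normalize raw event intervals into canonical tracks
#'
#' Sorts intervals by start time and coalesces overlapping or touching
#' intervals within each track (a track is one combination of the identifier
#' columns present: `participant_id`, `night_id`, `source`, `kind`). The
#' total covered duration is preserved.
#'
#' @inheritParams validate_events
#' @return A tibble with one row per canonical interval, sorted within track.
#' @examples
#' normalize_events(tibble::tibble(start_s = c(0, 3), end_s = c(5, 8)))
#' @export
normalize_events <- function(x) {
  validate_events(x)
  map_tracks(x, function(s, e) coalesce_intervals(s, e, gap = 0, strict = FALSE))
}

#' Merge events separated by short gaps into bouts
#'
#' Consecutive intervals within a track whose gap is strictly less than
#' `max_gap_s` are fused (transitively) into a single bout; a gap of exactly
#' `max_gap_s` is kept. The default 3 s is the bout definition used for
#' nocturnal scratching: scratch events with a <3 s gap form one scratching
#' bout.
#'
#' @param x A normalized events table (see [normalize_events()]).
#' @param max_gap_s Maximum gap, in seconds, strictly below which two events
#'   merge. Must be non-negative.
#' @return A tibble of merged bouts; the bout count never increases and the
#'   total covered duration never decreases.
#' @examples
#' merge_gaps(tibble::tibble(start_s = c(0, 3), end_s = c(2, 6)))   # -> [0, 6)
#' merge_gaps(tibble::tibble(start_s = c(0, 5), end_s = c(2, 6)))   # unchanged
#' @export
merge_gaps <- function(x, max_gap_s = 3) {
  check_number(max_gap_s, "max_gap_s", min = 0)
  validate_events(x)
  map_tracks(x, function(s, e) {
    out <- coalesce_intervals(s, e, gap = 0, strict = FALSE)
    coalesce_intervals(out$start, out$end, gap = max_gap_s, strict = TRUE)
  })
}

#' Drop events shorter than a minimum duration
#'
#' Retains intervals whose duration is at least `min_dur_s` (inclusive:
#' an event of exactly `min_dur_s` is kept). Applied after [merge_gaps()]
#' in the scratch-outcome pipeline: first merge, then filter.
#'
#' @inheritParams merge_gaps
#' @param min_dur_s Minimum duration in seconds (inclusive). Must be
#'   non-negative; default 2 s.
#' @return A tibble containing only the retained intervals.
#' @export
filter_min_duration <- function(x, min_dur_s = 2) {
  check_number(min_dur_s, "min_dur_s", min = 0)
  validate_events(x)
  dplyr::filter(x, .data$end_s - .data$start_s >= min_dur_s)
}

#' Total covered duration per track
#'
#' @inheritParams merge_gaps
#' @return A tibble with the identifier columns present in `x` and a
#'   `duration_s` column (a single row when `x` has no identifier columns).
#'   Tracks are normalized first, so overlapping raw intervals are not
#'   double-counted.
#' @export
total_duration <- function(x) {
  validate_events(x)
  keys <- event_keys(x)
  norm <- normalize_events(x)
  if (length(keys) == 0L) {
    return(tibble::tibble(duration_s = track_duration(norm$start_s, norm$end_s)))
  }
  dplyr::summarise(
    dplyr::group_by(norm, dplyr::across(dplyr::all_of(keys))),
    duration_s = sum(.data$end_s - .data$start_s),
    .groups = "drop")
}

#' Pairwise intersection of two half-open intervals
#'
#' Vectorized over its arguments. Returns the intersection
#' `[max(starts), min(ends))` where it has positive length and `NA` rows
#' otherwise (half-open semantics: touching intervals share nothing).
#'
#' @param a_start,a_end,b_start,b_end Numeric vectors of interval endpoints.
#' @return A tibble with `start_s`, `end_s` (`NA` where the intersection is
#'   empty).
#' @export
interval_intersect <- function(a_start, a_end, b_start, b_end) {
  s <- pmax(a_start, b_start)
  e <- pmin(a_end, b_end)
  empty <- !(e > s)
  s[empty] <- NA_real_
  e[empty] <- NA_real_
  tibble::tibble(start_s = s, end_s = e)
}

# Match two event tables into per-track pairs over their shared keys
# (excluding `source`, which distinguishes the two annotation streams).
pair_tracks <- function(x, y) {
  keys <- union(event_keys(x, exclude = "source"),
                event_keys(y, exclude = "source"))
  if (length(keys) == 0L) {
    return(list(keys = tibble::tibble(.rows = 1L),
                x = list(x), y = list(y)))
  }
  miss_x <- setdiff(keys, names(x))
  miss_y <- setdiff(keys, names(y))
  if (length(miss_x) || length(miss_y)) {
    stop_scratchval(
      "both event tables must carry the same identifier columns to be compared (missing: %s).",
      paste(unique(c(miss_x, miss_y)), collapse = ", "))
  }
  gx <- tidyr::nest(dplyr::select(x, -dplyr::any_of("source")),
                    .x = -dplyr::all_of(keys))
  gy <- tidyr::nest(dplyr::select(y, -dplyr::any_of("source")),
                    .y = -dplyr::all_of(keys))
  joined <- dplyr::full_join(gx, gy, by = keys)
  empty <- tibble::tibble(start_s = numeric(), end_s = numeric())
  joined$.x <- lapply(joined$.x, function(d) d %||% empty)
  joined$.y <- lapply(joined$.y, function(d) d %||% empty)
  list(keys = joined[keys], x = joined$.x, y = joined$.y)
}

#' Interval-set intersection of two event tables
#'
#' Intersects the two annotation streams track by track, matching tracks on
#' the identifier columns the tables share apart from `source`. Used, for
#' example, to take the intersection of two raters' scratch labels as the
#' consensus annotation.
#'
#' @param x,y Normalized events tables covering the same nights.
#' @return A tibble of intersection intervals with the shared identifier
#'   columns.
#' @export
intersect_events <- function(x, y) {
  validate_events(x)
  validate_events(y)
  p <- pair_tracks(normalize_events(x), normalize_events(y))
  res <- purrr::map2(p$x, p$y, function(a, b) {
    out <- intersect_sets(a$start_s, a$end_s, b$start_s, b$end_s)
    tibble::tibble(start_s = out$start, end_s = out$end)
  })
  dplyr::bind_rows(
    purrr::map2(seq_along(res), res, function(i, d) {
      if (ncol(p$keys) == 0) return(d)
      dplyr::bind_cols(p$keys[rep(i, nrow(d)), , drop = FALSE], d)
    })
  )
}

#' Intersection over union of two event tables
#'
#' Duration of the intersection divided by duration of the union, computed
#' per matched track. Defined as 1 when both tracks are empty: a segment in
#' which neither annotator marks an event is agreement on "no event". Always
#' in `[0, 1]` and symmetric in its arguments.
#'
#' @inheritParams intersect_events
#' @return A tibble with the shared identifier columns and an `iou` column.
#' @export
iou <- function(x, y) {
  validate_events(x)
  validate_events(y)
  p <- pair_tracks(normalize_events(x), normalize_events(y))
  vals <- purrr::map2_dbl(p$x, p$y, function(a, b) {
    iou_pair(a$start_s, a$end_s, b$start_s, b$end_s)
  })
  dplyr::bind_cols(p$keys, tibble::tibble(iou = vals))
}
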