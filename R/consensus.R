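# Reference construction from multiple human raters.
#
# Scratch bouts: two raters label independently; if their IoU exceeds a
# threshold the intersection of their labels is the consensus. Otherwise two
# further raters repeat the exercise (round 2), and failing that a fifth
# rater decides (round 3). TSO: two raters mark start/end; if either endpoint
# differs by more than a tolerance a third rater adjudicates, otherwise the
# endpoints are averaged.

#' Multi-round scratch-bout consensus
#'
#' Builds the consensus ("Reference") scratch annotation from up to five
#' rater streams, per track (one combination of `participant_id`,
#' `night_id`, and `segment_id` if present). Round 1 compares the first two
#' raters: if their intersection-over-union strictly exceeds `threshold`,
#' the interval-set intersection of their labels is the consensus. Round 2
#' repeats this with raters three and four. If neither round reaches
#' consensus, the fifth rater's labels are taken verbatim (round 3).
#'
#' An empty track for a listed rater is a legitimate annotation ("no
#' scratching seen"); rounds that would need raters not listed in
#' `rater_sources` raise an error naming the round.
#'
#' @param raters Events table of rater scratch annotations with a `source`
#'   column whose values include the entries of `rater_sources`.
#' @param threshold IoU value that must be strictly exceeded for a round to
#'   reach consensus (default 0.765).
#' @param rater_sources Character vector naming the rater streams in round
#'   order: raters 1-2 (round 1), 3-4 (round 2), 5 (round 3).
#' @param reference_source Value written to the `source` column of the
#'   consensus track.
#' @return A list with components
#'   \describe{
#'     \item{reference}{events tibble of the consensus annotation,}
#'     \item{provenance}{one row per track: `round_reached` (1, 2 or 3),
#'       `iou_round1`, `iou_round2` (`NA` when round 2 was not needed).}
#'   }
#' @export
bout_consensus <- function(raters, threshold = 0.765,
                           rater_sources = c("R1", "R2", "R3", "R4", "R5"),
                           reference_source = "Reference") {
  validate_events(raters)
  if (!"source" %in% names(raters)) {
    stop_scratchval("`raters` must have a `source` column.")
  }
  check_number(threshold, "threshold", min = 0)
  if (length(rater_sources) < 2L) {
    stop_scratchval("at least two rater sources are required for round 1.")
  }
  extra <- setdiff(unique(raters$source), rater_sources)
  if (length(extra)) {
    stop_scratchval("unknown rater source(s): %s.", paste(extra, collapse = ", "))
  }

  keys <- event_keys(raters, exclude = c("source", "kind"))
  raters <- normalize_events(raters)
  # One row per track; each rater's intervals as a nested pair of vectors.
  grp <- if (length(keys)) {
    dplyr::group_split(dplyr::group_by(raters, dplyr::across(dplyr::all_of(keys))))
  } else {
    list(raters)
  }

  one_track <- function(d) {
    get_rater <- function(src) {
      r <- d[d$source == src, , drop = FALSE]
      list(s = r$start_s, e = r$end_s)
    }
    r <- lapply(rater_sources, get_rater)
    iou1 <- iou_pair(r[[1]]$s, r[[1]]$e, r[[2]]$s, r[[2]]$e)
    if (iou1 > threshold) {
      fin <- intersect_sets(r[[1]]$s, r[[1]]$e, r[[2]]$s, r[[2]]$e)
      return(list(final = fin, round = 1L, iou1 = iou1, iou2 = NA_real_))
    }
    if (length(rater_sources) < 4L) {
      stop_scratchval(
        "round 2 required but raters 3 and 4 are not available (round 1 IoU %.3f <= %.3f).",
        iou1, threshold)
    }
    iou2 <- iou_pair(r[[3]]$s, r[[3]]$e, r[[4]]$s, r[[4]]$e)
    if (iou2 > threshold) {
      fin <- intersect_sets(r[[3]]$s, r[[3]]$e, r[[4]]$s, r[[4]]$e)
      return(list(final = fin, round = 2L, iou1 = iou1, iou2 = iou2))
    }
    if (length(rater_sources) < 5L) {
      stop_scratchval(
        "round 3 required but rater 5 is not available (round 2 IoU %.3f <= %.3f).",
        iou2, threshold)
    }
    list(final = list(start = r[[5]]$s, end = r[[5]]$e),
         round = 3L, iou1 = iou1, iou2 = iou2)
  }

  res <- lapply(grp, one_track)
  key_rows <- lapply(grp, function(d) {
    if (length(keys)) d[1, keys, drop = FALSE] else tibble::tibble(.rows = 1L)
  })
  provenance <- dplyr::bind_cols(
    dplyr::bind_rows(key_rows),
    tibble::tibble(
      round_reached = vapply(res, `[[`, integer(1), "round"),
      iou_round1 = vapply(res, `[[`, numeric(1), "iou1"),
      iou_round2 = vapply(res, `[[`, numeric(1), "iou2")))
  reference <- dplyr::bind_rows(purrr::map2(key_rows, res, function(k, x) {
    n <- length(x$final$start)
    dplyr::bind_cols(
      k[rep(1L, n), , drop = FALSE],
      tibble::tibble(source = rep(reference_source, n),
                     kind = rep("scratch", n),
                     start_s = x$final$start, end_s = x$final$end))
  }))
  list(reference = reference, provenance = provenance)
}

#' TSO consensus between two raters with adjudication
#'
#' Per night, compares the two round-1 raters' total-sleep-opportunity (TSO)
#' windows. If both the start and the end differ by at most `tolerance_s`
#' (default 60 s), the consensus endpoints are the means of the two raters'
#' endpoints. A larger difference at either endpoint sends the night to the
#' adjudicating rater, whose window is taken verbatim (`adjudicated = TRUE`).
#'
#' @param tso Table with one row per (night, source) TSO window: columns
#'   `start_s`, `end_s`, `source`, plus any of `participant_id`, `night_id`.
#' @param tolerance_s Maximum endpoint difference, in seconds, for the two
#'   raters to count as agreeing (inclusive; default 60).
#' @param rater_sources Length-2 character vector naming the round-1 raters.
#' @param adjudicator_source Source name of the adjudicating rater; only
#'   required for nights where the round-1 raters disagree.
#' @param reference_source Value written to the output `source` column.
#' @return A tibble with one row per night: identifier columns, `source`,
#'   `kind = "tso"`, `start_s`, `end_s`, and `adjudicated`.
#' @export
tso_consensus <- function(tso, tolerance_s = 60,
                          rater_sources = c("R1", "R2"),
                          adjudicator_source = "R3",
                          reference_source = "Reference") {
  validate_events(tso)
  check_number(tolerance_s, "tolerance_s", min = 0)
  if (!"source" %in% names(tso)) stop_scratchval("`tso` must have a `source` column.")
  if (length(rater_sources) != 2L) {
    stop_scratchval("exactly two round-1 rater sources are required.")
  }
  keys <- event_keys(tso, exclude = c("source", "kind"))
  grp <- if (length(keys)) {
    dplyr::group_split(dplyr::group_by(tso, dplyr::across(dplyr::all_of(keys))))
  } else {
    list(tso)
  }
  rows <- lapply(grp, function(d) {
    pick <- function(src) d[d$source == src, , drop = FALSE]
    r1 <- pick(rater_sources[1]); r2 <- pick(rater_sources[2])
    if (nrow(r1) != 1L || nrow(r2) != 1L) {
      stop_scratchval("each night needs exactly one TSO row per round-1 rater (%s).",
                      paste(rater_sources, collapse = ", "))
    }
    agree <- abs(r1$start_s - r2$start_s) <= tolerance_s &&
      abs(r1$end_s - r2$end_s) <= tolerance_s
    if (agree) {
      out <- tibble::tibble(start_s = mean(c(r1$start_s, r2$start_s)),
                            end_s = mean(c(r1$end_s, r2$end_s)),
                            adjudicated = FALSE)
    } else {
      adj <- pick(adjudicator_source)
      if (nrow(adj) != 1L) {
        stop_scratchval(
          "TSO adjudication required (endpoint difference > %g s) but no '%s' row present.",
          tolerance_s, adjudicator_source)
      }
      out <- tibble::tibble(start_s = adj$start_s, end_s = adj$end_s,
                            adjudicated = TRUE)
    }
    k <- if (length(keys)) d[1, keys, drop = FALSE] else tibble::tibble(.rows = 1L)
    dplyr::bind_cols(k, tibble::tibble(source = reference_source, kind = "tso"), out)
  })
  dplyr::bind_rows(rows)
}
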