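# Epoch-level scratch classification scoring.
#
# The comparison window for a night is the intersection of the Reference and
# DHT TSO windows. It is tiled with consecutive non-overlapping epochs
# (10 s primary, 1 s for the sensitivity analysis), anchored at the window
# start; a trailing partial epoch is discarded so all pooled epochs are
# comparable. An epoch is positive when any part of a scratch event overlaps
# it. Counts are pooled (summed) across nights and participants BEFORE
# metrics are computed (micro-averaging); no rebalancing of scratch and
# non-scratch epochs is done.

#' Tile a window with fixed-length epochs
#'
#' @param start_s,end_s Window endpoints in seconds (half-open).
#' @param epoch_s Epoch length in seconds (default 10; use 1 for the
#'   sensitivity analysis).
#' @return A tibble of `floor(duration / epoch_s)` epochs with columns
#'   `epoch` (1-based index), `start_s`, `end_s`; the trailing partial epoch
#'   is dropped.
#' @export
make_epochs <- function(start_s, end_s, epoch_s = 10) {
  check_number(epoch_s, "epoch_s", min = 0, allow_zero = FALSE)
  check_number(start_s, "start_s")
  check_number(end_s, "end_s")
  if (end_s <= start_s) stop_scratchval("window is empty (end_s <= start_s).")
  n <- floor((end_s - start_s) / epoch_s + 1e-9)
  if (n < 1) {
    return(tibble::tibble(epoch = integer(), start_s = numeric(), end_s = numeric()))
  }
  idx <- seq_len(n)
  tibble::tibble(epoch = idx,
                 start_s = start_s + (idx - 1) * epoch_s,
                 end_s = start_s + idx * epoch_s)
}

# Kernel: binary labels for n_epochs epochs of length epoch_s anchored at
# `origin`, positive where any event [s, e) overlaps the epoch (half-open).
label_kernel <- function(s, e, origin, n_epochs, epoch_s) {
  lab <- logical(n_epochs)
  if (length(s)) {
    rs <- (s - origin) / epoch_s
    re <- (e - origin) / epoch_s
    i0 <- pmax(1L, floor(rs + 1e-9) + 1L)
    i1 <- pmin(n_epochs, ceiling(re - 1e-9))
    for (k in seq_along(i0)) {
      if (i1[k] >= i0[k]) lab[i0[k]:i1[k]] <- TRUE
    }
  }
  as.integer(lab)
}

#' Label epochs by overlap with events
#'
#' An epoch is positive iff the interval intersection of any event with the
#' epoch is non-empty (half-open semantics: an event ending exactly at an
#' epoch boundary does not label the following epoch).
#'
#' @param epochs Epoch grid from [make_epochs()].
#' @param events Normalized, merged and filtered events table for one night
#'   and source (only `start_s`/`end_s` are used).
#' @return Integer vector of 0/1 labels, one per epoch.
#' @export
label_epochs <- function(epochs, events) {
  if (nrow(epochs) == 0L) return(integer())
  validate_events(events)
  epoch_s <- epochs$end_s[1] - epochs$start_s[1]
  label_kernel(events$start_s, events$end_s,
               origin = epochs$start_s[1],
               n_epochs = nrow(epochs), epoch_s = epoch_s)
}

#' Confusion counts for one night
#'
#' Element-wise 2x2 tally of reference vs DHT epoch labels.
#'
#' @param ref_labels,dht_labels Equal-length 0/1 vectors on the same epoch
#'   grid.
#' @return A one-row tibble with `tp`, `fp`, `tn`, `fn`
#'   (`tp + fp + tn + fn` equals the number of epochs).
#' @export
score_night <- function(ref_labels, dht_labels) {
  if (length(ref_labels) != length(dht_labels)) {
    stop_scratchval("label vectors differ in length (%d vs %d); same grid required.",
                    length(ref_labels), length(dht_labels))
  }
  r <- as.logical(ref_labels)
  d <- as.logical(dht_labels)
  tibble::tibble(tp = sum(r & d), fp = sum(!r & d),
                 tn = sum(!r & !d), fn = sum(r & !d))
}

#' Per-night epoch confusion counts for DHT vs Reference
#'
#' High-level wrapper: for each comparison window (one row of `windows`,
#' typically from [paired_overlap_window()]), tiles the window with epochs,
#' labels the Reference and DHT scratch tracks, and tallies the confusion
#' counts.
#'
#' @param windows Tibble of comparison windows (`participant_id`,
#'   `night_id`, `start_s`, `end_s`; a `source` column, if present, names
#'   the DHT).
#' @param ref_events,dht_events Merged + filtered scratch events tables.
#' @param epoch_s Epoch length in seconds.
#' @return `windows`' identifier columns plus `n_epochs`, `tp`, `fp`, `tn`,
#'   `fn` per night.
#' @export
epoch_confusion <- function(windows, ref_events, dht_events, epoch_s = 10) {
  check_number(epoch_s, "epoch_s", min = 0, allow_zero = FALSE)
  keys <- intersect(c("participant_id", "night_id"), names(windows))
  track_of <- function(ev) {
    if (length(keys) == 0L || nrow(ev) == 0L) return(NULL)
    split(ev[c("start_s", "end_s")],
          interaction(ev[keys], drop = FALSE, lex.order = TRUE), drop = TRUE)
  }
  ref_split <- track_of(ref_events)
  dht_split <- track_of(dht_events)
  win_key <- if (length(keys)) {
    as.character(interaction(windows[keys], drop = FALSE, lex.order = TRUE))
  } else rep("", nrow(windows))
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    w0 <- windows$start_s[i]; w1 <- windows$end_s[i]
    n <- floor((w1 - w0) / epoch_s + 1e-9)
    get <- function(sp, ev) {
      if (length(keys) == 0L) ev else sp[[win_key[i]]]
    }
    rtr <- get(ref_split, ref_events) %||% data.frame(start_s = numeric(), end_s = numeric())
    dtr <- get(dht_split, dht_events) %||% data.frame(start_s = numeric(), end_s = numeric())
    r <- label_kernel(rtr$start_s, rtr$end_s, w0, n, epoch_s)
    d <- label_kernel(dtr$start_s, dtr$end_s, w0, n, epoch_s)
    cbind(n_epochs = n, score_night(r, d))
  })
  dplyr::bind_cols(windows[intersect(c(keys, "source"), names(windows))],
                   dplyr::bind_rows(rows))
}

#' Classification metrics from pooled confusion counts
#'
#' Sums the counts across all rows of `counts` within each group given by
#' `by` (micro-averaging: counts are pooled BEFORE metrics are computed),
#' then derives sensitivity, precision, F1 (harmonic mean of sensitivity and
#' precision), balanced accuracy ((sensitivity + specificity)/2) and scratch
#' prevalence ((tp + fn)/total). Metrics with a zero denominator are
#' reported as `NA` with a warning, never coerced to 0 or 1.
#'
#' @param counts Tibble with `tp`, `fp`, `tn`, `fn` columns (e.g. from
#'   [epoch_confusion()]), plus grouping columns.
#' @param by Character vector of grouping columns (default none: one pooled
#'   row).
#' @return One row per group with the pooled counts, the five metrics, and
#'   `n_participants` / `n_participant_nights` when the corresponding
#'   identifier columns are present in `counts`.
#' @export
pool_and_score <- function(counts, by = character()) {
  if (nrow(counts) == 0L) stop_scratchval("empty confusion pool.")
  miss <- setdiff(c("tp", "fp", "tn", "fn"), names(counts))
  if (length(miss)) stop_scratchval("missing count column(s): %s.", paste(miss, collapse = ", "))
  grouped <- dplyr::group_by(counts, dplyr::across(dplyr::all_of(by)))
  pooled <- dplyr::summarise(
    grouped,
    n_participants = if ("participant_id" %in% names(counts)) {
      dplyr::n_distinct(.data$participant_id)
    } else NA_integer_,
    n_participant_nights = dplyr::n(),
    tp = sum(.data$tp), fp = sum(.data$fp),
    tn = sum(.data$tn), fn = sum(.data$fn),
    .groups = "drop")
  safe_ratio <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, NA_real_)
    if (anyNA(out)) {
      warning(sprintf("%s undefined (zero denominator) for %d group(s); reported as NA.",
                      what, sum(is.na(out))), call. = FALSE)
    }
    out
  }
  total <- pooled$tp + pooled$fp + pooled$tn + pooled$fn
  if (any(total == 0)) stop_scratchval("group with zero epochs in the pool.")
  sens <- safe_ratio(pooled$tp, pooled$tp + pooled$fn, "sensitivity")
  prec <- safe_ratio(pooled$tp, pooled$tp + pooled$fp, "precision")
  spec <- safe_ratio(pooled$tn, pooled$tn + pooled$fp, "specificity")
  f1 <- ifelse(!is.na(sens) & !is.na(prec) & (sens + prec) > 0,
               2 * sens * prec / (sens + prec),
               ifelse(!is.na(sens) & sens == 0, 0, NA_real_))
  dplyr::mutate(pooled,
                total_epochs = total,
                sensitivity = sens,
                precision = prec,
                f1 = f1,
                balanced_accuracy = (sens + spec) / 2,
                prevalence = (pooled$tp + pooled$fn) / total)
}
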