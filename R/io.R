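# File interfaces. All tables are plain CSV; times inside a night are
# seconds from the night origin (noon of the evening the night begins).

events_cols <- c("participant_id", "night_id", "source", "kind", "start_s", "end_s")

#' Read an events CSV
#'
#' One row per interval with the documented header (`participant_id`,
#' `night_id`, `source`, `kind`, `start_s`, `end_s`); extra attribute
#' columns are passed through untouched. Malformed rows (non-finite
#' endpoints or `end_s <= start_s`) are collected into a problems table
#' (attached as the `"problems"` attribute, with file line numbers) and
#' dropped with a warning; the remaining rows are normalized per track.
#'
#' @param path CSV file path.
#' @return A normalized events tibble.
#' @export
read_events <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    night_id = readr::col_character(),
    source = readr::col_character(),
    kind = readr::col_character(),
    start_s = readr::col_double(),
    end_s = readr::col_double(),
    .default = readr::col_guess()), progress = FALSE)
  miss <- setdiff(events_cols, names(raw))
  if (length(miss)) {
    stop_scratchval("events file %s is missing required column(s): %s.",
                    path, paste(miss, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    warning(sprintf("events file %s contains a header but no rows.", path),
            call. = FALSE)
    return(raw)
  }
  bad <- !is.finite(raw$start_s) | !is.finite(raw$end_s) | raw$end_s <= raw$start_s
  problems <- tibble::tibble(line = which(bad) + 1L, # +1 for the header line
                             reason = "end_s <= start_s or non-finite endpoint")
  if (any(bad)) {
    warning(sprintf("%d malformed row(s) dropped from %s (see attr(, 'problems')).",
                    sum(bad), path), call. = FALSE)
  }
  out <- normalize_events(raw[!bad, , drop = FALSE])
  attr(out, "problems") <- problems
  out
}

#' Write an events CSV
#' @param x Events tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(x, path) {
  validate_events(x)
  readr::write_csv(x, path)
  invisible(path)
}

#' Read / write the PRO responses CSV
#'
#' Columns: `participant_id`, `date`, `administration`, `timestamp`,
#' `itch_nrs` (plus any extras, e.g. `night_id`).
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_pro <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    date = readr::col_character(),
    administration = readr::col_character(),
    timestamp = readr::col_character(),
    itch_nrs = readr::col_integer(),
    .default = readr::col_guess()), progress = FALSE)
  miss <- setdiff(c("participant_id", "date", "administration", "timestamp", "itch_nrs"),
                  names(out))
  if (length(miss)) stop_scratchval("PRO file missing column(s): %s.",
                                    paste(miss, collapse = ", "))
  out
}

#' @rdname read_pro
#' @param x Tibble to write.
#' @export
write_pro <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' Write and read the pipeline provenance JSON
#'
#' The full pipeline configuration round-trips losslessly through this
#' file, so a report can always be regenerated from its provenance.
#'
#' @param config A [pipeline_config()].
#' @param path JSON path.
#' @return For `write_provenance`, `path` invisibly; for
#'   `read_provenance`, the reconstructed `pipeline_config`.
#' @export
write_provenance <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_provenance
#' @export
read_provenance <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$itch_bands <- tibble::as_tibble(raw$itch_bands)
  do.call(pipeline_config, raw)
}
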