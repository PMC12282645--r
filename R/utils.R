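# Internal helpers shared across modules.

# Identifier columns that define a track within a long events table. Only the
# columns actually present in the input are used, so bare two-column
# (start_s, end_s) tables behave as a single track.
.track_key_cols <- c("participant_id", "night_id", "segment_id", "source", "kind")

event_keys <- function(x, exclude = character()) {
  setdiff(intersect(.track_key_cols, names(x)), exclude)
}

# Run `expr` under a fixed seed without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv(), inherits = FALSE)
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_scratchval <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "scratchval_error")
}

check_number <- function(x, name, min = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_scratchval("`%s` must be a single finite number.", name)
  }
  if (x < min || (!allow_zero && x == min)) {
    stop_scratchval("`%s` must be %s %s (got %s).", name,
                    if (allow_zero) ">=" else ">", format(min), format(x))
  }
  invisible(x)
}

# Clock string "HH:MM[:SS]" -> seconds since midnight.
clock_to_seconds <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- suppressWarnings(as.numeric(p))
    if (anyNA(p) || length(p) < 2L || length(p) > 3L) return(NA_real_)
    sum(p * c(3600, 60, 1)[seq_along(p)])
  }, numeric(1))
}
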