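# Brute-force grid oracle for the interval algebra. Tracks used with the
# oracle are generated on a 0.01 s lattice so that rasterization is exact:
# cell k covers [(k-1)*RES, k*RES).

RES <- 0.01

rasterize <- function(start, end, span_cells) {
  v <- logical(span_cells)
  if (length(start)) {
    i0 <- as.integer(round(start / RES)) + 1L
    i1 <- as.integer(round(end / RES))
    for (k in seq_along(i0)) if (i1[k] >= i0[k]) v[i0[k]:i1[k]] <- TRUE
  }
  v
}

cells_to_intervals <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(start_s = (starts[keep] - 1L) * RES, end_s = ends[keep] * RES)
}

oracle_normalize <- function(start, end, span_cells) {
  cells_to_intervals(rasterize(start, end, span_cells))
}

oracle_merge_gaps <- function(start, end, max_gap_s, span_cells) {
  v <- rasterize(start, end, span_cells)
  gap_cells <- as.integer(round(max_gap_s / RES))
  r <- rle(v)
  # fill interior FALSE runs strictly shorter than the gap
  interior <- !r$values & seq_along(r$values) > 1 & seq_along(r$values) < length(r$values)
  r$values[interior & r$lengths < gap_cells] <- TRUE
  cells_to_intervals(inverse.rle(r))
}

oracle_filter <- function(start, end, min_dur_s, span_cells) {
  iv <- cells_to_intervals(rasterize(start, end, span_cells))
  iv[iv$end_s - iv$start_s >= min_dur_s - 1e-9, , drop = FALSE]
}

oracle_iou <- function(s1, e1, s2, e2, span_cells) {
  a <- rasterize(s1, e1, span_cells)
  b <- rasterize(s2, e2, span_cells)
  u <- sum(a | b)
  if (u == 0) 1 else sum(a & b) / u
}

oracle_intersect <- function(s1, e1, s2, e2, span_cells) {
  cells_to_intervals(rasterize(s1, e1, span_cells) & rasterize(s2, e2, span_cells))
}

oracle_labels <- function(s, e, w0, w1, epoch_s, span_cells) {
  v <- rasterize(s, e, span_cells)
  n <- floor((w1 - w0) / epoch_s + 1e-9)
  vapply(seq_len(n), function(i) {
    c0 <- as.integer(round((w0 + (i - 1) * epoch_s) / RES)) + 1L
    c1 <- as.integer(round((w0 + i * epoch_s) / RES))
    as.integer(any(v[c0:c1]))
  }, integer(1))
}

# Random lattice track over [0, span_s]; possibly empty, unsorted,
# overlapping - exercises normalization too.
random_track <- function(max_n = 6, span_s = 120, max_len_s = 8) {
  n <- sample(0:max_n, 1)
  if (n == 0) return(list(s = numeric(), e = numeric()))
  s_cells <- sample.int(span_s / RES - max_len_s / RES, n, replace = TRUE)
  len_cells <- sample.int(max_len_s / RES, n, replace = TRUE)
  list(s = s_cells * RES, e = (s_cells + len_cells) * RES)
}

expect_same_intervals <- function(got, want, tol = 1e-8) {
  expect_equal(nrow(got), nrow(want))
  if (nrow(got)) {
    expect_equal(got$start_s, want$start_s, tolerance = tol)
    expect_equal(got$end_s, want$end_s, tolerance = tol)
  }
}

# quick events-tibble constructor
evt <- function(start, end, ...) {
  tibble::tibble(..., start_s = start, end_s = end)
}
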