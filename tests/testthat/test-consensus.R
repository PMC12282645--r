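# Multi-round bout consensus and TSO consensus.

rater_tbl <- function(source, start, end, night = "N1") {
  evt(start, end, night_id = night, source = source, kind = "scratch")
}

test_that("round 1 consensus takes the intersection when IoU exceeds the threshold", {
  r <- dplyr::bind_rows(rater_tbl("R1", 0, 10), rater_tbl("R2", 0, 10))
  out <- bout_consensus(r, rater_sources = c("R1", "R2"))
  expect_equal(out$provenance$round_reached, 1L)
  expect_equal(out$provenance$iou_round1, 1)
  expect_true(is.na(out$provenance$iou_round2))
  expect_same_intervals(out$reference, evt(0, 10))
  expect_equal(unique(out$reference$source), "Reference")
})

test_that("round 2 engages when round 1 fails, using raters 3 and 4", {
  r <- dplyr::bind_rows(
    rater_tbl("R1", 0, 10), rater_tbl("R2", 5, 15),   # IoU 1/3
    rater_tbl("R3", 6, 9), rater_tbl("R4", 6, 9))
  out <- bout_consensus(r, rater_sources = c("R1", "R2", "R3", "R4"))
  expect_equal(out$provenance$round_reached, 2L)
  expect_equal(out$provenance$iou_round1, 1 / 3, tolerance = 1e-12)
  expect_equal(out$provenance$iou_round2, 1)
  expect_same_intervals(out$reference, evt(6, 9))
})

test_that("round 3 takes the fifth rater verbatim", {
  r <- dplyr::bind_rows(
    rater_tbl("R1", 0, 10), rater_tbl("R2", 20, 30),
    rater_tbl("R3", 0, 10), rater_tbl("R4", 20, 30),
    rater_tbl("R5", 1, 4))
  out <- bout_consensus(r)
  expect_equal(out$provenance$round_reached, 3L)
  expect_same_intervals(out$reference, evt(1, 4))
})

test_that("missing escalation raters are rejected naming the round", {
  r <- dplyr::bind_rows(rater_tbl("R1", 0, 10), rater_tbl("R2", 20, 30))
  expect_error(bout_consensus(r, rater_sources = c("R1", "R2")), "round 2")
  r4 <- dplyr::bind_rows(r, rater_tbl("R3", 0, 10), rater_tbl("R4", 20, 30))
  expect_error(bout_consensus(r4, rater_sources = c("R1", "R2", "R3", "R4")),
               "round 3")
})

test_that("consensus threshold is strictly exceeded", {
  # construct IoU exactly at the threshold: 0.765 = 765/1000
  r <- dplyr::bind_rows(rater_tbl("R1", 0, 765), rater_tbl("R2", 0, 1000),
                        rater_tbl("R3", 0, 10), rater_tbl("R4", 0, 10))
  out <- bout_consensus(r, threshold = 0.765,
                        rater_sources = c("R1", "R2", "R3", "R4"))
  expect_equal(out$provenance$iou_round1, 0.765)
  expect_equal(out$provenance$round_reached, 2L) # at threshold -> escalate
})

test_that("round-1/2 consensus is a subset of each contributing rater and symmetric", {
  set.seed(7)
  for (i in 1:40) {
    a <- random_track(); b <- random_track()
    r <- dplyr::bind_rows(rater_tbl("R1", a$s, a$e), rater_tbl("R2", b$s, b$e),
                          rater_tbl("R3", a$s, a$e), rater_tbl("R4", a$s, a$e))
    if (nrow(r) == 0) next # no rater saw anything: no tracks to rate
    out <- bout_consensus(r, rater_sources = c("R1", "R2", "R3", "R4"))
    swapped <- bout_consensus(
      dplyr::bind_rows(rater_tbl("R1", b$s, b$e), rater_tbl("R2", a$s, a$e),
                       rater_tbl("R3", a$s, a$e), rater_tbl("R4", a$s, a$e)),
      rater_sources = c("R1", "R2", "R3", "R4"))
    expect_same_intervals(out$reference, swapped$reference)
    # subset of each rater: intersecting with either rater leaves it unchanged
    for (tr in list(evt(a$s, a$e), evt(b$s, b$e))) {
      if (out$provenance$round_reached == 1L) {
        expect_same_intervals(intersect_events(out$reference[c("start_s", "end_s")], tr),
                              normalize_events(out$reference[c("start_s", "end_s")]))
      }
    }
  }
})

test_that("identical raters always reach consensus in their round", {
  tr <- random_track()
  r <- dplyr::bind_rows(rater_tbl("R1", tr$s, tr$e), rater_tbl("R2", tr$s, tr$e))
  out <- bout_consensus(r, rater_sources = c("R1", "R2"))
  expect_equal(out$provenance$round_reached, 1L)
})

test_that("consensus runs per segment when a segment column is present", {
  r <- dplyr::bind_rows(
    evt(0, 10, night_id = "N1", segment_id = "S1", source = "R1", kind = "scratch"),
    evt(0, 10, night_id = "N1", segment_id = "S1", source = "R2", kind = "scratch"),
    evt(50, 60, night_id = "N1", segment_id = "S2", source = "R1", kind = "scratch"),
    evt(80, 90, night_id = "N1", segment_id = "S2", source = "R2", kind = "scratch"),
    evt(55, 58, night_id = "N1", segment_id = "S2", source = "R5", kind = "scratch"))
  # segment S2 disagrees and needs escalation; with all five raters present:
  r5 <- dplyr::bind_rows(
    r,
    evt(0, 10, night_id = "N1", segment_id = "S2", source = "R3", kind = "scratch"),
    evt(20, 30, night_id = "N1", segment_id = "S2", source = "R4", kind = "scratch"),
    evt(0, 10, night_id = "N1", segment_id = "S1", source = "R3", kind = "scratch"),
    evt(0, 10, night_id = "N1", segment_id = "S1", source = "R4", kind = "scratch"))
  out <- bout_consensus(r5)
  expect_equal(nrow(out$provenance), 2)
  s2 <- out$provenance[out$provenance$segment_id == "S2", ]
  expect_equal(s2$round_reached, 3L)
  expect_same_intervals(
    out$reference[out$reference$segment_id == "S2", c("start_s", "end_s")],
    evt(55, 58))
})

test_that("TSO consensus averages agreeing raters and adjudicates beyond tolerance", {
  tso <- function(src, s, e) evt(s, e, night_id = "N1", source = src, kind = "tso")
  # identical raters
  out <- tso_consensus(dplyr::bind_rows(tso("R1", 3600, 32400), tso("R2", 3600, 32400)))
  expect_equal(c(out$start_s, out$end_s), c(3600, 32400))
  expect_false(out$adjudicated)
  # within tolerance: endpoint means
  out <- tso_consensus(dplyr::bind_rows(tso("R1", 3600, 32400), tso("R2", 3630, 32430)))
  expect_equal(c(out$start_s, out$end_s), c(3615, 32415))
  expect_false(out$adjudicated)
  # exactly at tolerance still counts as agreement (disagreement is "> 1 min")
  out <- tso_consensus(dplyr::bind_rows(tso("R1", 3600, 32400), tso("R2", 3660, 32400)))
  expect_false(out$adjudicated)
  # beyond tolerance: adjudicator verbatim
  out <- tso_consensus(dplyr::bind_rows(tso("R1", 3600, 32400), tso("R2", 3720, 32400),
                                        tso("R3", 3700, 32000)))
  expect_true(out$adjudicated)
  expect_equal(c(out$start_s, out$end_s), c(3700, 32000))
  # adjudicator required but absent
  expect_error(
    tso_consensus(dplyr::bind_rows(tso("R1", 3600, 32400), tso("R2", 3720, 32400))),
    "adjudication")
})
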