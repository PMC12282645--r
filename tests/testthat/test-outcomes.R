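# Night outcomes, geometric means, group summaries, PRO handling.

mk_tso <- function(id = "P1", night = "N1", src = "Reference",
                   start = 0, end = 8 * 3600) {
  evt(start, end, participant_id = id, night_id = night, source = src,
      kind = "tso")
}

test_that("night_summary normalizes by TSO hours", {
  scratch <- evt(seq(0, by = 100, length.out = 5),
                 seq(0, by = 100, length.out = 5) + 12,
                 participant_id = "P1", night_id = "N1", source = "Reference",
                 kind = "scratch")
  out <- night_summary(scratch, mk_tso())
  expect_equal(out$scratch_seconds, 60)
  expect_equal(out$bout_count, 5L)
  expect_equal(out$norm_duration, 7.5)
  expect_equal(out$norm_frequency, 0.625)
})

test_that("nights with no scratch rows score zero; excluded TSO is rejected", {
  out <- night_summary(evt(numeric(), numeric(), participant_id = character(),
                           night_id = character(), source = character(),
                           kind = character()),
                       mk_tso())
  expect_equal(out$norm_duration, 0)
  expect_equal(out$norm_frequency, 0)
  flagged <- exclude_short_tso(mk_tso(end = 2 * 3600))
  expect_error(night_summary(evt(0, 10), flagged), "excluded")
})

test_that("doubling the TSO halves both normalized outcomes", {
  scratch <- evt(c(0, 500), c(30, 520), participant_id = "P1", night_id = "N1",
                 source = "Reference", kind = "scratch")
  a <- night_summary(scratch, mk_tso(end = 4 * 3600))
  b <- night_summary(scratch, mk_tso(end = 8 * 3600))
  expect_equal(a$norm_duration, 2 * b$norm_duration)
  expect_equal(a$norm_frequency, 2 * b$norm_frequency)
})

test_that("normalized outcomes are invariant to shifting the night origin", {
  shift <- 12345
  scratch <- evt(c(1000, 2000), c(1030, 2015), participant_id = "P1",
                 night_id = "N1", source = "Reference", kind = "scratch")
  a <- night_summary(scratch, mk_tso(start = 0, end = 6 * 3600))
  b <- night_summary(dplyr::mutate(scratch, start_s = start_s + shift,
                                   end_s = end_s + shift),
                     mk_tso(start = shift, end = 6 * 3600 + shift))
  expect_equal(a$norm_duration, b$norm_duration)
  expect_equal(a$norm_frequency, b$norm_frequency)
})

test_that("geometric_mean matches hand values including the offset formula", {
  expect_equal(geometric_mean(c(4, 9), delta = 0), 6)
  expect_equal(geometric_mean(5, delta = 0), 5)
  expect_equal(geometric_mean(c(0, 10), delta = 1),
               exp((log(1) + log(11)) / 2) - 1, tolerance = 1e-12)
  expect_equal(geometric_mean(c(0, 10), delta = 1), 2.3166, tolerance = 1e-4)
  expect_error(geometric_mean(numeric()), "empty")
  expect_error(geometric_mean(c(1, 2), delta = -1), "delta")
})

test_that("participant geometric means respect AM-GM", {
  set.seed(21)
  nights <- tibble::tibble(
    participant_id = rep(c("P1", "P2"), each = 6),
    source = "Reference",
    norm_duration = rlnorm(12, 2, 0.8),
    norm_frequency = rlnorm(12, 1, 0.5))
  ps <- participant_summary(nights, delta = 0)
  am <- dplyr::summarise(dplyr::group_by(nights, participant_id),
                         d = mean(norm_duration), f = mean(norm_frequency))
  expect_true(all(ps$norm_duration < am$d))
  expect_true(all(ps$norm_frequency < am$f))
})

test_that("group_summary reports medians/IQRs and ignores row order", {
  ps <- tibble::tibble(cohort = c("A", "A", "A", "B"),
                       norm_duration = c(1, 2, 9, 5),
                       norm_frequency = c(2, 4, 6, 1))
  gs <- group_summary(ps)
  a_dur <- gs[gs$cohort == "A" & gs$outcome == "norm_duration", ]
  expect_equal(a_dur$median, 2)
  expect_equal(a_dur$n, 3L)
  b_dur <- gs[gs$cohort == "B" & gs$outcome == "norm_duration", ]
  expect_equal(b_dur$median, 5) # single-member group: its own value
  gs_perm <- group_summary(ps[sample(4), ])
  expect_equal(dplyr::arrange(gs, cohort, outcome),
               dplyr::arrange(gs_perm, cohort, outcome))
})

test_that("PRO filtering applies the morning window inclusively", {
  pro <- tibble::tibble(
    participant_id = "P1",
    date = c("2022-03-02", "2022-03-03", "2022-03-04", "2022-03-05", "2022-03-05"),
    administration = c("morning", "morning", "morning", "evening", "morning"),
    timestamp = c("03:59:00", "04:00:00", "12:00:00", "20:00:00", "12:01:00"),
    itch_nrs = c(3L, 4L, 5L, 2L, 6L))
  out <- filter_pro_responses(pro)
  expect_equal(out$date, c("2022-03-03", "2022-03-04")) # 03:59 and 12:01 dropped
  expect_true(all(out$administration == "morning"))
})

test_that("duplicate morning responses void the whole participant-day", {
  pro <- tibble::tibble(
    participant_id = "P1",
    date = rep("2022-03-02", 2),
    administration = "morning",
    timestamp = c("08:00:00", "09:00:00"), # both in-window
    itch_nrs = c(3L, 4L))
  expect_equal(nrow(filter_pro_responses(pro)), 0)
})

test_that("itch bands partition the NRS range and reject overlaps", {
  b <- itch_bands()
  covered <- unlist(purrr::map2(b$lo, b$hi, seq))
  expect_equal(sort(covered), 0:10)
  ns <- tibble::tibble(participant_id = "P1", night_id = "N1",
                       source = "Reference", date = "2022-03-01",
                       norm_duration = 10, norm_frequency = 2)
  pro <- tibble::tibble(participant_id = "P1", date = "2022-03-02",
                        administration = "morning", timestamp = "08:00:00",
                        itch_nrs = 0L)
  bad <- tibble::tibble(band = c("a", "b"), lo = c(0, 2), hi = c(3, 5))
  expect_error(stratify_by_itch(ns, pro, bands = bad), "overlap")
})

test_that("stratification joins the morning PRO to the preceding night", {
  ns <- tibble::tibble(participant_id = "P1", night_id = c("N1", "N2"),
                       source = "Reference", date = c("2022-03-01", "2022-03-04"),
                       norm_duration = c(10, 20), norm_frequency = c(2, 4))
  pro <- tibble::tibble(participant_id = "P1",
                        date = c("2022-03-02", "2022-03-05"),
                        administration = "morning", timestamp = "08:00:00",
                        itch_nrs = c(0L, 5L))
  out <- stratify_by_itch(ns, pro)
  expect_equal(as.character(out$itch_band), c("no itch", "moderate"))
  expect_equal(out$night_id, c("N1", "N2"))
  # missing PRO -> night unassigned and dropped
  out2 <- stratify_by_itch(ns, pro[2, ])
  expect_equal(out2$night_id, "N2")
  # direct night_id join when both tables carry it
  pro_nid <- dplyr::mutate(pro, night_id = c("N1", "N2"))
  out3 <- stratify_by_itch(ns, pro_nid)
  expect_equal(as.character(out3$itch_band), c("no itch", "moderate"))
})
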