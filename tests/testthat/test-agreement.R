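# Variance components, ICC, bootstrap, Bland-Altman.

test_that("icc_from_components computes both definitions", {
  vc <- list(var_participant = 3, var_night = 1, var_residual = 1, var_fixed = 0)
  expect_equal(icc_from_components(vc), 0.8)
  expect_equal(icc_from_components(list(var_participant = 1, var_night = 0,
                                        var_residual = 0, var_fixed = 0)), 1)
  expect_equal(icc_from_components(list(var_participant = 1, var_night = 1,
                                        var_residual = 2, var_fixed = 0)), 0.5)
  # unadjusted adds fixed-effect variance to the denominator
  vc$var_fixed <- 1
  expect_equal(icc_from_components(vc, "unadjusted"), 4 / 6)
  expect_equal(icc_from_components(vc, "adjusted"), 0.8)
  expect_warning(
    out <- icc_from_components(list(var_participant = 0, var_night = 0,
                                    var_residual = 0, var_fixed = 0)),
    "undefined")
  expect_true(is.na(out))
})

test_that("moment estimator equals REML on a balanced design", {
  dat <- simulate_vc_data(n_participants = 12, n_nights = 4,
                          sources = c("A", "B", "C"),
                          fixed_effects = c(0, 0.3, -0.2),
                          var_participant = 1, var_night = 0.5,
                          var_residual = 0.5, seed = 101)
  m <- fit_variance_components(dat, method = "moment")
  r <- fit_variance_components(dat, method = "reml")
  expect_equal(m$var_participant, r$var_participant, tolerance = 1e-4)
  expect_equal(m$var_night, r$var_night, tolerance = 1e-4)
  expect_equal(m$var_residual, r$var_residual, tolerance = 1e-4)
  expect_equal(m$var_fixed, r$var_fixed, tolerance = 1e-4)
  expect_equal(icc_from_components(m), icc_from_components(r), tolerance = 1e-4)
  # auto picks the moment path on balanced data
  expect_equal(fit_variance_components(dat)$method, "moment")
})

test_that("variance components are recovered from simulated data", {
  set.seed(77)
  ests <- t(vapply(1:20, function(i) {
    dat <- simulate_vc_data(n_participants = 28, n_nights = 8,
                            var_participant = 1, var_night = 0.5,
                            var_residual = 0.5)
    vc <- fit_variance_components(dat)
    c(vc$var_participant, vc$var_night, vc$var_residual)
  }, numeric(3)))
  expect_equal(colMeans(ests), c(1, 0.5, 0.5), tolerance = 0.15)
})

test_that("identical sources give residual ~ 0 and ICC ~ 1; pure noise gives ~0", {
  base <- simulate_vc_data(n_participants = 10, n_nights = 4,
                           sources = "A", var_participant = 1,
                           var_night = 0.5, var_residual = 0, seed = 5)
  dup <- dplyr::bind_rows(base, dplyr::mutate(base, source = "B"))
  vc <- fit_variance_components(dup)
  expect_lt(vc$var_residual, 1e-10)
  expect_gt(icc_from_components(vc), 0.999)
  noise <- simulate_vc_data(n_participants = 20, n_nights = 6,
                            var_participant = 0, var_night = 0,
                            var_residual = 1, seed = 6)
  vcn <- fit_variance_components(noise)
  expect_lt(icc_from_components(vcn), 0.2)
})

test_that("adding a constant to one source moves unadjusted but not adjusted ICC", {
  dat <- simulate_vc_data(seed = 55)
  shifted <- dplyr::mutate(dat, y = y + (source == "DHT") * 2)
  a <- fit_variance_components(dat)
  b <- fit_variance_components(shifted)
  expect_equal(icc_from_components(a, "adjusted"),
               icc_from_components(b, "adjusted"), tolerance = 1e-10)
  expect_lt(icc_from_components(b, "unadjusted"),
            icc_from_components(a, "unadjusted"))
})

test_that("bootstrap_icc is seeded, reproducible, and brackets its estimate", {
  dat <- simulate_vc_data(n_participants = 20, n_nights = 4, seed = 9)
  r1 <- bootstrap_icc(dat, n_boot = 100, seed = 42)
  r2 <- bootstrap_icc(dat, n_boot = 100, seed = 42)
  expect_identical(r1$estimates, r2$estimates)
  est <- r1$estimates[r1$estimates$definition == "adjusted", ]
  expect_true(est$ci_low <= est$estimate + 0.02 &&
                est$ci_high >= est$estimate - 0.02)
  expect_true(all(r1$estimates$estimate >= 0 & r1$estimates$estimate <= 1))
  # perfect agreement: upper bound near 1
  base <- simulate_vc_data(n_participants = 10, n_nights = 4, sources = "A",
                           var_residual = 0, seed = 5)
  dup <- dplyr::bind_rows(base, dplyr::mutate(base, source = "B"))
  perf <- bootstrap_icc(dup, n_boot = 50, seed = 1)
  expect_gte(perf$estimates$ci_high[1], 0.99)
})

test_that("tidiers return the documented shapes", {
  dat <- simulate_vc_data(n_participants = 8, n_nights = 3, seed = 2)
  vc <- fit_variance_components(dat)
  expect_equal(tidy(vc)$term, c("participant", "night", "residual"))
  expect_equal(glance(vc)$n_obs, nrow(dat))
  icc <- bootstrap_icc(dat, n_boot = 20, seed = 3)
  expect_equal(nrow(tidy(icc)), 2)
  expect_equal(glance(icc)$n_bootstrap, 20)
})

test_that("Bland-Altman handles degenerate zero-variance differences exactly", {
  pairs <- tibble::tibble(participant_id = rep(c("P1", "P2"), each = 4),
                          ref_tso_hours = 8, dht_tso_hours = 8)
  ba <- bland_altman_repeated(pairs, n_boot = 0)
  expect_equal(ba$bias, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(0, 0))
  shifted <- dplyr::mutate(pairs, dht_tso_hours = 8.42)
  ba2 <- bland_altman_repeated(shifted, n_boot = 0)
  expect_equal(ba2$bias, 0.42)
  expect_equal(c(ba2$loa_low, ba2$loa_high), c(0.42, 0.42))
})

test_that("Bland-Altman recovers a known bias and limits", {
  set.seed(31)
  P <- 28; N <- 8
  sd_tot <- 1.17
  d <- 0.44 + rep(rnorm(P, 0, sd_tot / sqrt(2)), each = N) +
    rnorm(P * N, 0, sd_tot / sqrt(2))
  pairs <- tibble::tibble(participant_id = rep(sprintf("P%02d", 1:P), each = N),
                          ref_tso_hours = 8, dht_tso_hours = 8 + d)
  ba <- bland_altman_repeated(pairs, n_boot = 100, seed = 1)
  expect_equal(ba$bias, 0.44, tolerance = 0.45) # single-replicate check
  expect_lt(ba$loa_low, ba$bias)
  expect_gt(ba$loa_high, ba$bias)
  expect_equal(ba$loa_high - ba$bias, ba$bias - ba$loa_low, tolerance = 1e-9)
  expect_equal(ba$n_pairs, P * N)
  # CI rows present and ordered
  expect_equal(ba$ci$quantity, c("bias", "loa_low", "loa_high"))
  expect_true(all(ba$ci$ci_low <= ba$ci$ci_high))
  expect_error(bland_altman_repeated(pairs[1:8, ]), "2 participants")
})

test_that("REML and moment Bland-Altman fits agree on balanced data", {
  set.seed(13)
  d <- 0.3 + rep(rnorm(10, 0, 0.5), each = 6) + rnorm(60, 0, 0.5)
  pairs <- tibble::tibble(participant_id = rep(sprintf("P%02d", 1:10), each = 6),
                          ref_tso_hours = 8, dht_tso_hours = 8 + d)
  a <- bland_altman_repeated(pairs, n_boot = 0, method = "reml")
  b <- bland_altman_repeated(pairs, n_boot = 0, method = "moment")
  expect_equal(a$bias, b$bias, tolerance = 1e-6)
  expect_equal(a$loa_high, b$loa_high, tolerance = 1e-3)
})
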