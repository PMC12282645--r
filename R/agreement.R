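# Night-level agreement statistics.
#
# Scratch outcomes are compared across sources (Reference, devices, single
# raters) with an intraclass correlation derived from a linear mixed model
# on the log scale: a fixed effect for source, a random intercept per
# participant, and a random intercept per study night nested within
# participant (two-way mixed-effects, interaction absent, absolute
# agreement). TSO duration is compared with a repeated-measures
# Bland-Altman analysis. Confidence intervals come from a cluster bootstrap
# that resamples participants, respecting the repeated-measures structure.

check_vc_data <- function(data) {
  need <- c("participant_id", "night_id", "source", "y")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop_scratchval("variance-component data missing column(s): %s.",
                                    paste(miss, collapse = ", "))
  if (dplyr::n_distinct(data$source) < 2L) {
    stop_scratchval("at least two sources are required.")
  }
  invisible(data)
}

# A design is balanced here when every participant has the same set size of
# nights and every (participant, night) cell has exactly one observation per
# source. Balanced designs admit the closed-form ANOVA estimator, which for
# this model equals REML (up to the non-negativity boundary).
is_balanced_design <- function(data) {
  tab <- table(data$participant_id, data$night_id, data$source)
  all(tab %in% c(0L, 1L)) && {
    cells <- table(data$participant_id, data$night_id) # obs per cell
    used <- cells[cells > 0]
    length(unique(used)) == 1L &&
      all(used == length(unique(data$source))) &&
      length(unique(rowSums(cells > 0))) == 1L
  }
}

# Closed-form balanced ANOVA estimator on integer-coded inputs.
# y: response; p: participant code 1..P; cell: night-cell code 1..(P*N)
# (cell_p maps cell -> participant); s: source code 1..S.
moment_kernel <- function(y, p, cell, cell_p, s, P, N, S) {
  grand <- mean(y)
  ybar_cell <- rowsum(y, cell, reorder = TRUE)[, 1] / S
  ybar_p <- rowsum(y, p, reorder = TRUE)[, 1] / (N * S)
  ybar_s <- rowsum(y, s, reorder = TRUE)[, 1] / (P * N)
  MSA <- N * S * sum((ybar_p - grand)^2) / (P - 1)
  resid <- y - ybar_cell[cell] - ybar_s[s] + grand
  MSE <- sum(resid^2) / ((P * N - 1) * (S - 1))
  if (N > 1) {
    MSB <- S * sum((ybar_cell - ybar_p[cell_p])^2) / (P * (N - 1))
    vb <- max(0, (MSB - MSE) / S)
    va <- max(0, (MSA - MSB) / (N * S))
  } else {
    vb <- 0
    va <- max(0, (MSA - MSE) / (N * S))
  }
  fixed <- ybar_s - ybar_s[1]
  list(var_participant = va, var_night = vb, var_residual = MSE,
       fixed_effects = fixed, var_fixed = stats::var(ybar_s[s]))
}

moment_fit <- function(data) {
  p_f <- factor(data$participant_id)
  s_f <- factor(data$source)
  cell_f <- factor(paste(data$participant_id, data$night_id, sep = "\r"))
  P <- nlevels(p_f); S <- nlevels(s_f)
  N <- nlevels(cell_f) / P
  if (N != round(N)) stop_scratchval("design is not balanced; use method = 'reml'.")
  p <- as.integer(p_f)
  cell <- as.integer(cell_f)
  cell_p <- tapply(p, cell, function(v) v[1])
  out <- moment_kernel(data$y, p, cell, as.vector(cell_p), as.integer(s_f),
                       P, as.integer(N), S)
  names(out$fixed_effects) <- levels(s_f)
  out
}

reml_fit <- function(data) {
  msgs <- character()
  fit <- withCallingHandlers(
    tryCatch(
      lme4::lmer(
        y ~ source + (1 | participant_id) + (1 | participant_id:night_id),
        data = data, REML = TRUE,
        control = lme4::lmerControl(calc.derivs = FALSE,
                                    check.conv.singular = "ignore")),
      error = function(e) e),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  if (inherits(fit, "error")) {
    return(list(var_participant = NA_real_, var_night = NA_real_,
                var_residual = NA_real_, fixed_effects = NULL,
                var_fixed = NA_real_, converged = FALSE,
                messages = conditionMessage(fit)))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) vc$vcov[vc$grp == g][1]
  fe <- lme4::fixef(fit)
  Xb <- as.numeric(stats::model.matrix(fit) %*% fe)
  conv <- !any(grepl("failed to converge|unable to evaluate|degenerate",
                     msgs, ignore.case = TRUE))
  list(var_participant = getv("participant_id"),
       var_night = getv("participant_id:night_id"),
       var_residual = getv("Residual"),
       fixed_effects = c(0, fe[-1]) |> stats::setNames(levels(factor(data$source))),
       var_fixed = stats::var(Xb),
       converged = conv,
       messages = msgs)
}

#' Fit the nested variance-component model for scratch agreement
#'
#' Restricted-maximum-likelihood estimation of the three variance
#' components (participant, night within participant, residual) and the
#' fixed source effects for a long table of log-scale outcomes.
#'
#' @param data Long tibble with columns `participant_id`, `night_id`,
#'   `source` and `y` (the outcome, already log-transformed with whatever
#'   offset policy applies).
#' @param method `"reml"` fits with [lme4::lmer()]; `"moment"` uses the
#'   closed-form balanced-ANOVA estimator, which equals REML on balanced
#'   designs and is orders of magnitude faster; `"auto"` (default) picks
#'   `"moment"` when the design is balanced and `"reml"` otherwise.
#' @return An object of class `scratch_vc`: variance components (all
#'   constrained non-negative), fixed source effects, the variance of the
#'   fixed-effect predictor, the fitting method, a `converged` flag and any
#'   fitter diagnostics. Non-convergence is flagged, never silently
#'   replaced.
#' @seealso [icc_from_components()], [bootstrap_icc()]
#' @export
fit_variance_components <- function(data, method = c("auto", "reml", "moment")) {
  method <- match.arg(method)
  check_vc_data(data)
  if (method == "auto") {
    method <- if (is_balanced_design(data)) "moment" else "reml"
  }
  res <- if (method == "moment") {
    c(moment_fit(data), list(converged = TRUE, messages = character()))
  } else {
    reml_fit(data)
  }
  structure(
    list(var_participant = res$var_participant,
         var_night = res$var_night,
         var_residual = res$var_residual,
         fixed_effects = res$fixed_effects,
         var_fixed = res$var_fixed,
         method = method,
         converged = res$converged,
         messages = res$messages,
         n_participants = dplyr::n_distinct(data$participant_id),
         n_obs = nrow(data)),
    class = "scratch_vc")
}

#' @export
print.scratch_vc <- function(x, ...) {
  cat("Nested variance components (", x$method, ")\n", sep = "")
  cat(sprintf("  participant: %.4f\n  night:       %.4f\n  residual:    %.4f\n",
              x$var_participant, x$var_night, x$var_residual))
  if (!x$converged) cat("  ! fit did not converge cleanly\n")
  invisible(x)
}

#' Intraclass correlation from variance components
#'
#' The adjusted ICC excludes the fixed source effects from the denominator:
#' `(var_participant + var_night) / (var_participant + var_night +
#' var_residual)`. The unadjusted ICC additionally adds the variance of the
#' fixed source effects to the denominator, so systematic offsets between
#' sources lower it.
#'
#' @param vc A `scratch_vc` object (or list with the same fields).
#' @param definition `"adjusted"` (default) or `"unadjusted"`.
#' @return A single ICC in `[0, 1]`, or `NA` (with a warning) when all
#'   components are zero.
#' @export
icc_from_components <- function(vc, definition = c("adjusted", "unadjusted")) {
  definition <- match.arg(definition)
  num <- vc$var_participant + vc$var_night
  den <- num + vc$var_residual
  if (definition == "unadjusted") den <- den + (vc$var_fixed %||% 0)
  if (!is.finite(den) || den == 0) {
    warning("all variance components are zero; ICC undefined.", call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' Bootstrap ICC with participant-level resampling
#'
#' Point estimates (both ICC definitions) from the full data plus percentile
#' confidence intervals from a cluster bootstrap that resamples
#' participants with replacement, preserving each participant's nights.
#' Non-convergent bootstrap replicates are dropped and counted; the result
#' is flagged when more than 20\% fail.
#'
#' @inheritParams fit_variance_components
#' @param n_boot Number of bootstrap resamples (default 500).
#' @param seed Integer seed for reproducibility (the caller's RNG state is
#'   left untouched).
#' @param engine Fitting engine for the point estimate and the bootstrap
#'   replicates; see `method` in [fit_variance_components()].
#' @param conf Confidence level (default 0.95).
#' @return An object of class `scratch_icc` whose `estimates` element is a
#'   tibble with one row per definition: `estimate`, `ci_low`, `ci_high`;
#'   plus `n_bootstrap`, `n_nonconverged`, `flagged` and the fitted
#'   `scratch_vc`.
#' @export
bootstrap_icc <- function(data, n_boot = 500, seed = NULL,
                          engine = c("auto", "reml", "moment"), conf = 0.95) {
  engine <- match.arg(engine)
  check_vc_data(data)
  check_number(n_boot, "n_boot", min = 1)
  vc <- fit_variance_components(data, method = engine)
  boot_engine <- switch(engine,
                        moment = "moment",
                        reml = "reml",
                        auto = if (vc$method == "moment") "moment" else "reml")
  balanced <- boot_engine == "moment"

  p_f <- factor(data$participant_id)
  idx_by_p <- split(seq_len(nrow(data)), p_f)
  P <- length(idx_by_p)
  s_code <- as.integer(factor(data$source))
  S <- max(s_code)
  # night rank within participant (1..N), valid for the balanced fast path
  cell_key <- paste(data$participant_id, data$night_id, sep = "\r")
  night_rank <- stats::ave(cell_key, as.character(p_f),
                           FUN = function(k) as.integer(factor(k)))
  night_rank <- as.integer(night_rank)
  N <- max(night_rank)

  one_boot <- function() {
    ids <- sample.int(P, P, replace = TRUE)
    rows <- unlist(idx_by_p[ids], use.names = FALSE)
    newp <- rep(seq_len(P), lengths(idx_by_p)[ids])
    if (balanced) {
      cell <- (newp - 1L) * N + night_rank[rows]
      cell_p <- rep(seq_len(P), each = N)
      mk <- moment_kernel(data$y[rows], newp, cell, cell_p, s_code[rows], P, N, S)
      c(icc_from_components(mk, "adjusted"),
        icc_from_components(mk, "unadjusted"), 1)
    } else {
      bd <- data[rows, ]
      bd$participant_id <- newp
      fit <- reml_fit(bd)
      if (!isTRUE(fit$converged) || !is.finite(fit$var_residual)) {
        return(c(NA_real_, NA_real_, 0))
      }
      c(icc_from_components(fit, "adjusted"),
        icc_from_components(fit, "unadjusted"), 1)
    }
  }
  draws <- with_seed(seed, vapply(seq_len(n_boot), function(i) one_boot(),
                                  numeric(3)))
  ok <- draws[3, ] == 1 & is.finite(draws[1, ])
  n_bad <- sum(!ok)
  alpha <- (1 - conf) / 2
  ci <- function(v) unname(stats::quantile(v[ok], c(alpha, 1 - alpha), na.rm = TRUE))
  ci_adj <- ci(draws[1, ]); ci_unadj <- ci(draws[2, ])
  structure(
    list(estimates = tibble::tibble(
           definition = c("adjusted", "unadjusted"),
           estimate = c(icc_from_components(vc, "adjusted"),
                        icc_from_components(vc, "unadjusted")),
           ci_low = c(ci_adj[1], ci_unadj[1]),
           ci_high = c(ci_adj[2], ci_unadj[2])),
         n_bootstrap = n_boot,
         n_nonconverged = n_bad,
         flagged = n_bad > 0.2 * n_boot || !vc$converged,
         conf = conf,
         seed = seed,
         vc = vc),
    class = "scratch_icc")
}

#' @export
print.scratch_icc <- function(x, ...) {
  cat("ICC (cluster bootstrap, ", x$n_bootstrap, " resamples)\n", sep = "")
  print(x$estimates)
  if (x$flagged) cat("! flagged:", x$n_nonconverged, "non-convergent replicates\n")
  invisible(x)
}

# One-way moment estimator for the Bland-Altman model: d_ij = mu + a_i + e_ij.
ba_moment <- function(d, p) {
  a <- nlevels(p)
  n_i <- tabulate(p)
  Ntot <- length(d)
  dbar_i <- rowsum(d, p, reorder = TRUE)[, 1] / n_i
  MSW <- sum((d - dbar_i[as.integer(p)])^2) / max(1, Ntot - a)
  grand <- mean(d)
  MSB <- sum(n_i * (dbar_i - grand)^2) / max(1, a - 1)
  n0 <- (Ntot - sum(n_i^2) / Ntot) / max(1, a - 1)
  vb <- max(0, (MSB - MSW) / n0)
  vw <- MSW
  w <- n_i / (vw + n_i * vb)
  if (!any(is.finite(w)) || sum(w) == 0) w <- n_i
  bias <- sum(w * dbar_i) / sum(w)
  list(bias = bias, var_between = vb, var_within = vw)
}

#' Repeated-measures Bland-Altman analysis
#'
#' Agreement of a DHT-derived quantity (typically TSO duration in hours)
#' with the Reference over repeated nights per participant. The per-night
#' difference `d = dht - ref` is modeled with a participant random
#' intercept; the bias is the model intercept and the 95\% limits of
#' agreement are `bias +/- 1.96 * sqrt(between-participant variance +
#' within-participant variance)`. Confidence intervals for the bias and for
#' each limit use a participant-level bootstrap.
#'
#' @param pairs Tibble with `participant_id` and the two paired measurement
#'   columns; unpaired nights must already be removed.
#' @param dht_col,ref_col Names of the DHT and Reference columns (default
#'   `"dht_tso_hours"`, `"ref_tso_hours"`).
#' @param n_boot Bootstrap resamples for the CIs (default 500; 0 skips CIs).
#' @param seed Integer seed for the bootstrap.
#' @param method `"reml"` fits the intercept model with [lme4::lmer()];
#'   `"moment"` uses the closed-form one-way ANOVA estimator (always used
#'   for bootstrap replicates). Default `"auto"`: REML, with exact handling
#'   of degenerate zero-variance differences.
#' @return An object of class `scratch_ba` with `bias`, `loa_low`,
#'   `loa_high`, the variance split, a `ci` tibble, `n_pairs`,
#'   `n_participants` and the per-night differences (for plotting).
#' @export
bland_altman_repeated <- function(pairs, dht_col = "dht_tso_hours",
                                  ref_col = "ref_tso_hours",
                                  n_boot = 500, seed = NULL,
                                  method = c("auto", "reml", "moment")) {
  method <- match.arg(method)
  miss <- setdiff(c("participant_id", dht_col, ref_col), names(pairs))
  if (length(miss)) stop_scratchval("`pairs` missing column(s): %s.",
                                    paste(miss, collapse = ", "))
  if (anyNA(pairs[[dht_col]]) || anyNA(pairs[[ref_col]])) {
    stop_scratchval("unpaired rows (NA) must be removed before Bland-Altman analysis.")
  }
  p <- factor(pairs$participant_id)
  if (nlevels(p) < 2L) stop_scratchval("at least 2 participants are required.")
  d <- pairs[[dht_col]] - pairs[[ref_col]]

  fit_once <- function(d, p, how) {
    if (how != "reml" || stats::var(d) < 1e-12) return(ba_moment(d, p))
    msgs <- character()
    fit <- withCallingHandlers(
      tryCatch(lme4::lmer(d ~ 1 + (1 | p),
                          control = lme4::lmerControl(calc.derivs = FALSE,
                                                      check.conv.singular = "ignore")),
               error = function(e) NULL),
      warning = function(w) invokeRestart("muffleWarning"),
      message = function(m) invokeRestart("muffleMessage"))
    if (is.null(fit)) return(ba_moment(d, p))
    vc <- as.data.frame(lme4::VarCorr(fit))
    list(bias = unname(lme4::fixef(fit)[1]),
         var_between = vc$vcov[vc$grp == "p"][1],
         var_within = vc$vcov[vc$grp == "Residual"][1])
  }
  how <- if (method == "moment") "moment" else "reml"
  est <- fit_once(d, p, how)
  sd_total <- sqrt(est$var_between + est$var_within)
  loa <- est$bias + c(-1, 1) * 1.96 * sd_total

  ci <- NULL
  if (n_boot > 0) {
    idx_by_p <- split(seq_along(d), p)
    P <- length(idx_by_p)
    draws <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      ids <- sample.int(P, P, replace = TRUE)
      rows <- unlist(idx_by_p[ids], use.names = FALSE)
      bp <- factor(rep(seq_len(P), lengths(idx_by_p)[ids]))
      b <- ba_moment(d[rows], bp)
      s <- sqrt(b$var_between + b$var_within)
      c(b$bias, b$bias - 1.96 * s, b$bias + 1.96 * s)
    }, numeric(3)))
    qs <- apply(draws, 1, stats::quantile, probs = c(0.025, 0.975))
    ci <- tibble::tibble(quantity = c("bias", "loa_low", "loa_high"),
                         ci_low = qs[1, ], ci_high = qs[2, ])
  }
  structure(
    list(bias = est$bias, loa_low = loa[1], loa_high = loa[2],
         sd_total = sd_total,
         var_between = est$var_between, var_within = est$var_within,
         ci = ci, n_pairs = length(d), n_participants = nlevels(p),
         data = tibble::tibble(participant_id = pairs$participant_id,
                               mean_value = (pairs[[dht_col]] + pairs[[ref_col]]) / 2,
                               difference = d)),
    class = "scratch_ba")
}

#' @export
print.scratch_ba <- function(x, ...) {
  cat(sprintf("Bland-Altman (repeated measures): bias %.3f, 95%% LoA [%.3f, %.3f]\n",
              x$bias, x$loa_low, x$loa_high))
  cat(sprintf("  %d pairs from %d participants\n", x$n_pairs, x$n_participants))
  invisible(x)
}
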