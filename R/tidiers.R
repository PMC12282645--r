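# broom-style tidiers for the fitted agreement objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a variance-component fit
#'
#' @param x A `scratch_vc` from [fit_variance_components()].
#' @param ... Unused.
#' @return One row per component: `term`, `variance`.
#' @export
tidy.scratch_vc <- function(x, ...) {
  tibble::tibble(term = c("participant", "night", "residual"),
                 variance = c(x$var_participant, x$var_night, x$var_residual))
}

#' @rdname tidy.scratch_vc
#' @export
glance.scratch_vc <- function(x, ...) {
  tibble::tibble(method = x$method, converged = x$converged,
                 var_fixed = x$var_fixed,
                 n_participants = x$n_participants, n_obs = x$n_obs)
}

#' Tidy a bootstrap ICC result
#'
#' @param x A `scratch_icc` from [bootstrap_icc()].
#' @param ... Unused.
#' @return One row per ICC definition with estimate and bootstrap CI.
#' @export
tidy.scratch_icc <- function(x, ...) x$estimates

#' @rdname tidy.scratch_icc
#' @export
glance.scratch_icc <- function(x, ...) {
  tibble::tibble(n_bootstrap = x$n_bootstrap,
                 n_nonconverged = x$n_nonconverged,
                 flagged = x$flagged, conf = x$conf,
                 n_participants = x$vc$n_participants, n_obs = x$vc$n_obs)
}

#' Tidy a repeated-measures Bland-Altman result
#'
#' @param x A `scratch_ba` from [bland_altman_repeated()].
#' @param ... Unused.
#' @return One row per quantity (`bias`, `loa_low`, `loa_high`) with its
#'   estimate and bootstrap CI (CIs `NA` when `n_boot = 0`).
#' @export
tidy.scratch_ba <- function(x, ...) {
  est <- tibble::tibble(quantity = c("bias", "loa_low", "loa_high"),
                        estimate = c(x$bias, x$loa_low, x$loa_high))
  if (!is.null(x$ci)) est <- dplyr::left_join(est, x$ci, by = "quantity")
  est
}

#' @rdname tidy.scratch_ba
#' @export
glance.scratch_ba <- function(x, ...) {
  tibble::tibble(sd_total = x$sd_total, var_between = x$var_between,
                 var_within = x$var_within,
                 n_pairs = x$n_pairs, n_participants = x$n_participants)
}
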