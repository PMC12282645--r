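# Plotting. ggplot2 throughout; each fitted result type gets an autoplot.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bland-Altman plot
#'
#' Each point is one participant-night (difference vs pair mean); the solid
#' line is the bias and the dashed lines the 95\% limits of agreement.
#'
#' @param object A `scratch_ba`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scratch_ba <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$mean_value, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of DHT and Reference (h)",
                  y = "DHT - Reference (h)",
                  title = sprintf("Bland-Altman: bias %.2f h, LoA [%.2f, %.2f] h",
                                  object$bias, object$loa_low, object$loa_high)) +
    ggplot2::theme_minimal()
}

#' ICC point estimate with bootstrap CI
#'
#' @param object A `scratch_icc`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scratch_icc <- function(object, ...) {
  ggplot2::ggplot(object$estimates,
                  ggplot2::aes(x = .data$definition, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "ICC") +
    ggplot2::theme_minimal()
}

#' ICC comparison dot-and-whisker chart
#'
#' Fig.-style summary of a report's ICC table: point estimates with 95\%
#' bootstrap CIs per source comparison, faceted by outcome.
#'
#' @param icc_table The `icc_table` element of a report (or any tibble with
#'   `comparison`, `outcome`, `definition`, `estimate`, `ci_low`,
#'   `ci_high`).
#' @param definition Which ICC definition to show (default `"adjusted"`).
#' @return A ggplot.
#' @export
plot_icc_comparisons <- function(icc_table, definition = "adjusted") {
  d <- dplyr::filter(icc_table, .data$definition == !!definition)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$comparison, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::facet_wrap(~.data$outcome) +
    ggplot2::coord_flip(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = sprintf("ICC (%s)", definition)) +
    ggplot2::theme_minimal()
}

#' Box plots of night or participant outcomes by group
#'
#' Linear scale, original units, one panel per outcome — the standard way
#' to compare normalized scratch duration and frequency across cohorts or
#' itch bands.
#'
#' @param summaries Night- or participant-level summaries with
#'   `norm_duration` and `norm_frequency`.
#' @param by Grouping column name (default `"cohort"`).
#' @return A ggplot.
#' @export
plot_outcomes <- function(summaries, by = "cohort") {
  long <- tidyr::pivot_longer(
    dplyr::select(summaries, dplyr::all_of(by), "norm_duration", "norm_frequency"),
    cols = c("norm_duration", "norm_frequency"),
    names_to = "outcome", values_to = "value")
  labs <- c(norm_duration = "scratch duration (s/h of TSO)",
            norm_frequency = "scratch frequency (bouts/h of TSO)")
  long$outcome <- labs[long$outcome]
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[by]], y = .data$value)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::facet_wrap(~.data$outcome, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
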