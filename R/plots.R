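#' Plot per-procedure savings ranges
#'
#' Range plot of the projected per-patient savings for each procedure, the
#' bounds corresponding to the two morbidity-reduction bounds of the
#' effect size.
#'
#' @param object A `gdft_procedure_savings` tibble from
#'   [per_procedure_savings()].
#' @param per_year Plot annual total savings (millions USD) instead of
#'   per-patient savings.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gdft_procedure_savings <- function(object, per_year = FALSE, ...) {
  check_flag(per_year, "per_year")
  d <- dplyr::mutate(object,
                     procedure = factor(.data$procedure,
                                        levels = rev(procedure_levels())))
  if (per_year) {
    d <- dplyr::mutate(d,
                       lo = .data$savings_per_year_low / 1e6,
                       hi = .data$savings_per_year_high / 1e6,
                       mid = (.data$lo + .data$hi) / 2)
    xlab <- "Projected savings per year (million USD)"
  } else {
    d <- dplyr::mutate(d,
                       lo = .data$savings_per_patient_low,
                       hi = .data$savings_per_patient_high,
                       mid = (.data$lo + .data$hi) / 2)
    xlab <- "Projected savings per patient (USD)"
  }
  ggplot(d, aes(y = .data$procedure)) +
    geom_linerange(aes(xmin = .data$lo, xmax = .data$hi), linewidth = 1.2) +
    geom_point(aes(x = .data$mid), size = 2) +
    labs(x = xlab, y = NULL) +
    theme_minimal()
}

#' Plot bed-day capacity gains
#'
#' Bar plot of bed-days lost to complications against the range of
#' bed-days recoverable with GDFT.
#'
#' @param object A `gdft_bed_days` tibble from [project_bed_days()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gdft_bed_days <- function(object, ...) {
  d <- tibble(
    quantity = factor(c("Bed-days lost", "Bed-days recoverable"),
                      levels = c("Bed-days lost", "Bed-days recoverable")),
    lo = c(object$days_lost, object$days_saved_low),
    hi = c(object$days_lost, object$days_saved_high)
  )
  ggplot(d, aes(x = .data$quantity)) +
    geom_col(aes(y = .data$hi), fill = "grey80") +
    geom_errorbar(aes(ymin = .data$lo, ymax = .data$hi), width = 0.2) +
    labs(x = NULL, y = "Days over the study period") +
    theme_minimal()
}

#' Plot group cost summaries
#'
#' Mean total cost by complication group, per procedure, from a
#' [summarize_cohort()] table computed with `by_procedure = TRUE`.
#'
#' @param summary A [summarize_cohort()] tibble.
#' @return A ggplot object.
#' @export
plot_cost_summary <- function(summary) {
  d <- dplyr::filter(summary, .data$scope != "all", !is.na(.data$cost_mean))
  if (nrow(d) == 0) d <- dplyr::filter(summary, !is.na(.data$cost_mean))
  ggplot(d, aes(x = .data$cost_mean,
                y = factor(.data$scope, levels = rev(unique(.data$scope))),
                fill = .data$group)) +
    geom_col(position = "dodge") +
    labs(x = "Mean total cost (USD)", y = NULL, fill = NULL) +
    theme_minimal() +
    theme(legend.position = "bottom")
}
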