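check_frame <- function(frame) {
  if (!inherits(frame, "gdft_frame")) {
    abort("`frame` must be a gdft_frame from study_frame().")
  }
  invisible(frame)
}

check_effect <- function(effect) {
  if (!inherits(effect, "gdft_effect")) {
    abort("`effect` must be a gdft_effect from gdft_effect().")
  }
  invisible(effect)
}

# Morbidity rate as printed: percent, one decimal, round half up.
morbidity_pct_1dp <- function(n_complications, n_total) {
  round_half_up(100 * n_complications / n_total, 1)
}

#' Project post-GDFT morbidity from an odds-ratio effect
#'
#' Applies each odds-ratio bound of the effect to the observed complication
#' burden. Under `count_scaling` (the reference arithmetic) the projected
#' complication count is `round(n_complications * OR)`, i.e. the OR is
#' treated as a relative risk; under `odds_transform` the baseline
#' proportion is mapped through the odds scale,
#' `p' = OR * p / (1 - p + OR * p)`, and the count is `round(n_total * p')`.
#' At small baseline morbidity the two coincide; at the reference baseline
#' of 37.5% the odds transform projects a smaller reduction.
#'
#' @param frame A [study_frame()].
#' @param effect A [gdft_effect()].
#' @return A tibble with one row per odds-ratio bound: `or`, `reduction`
#'   (`1 - or`), `projected_n` (count, rounded half up), `projected_rate`
#'   (% of `n_total`, one decimal), `averted` (observed minus projected
#'   count).
#' @export
#' @examples
#' project_morbidity(reference_study_frame(), gdft_effect())
project_morbidity <- function(frame, effect) {
  check_frame(frame)
  check_effect(effect)
  or <- c(effect$or_low, effect$or_high)
  p <- frame$n_complications / frame$n_total
  projected_n <- switch(
    effect$interpretation,
    count_scaling = round_half_up(frame$n_complications * or),
    odds_transform = round_half_up(
      frame$n_total * or * p / (1 - p + or * p))
  )
  tibble(
    or = or,
    reduction = 1 - or,
    projected_n = projected_n,
    projected_rate = round_half_up(100 * projected_n / frame$n_total, 1),
    averted = frame$n_complications - projected_n
  )
}

#' Project gross cost savings from averted complications
#'
#' The budget-impact core: for each odds-ratio bound, the number of averted
#' complications (observed minus projected count, see
#' [project_morbidity()]) is multiplied by the mean excess cost of a
#' complication to give gross savings over the study period, divided by the
#' period length for annual savings, and expressed per patient.
#'
#' Per-patient savings follow the printed-table arithmetic: the morbidity
#' rate rounded to one decimal percent times the morbidity reduction times
#' the excess cost, rounded half up to whole dollars. (Dividing the gross
#' total by `n_total` differs from this by at most a few dollars through
#' rounding; the table arithmetic is what the published per-patient figures
#' use.)
#'
#' @param frame A [study_frame()].
#' @param effect A [gdft_effect()].
#' @return A one-row tibble of class `gdft_savings`:
#'   `n_projected_low`/`_high`, `morbidity_projected_low`/`_high` (%),
#'   `savings_total_low`/`_high` (USD over the period),
#'   `savings_per_year_low`/`_high`, `savings_per_patient_low`/`_high`
#'   (whole USD). `low`/`high` order the numeric value of each quantity, so
#'   e.g. `savings_total_low` corresponds to the weaker effect (higher OR).
#' @export
#' @examples
#' project_savings(reference_study_frame(), gdft_effect())
project_savings <- function(frame, effect) {
  check_frame(frame)
  check_effect(effect)
  proj <- project_morbidity(frame, effect)
  totals <- proj$averted * frame$cost_diff
  p1 <- morbidity_pct_1dp(frame$n_complications, frame$n_total) / 100
  per_patient <- round_half_up(p1 * proj$reduction * frame$cost_diff)
  out <- tibble(
    n_projected_low = min(proj$projected_n),
    n_projected_high = max(proj$projected_n),
    morbidity_projected_low = min(proj$projected_rate),
    morbidity_projected_high = max(proj$projected_rate),
    savings_total_low = min(totals),
    savings_total_high = max(totals),
    savings_per_year_low = min(totals) / frame$period_years,
    savings_per_year_high = max(totals) / frame$period_years,
    savings_per_patient_low = min(per_patient),
    savings_per_patient_high = max(per_patient)
  )
  class(out) <- c("gdft_savings", class(out))
  out
}

#' Excess cost burden of postoperative complications
#'
#' Total spending attributable to complications over the study period:
#' the complication count times the mean excess cost per complicated
#' admission, with its annual equivalent.
#'
#' @param frame A [study_frame()].
#' @return A one-row tibble: `total` and `per_year`, USD.
#' @export
#' @examples
#' excess_cost_burden(reference_study_frame())  # > $908M, ~$363M/year
excess_cost_burden <- function(frame) {
  check_frame(frame)
  total <- frame$n_complications * frame$cost_diff
  tibble(total = total, per_year = total / frame$period_years)
}

#' Per-procedure savings projection
#'
#' Expected per-patient savings with GDFT for each procedure: the
#' procedure's morbidity rate times the morbidity-reduction bound times the
#' procedure's excess complication cost, rounded half up to whole dollars
#' (the printed-table arithmetic); annual savings scale the unrounded
#' per-patient value by the procedure volume over the period.
#'
#' @param rows A tibble with columns `procedure`, `morbidity` (proportion),
#'   `cost_diff` (USD) and `n` (procedure volume over the period);
#'   [procedure_parameters()] provides the published values, and
#'   [cohort_savings_inputs()] derives them from a patient-level cohort.
#' @param effect A [gdft_effect()] (only the reduction bounds `1 - or` are
#'   used; per-procedure counts are not projected here).
#' @param period_years Study period length in years.
#' @return A tibble of class `gdft_procedure_savings` with one row per
#'   procedure: `procedure`, `morbidity` (%), `cost_diff`, `n`,
#'   `savings_per_patient_low`/`_high` (whole USD),
#'   `savings_per_year_low`/`_high` (USD/year).
#' @export
#' @examples
#' per_procedure_savings(procedure_parameters(), gdft_effect())
per_procedure_savings <- function(rows, effect, period_years = 2.5) {
  check_effect(effect)
  check_number(period_years, "period_years", min = .Machine$double.eps)
  needed <- setdiff(c("procedure", "morbidity", "cost_diff", "n"), names(rows))
  if (length(needed) > 0) {
    abort(sprintf("`rows` is missing column(s): %s.",
                  paste(needed, collapse = ", ")))
  }
  red_low <- 1 - effect$or_high
  red_high <- 1 - effect$or_low
  out <- dplyr::transmute(
    as_tibble(rows),
    procedure = .data$procedure,
    morbidity = 100 * .data$morbidity,
    cost_diff = .data$cost_diff,
    n = .data$n,
    savings_per_patient_low =
      round_half_up(.data$morbidity / 100 * red_low * .data$cost_diff),
    savings_per_patient_high =
      round_half_up(.data$morbidity / 100 * red_high * .data$cost_diff),
    savings_per_year_low =
      .data$n * .data$morbidity / 100 * red_low * .data$cost_diff / period_years,
    savings_per_year_high =
      .data$n * .data$morbidity / 100 * red_high * .data$cost_diff / period_years
  )
  class(out) <- c("gdft_procedure_savings", class(out))
  out
}

#' Derive per-procedure savings inputs from a cohort
#'
#' Computes, for each procedure present in a patient-level cohort, the
#' inputs [per_procedure_savings()] needs: volume, morbidity (rounded to
#' one decimal percent, as in the printed tables), and the excess mean cost
#' of complicated admissions over records with valid cost data (rounded to
#' whole dollars).
#'
#' @param cohort A validated cohort tibble.
#' @return A tibble with columns `procedure`, `n`, `morbidity` (proportion)
#'   and `cost_diff`.
#' @export
cohort_savings_inputs <- function(cohort) {
  if (nrow(cohort) == 0) abort("Cohort is empty.")
  valid <- cohort[cohort$cost_valid & !is.na(cohort$cost), ]
  means <- valid |>
    dplyr::group_by(.data$procedure, .data$complication) |>
    dplyr::summarise(cost_mean = mean(.data$cost), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "complication", values_from = "cost_mean",
                       names_prefix = "m_")
  cohort |>
    dplyr::group_by(.data$procedure) |>
    dplyr::summarise(n = dplyr::n(),
                     morbidity = round_half_up(100 * mean(.data$complication), 1) / 100,
                     .groups = "drop") |>
    dplyr::left_join(means, by = "procedure") |>
    dplyr::mutate(cost_diff = round_half_up(.data$m_TRUE - .data$m_FALSE)) |>
    dplyr::select("procedure", "n", "morbidity", "cost_diff") |>
    dplyr::arrange(match(.data$procedure, procedure_levels()))
}

#' Derive an aggregate study frame from a cohort
#'
#' @param cohort A validated cohort tibble.
#' @param period_years Study period length in years.
#' @return A [study_frame()] with the cohort's size, complication count and
#'   excess mean cost (cost-valid records, rounded to whole dollars).
#' @export
frame_from_cohort <- function(cohort, period_years = 2.5) {
  if (nrow(cohort) == 0) abort("Cohort is empty.")
  valid <- cohort[cohort$cost_valid & !is.na(cohort$cost), ]
  m <- tapply(valid$cost, valid$complication, mean)
  if (any(is.na(m[c("TRUE", "FALSE")]))) {
    abort("Both complication groups need at least one cost-valid record.")
  }
  study_frame(
    n_total = nrow(cohort),
    n_complications = sum(cohort$complication),
    cost_diff = max(0, round_half_up(m[["TRUE"]] - m[["FALSE"]])),
    period_years = period_years
  )
}
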