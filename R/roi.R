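#' Implementation cost per patient
#'
#' Per-patient cost of GDFT monitoring: the disposable sensor plus the
#' monitor price amortized over its lifetime usage
#' (`uses_per_week * weeks_per_year * lifetime_years` patients).
#'
#' @param cost An [implementation_cost()] object.
#' @return A one-row tibble: `sensor`, `amortization`, `total` (all USD,
#'   unrounded) and `total_rounded` (whole USD, half up).
#' @export
#' @examples
#' implementation_cost_per_patient(implementation_cost())  # $298.08
implementation_cost_per_patient <- function(cost = implementation_cost()) {
  if (!inherits(cost, "gdft_impl_cost")) {
    abort("`cost` must come from implementation_cost().")
  }
  uses <- cost$uses_per_week * cost$weeks_per_year * cost$lifetime_years
  if (uses <= 0) abort("Monitor lifetime usage is zero; cannot amortize.")
  amort <- cost$monitor_price / uses
  total <- cost$sensor_cost + amort
  tibble(sensor = cost$sensor_cost, amortization = amort, total = total,
         total_rounded = round_half_up(total))
}

#' Savings returned per dollar spent
#'
#' Ratio of projected per-patient savings to per-patient implementation
#' cost, for each savings bound, reported to one decimal (half up). With
#' the reference savings of US$754-1286 against a US$300 implementation
#' cost the ratio is 2.5-4.3 (the source rounds the upper bound down to
#' "US$4" in prose).
#'
#' @param savings_per_patient_low,savings_per_patient_high Projected
#'   per-patient savings bounds, USD.
#' @param impl_cost_per_patient Per-patient implementation cost, USD (> 0).
#' @return A one-row tibble: `impl_cost_per_patient`, `roi_low`, `roi_high`.
#' @export
#' @examples
#' roi_ratio(754, 1286, 300)
roi_ratio <- function(savings_per_patient_low, savings_per_patient_high,
                      impl_cost_per_patient) {
  check_number(savings_per_patient_low, "savings_per_patient_low", min = 0)
  check_number(savings_per_patient_high, "savings_per_patient_high",
               min = savings_per_patient_low)
  check_number(impl_cost_per_patient, "impl_cost_per_patient",
               min = .Machine$double.eps)
  tibble(
    impl_cost_per_patient = impl_cost_per_patient,
    roi_low = round_half_up(savings_per_patient_low / impl_cost_per_patient, 1),
    roi_high = round_half_up(savings_per_patient_high / impl_cost_per_patient, 1)
  )
}

#' Bed-day opportunity cost and capacity gain
#'
#' Complicated admissions occupy beds longer: with a median excess stay of
#' `excess_los` days, the observed complication count represents
#' `n_complications * excess_los` bed-days lost. Averting complications
#' (per [project_morbidity()], applied to each effect bound) recovers
#' `averted * excess_los` days, which at an average stay of `avg_los` days
#' corresponds to newly admissible patients over the period and per year.
#'
#' Rounding follows the printed arithmetic: averted counts are integers
#' before multiplying by `excess_los`; new-patient counts round half up,
#' and the per-year figures round the (already rounded) patient count
#' divided by the period, half up.
#'
#' @param frame A [study_frame()].
#' @param effect A [gdft_effect()].
#' @param excess_los Median excess length of stay of a complicated
#'   admission, days; default 3.
#' @param avg_los Average length of stay across the cohort, days; default 5.
#' @return A one-row tibble of class `gdft_bed_days`: `days_lost`,
#'   `days_saved_low`/`_high`, `new_patients_low`/`_high`,
#'   `new_patients_per_year_low`/`_high`.
#' @export
#' @examples
#' project_bed_days(reference_study_frame(), gdft_effect())
project_bed_days <- function(frame, effect, excess_los = 3, avg_los = 5) {
  check_frame(frame)
  check_effect(effect)
  check_number(excess_los, "excess_los", min = .Machine$double.eps)
  check_number(avg_los, "avg_los", min = .Machine$double.eps)
  proj <- project_morbidity(frame, effect)
  days_saved <- proj$averted * excess_los
  new_patients <- round_half_up(days_saved / avg_los)
  per_year <- round_half_up(new_patients / frame$period_years)
  out <- tibble(
    days_lost = frame$n_complications * excess_los,
    days_saved_low = min(days_saved),
    days_saved_high = max(days_saved),
    new_patients_low = min(new_patients),
    new_patients_high = max(new_patients),
    new_patients_per_year_low = min(per_year),
    new_patients_per_year_high = max(per_year)
  )
  class(out) <- c("gdft_bed_days", class(out))
  out
}
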