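#' Canonical surgical procedure labels
#'
#' The ten major non-cardiac procedures covered by the model, in the fixed
#' canonical order used throughout the package. Procedure matching elsewhere
#' is case-insensitive with surrounding whitespace stripped, but these exact
#' strings are what the package writes out.
#'
#' @return Character vector of length 10.
#' @export
#' @examples
#' procedure_levels()
procedure_levels <- function() {
  c(
    "AAA open repair",
    "vascular bypass",
    "esophagectomy",
    "gastrectomy",
    "colectomy",
    "resection of rectum",
    "hepatectomy",
    "pancreatectomy",
    "cystectomy",
    "femur & hip fracture repair"
  )
}

#' Published procedure-level parameters
#'
#' Per-procedure estimates from a nationwide US claims analysis of 204,680
#' major non-cardiac surgical admissions (January 2011 to June 2013, 541
#' hospitals): patient counts, morbidity rates (proportion of admissions with
#' one or more in-hospital postoperative complications), mean/SD total cost
#' (index stay plus 30-day readmission, USD) by complication group, hospital
#' length-of-stay median and quartiles (days) by group, and 30-day
#' readmission rates by group. `cost_diff` is the with-minus-without
#' difference in mean cost, the marginal cost of a complicated admission.
#'
#' These values parameterize the synthetic cohort generator
#' ([simulate_cohort()]) and feed the per-procedure savings projection
#' ([per_procedure_savings()]).
#'
#' @return A tibble with one row per procedure and columns `procedure`, `n`,
#'   `morbidity` (proportion), `cost_mean_with`, `cost_sd_with`,
#'   `cost_mean_without`, `cost_sd_without`, `cost_diff`,
#'   `los_median_with`, `los_q25_with`, `los_q75_with`, `los_median_without`,
#'   `los_q25_without`, `los_q75_without`, `readmit_with`, `readmit_without`
#'   (proportions).
#' @export
#' @examples
#' procedure_parameters()
procedure_parameters <- function() {
  out <- tibble::tribble(
    ~procedure, ~n, ~morbidity,
    ~cost_mean_with, ~cost_sd_with, ~cost_mean_without, ~cost_sd_without,
    ~los_median_with, ~los_q25_with, ~los_q75_with,
    ~los_median_without, ~los_q25_without, ~los_q75_without,
    ~readmit_with, ~readmit_without,
    "AAA open repair",             2328L,  0.649, 48002, 48841, 24619, 14543,  8,  6, 14, 6, 4,  7, 0.165, 0.087,
    "vascular bypass",             16336L, 0.263, 31979, 30386, 16849, 12543,  6,  4,  9, 3, 2,  5, 0.213, 0.141,
    "esophagectomy",               690L,   0.677, 67924, 65377, 37382, 17973, 13,  9, 20, 9, 8, 11, 0.185, 0.154,
    "gastrectomy",                 25118L, 0.202, 27794, 33530, 12641,  9452,  4,  2, 10, 2, 1,  2, 0.127, 0.052,
    "colectomy",                   75121L, 0.433, 27851, 29286, 14755, 10524,  8,  5, 11, 4, 3,  6, 0.152, 0.090,
    "resection of rectum",         10753L, 0.336, 26916, 24466, 15979, 18855,  7,  5, 11, 5, 3,  6, 0.152, 0.104,
    "hepatectomy",                 2362L,  0.343, 37315, 38100, 20272, 13566,  7,  5, 11, 5, 3,  6, 0.179, 0.094,
    "pancreatectomy",              3569L,  0.475, 50559, 46784, 27488, 19653, 11,  8, 18, 7, 5,  9, 0.261, 0.186,
    "cystectomy",                  2552L,  0.589, 41128, 38293, 25978, 15061, 10,  7, 14, 7, 6,  8, 0.292, 0.219,
    "femur & hip fracture repair", 65851L, 0.385, 22218, 32644, 16805, 12167,  5,  4,  7, 4, 3,  5, 0.189, 0.174
  )
  dplyr::mutate(out, cost_diff = .data$cost_mean_with - .data$cost_mean_without,
                .after = "cost_sd_without")
}

#' Aggregate study frame
#'
#' The overall quantities the budget-impact projection needs: cohort size,
#' number of patients with one or more postoperative complications, the mean
#' excess cost of a complicated versus uncomplicated admission, and the
#' length of the observation period in years.
#'
#' @param n_total Number of surgical admissions.
#' @param n_complications Number of admissions with at least one in-hospital
#'   postoperative complication. Must not exceed `n_total`.
#' @param cost_diff Mean excess total cost of a complicated admission, USD
#'   (non-negative).
#' @param period_years Length of the study period in years (> 0).
#'
#' @return A one-row tibble of class `gdft_frame`.
#' @seealso [reference_study_frame()] for the published defaults.
#' @export
study_frame <- function(n_total, n_complications, cost_diff,
                        period_years = 2.5) {
  check_number(n_total, "n_total", min = 1, integer = TRUE)
  check_number(n_complications, "n_complications", min = 0, max = n_total,
               integer = TRUE)
  check_number(cost_diff, "cost_diff", min = 0)
  check_number(period_years, "period_years", min = .Machine$double.eps)
  out <- tibble(
    n_total = as.integer(n_total),
    n_complications = as.integer(n_complications),
    cost_diff = as.numeric(cost_diff),
    period_years = as.numeric(period_years)
  )
  class(out) <- c("gdft_frame", class(out))
  out
}

#' Published aggregate study frame
#'
#' The headline aggregates of the reference analysis: 204,680 admissions, of
#' which 76,807 (37.5%) had one or more complications; complicated
#' admissions cost on average US$11,824 more; the study window (January 2011
#' to June 2013) spans 2.5 years.
#'
#' @param period_years Study period length in years; default 2.5.
#' @return A `gdft_frame` tibble (see [study_frame()]).
#' @export
#' @examples
#' reference_study_frame()
reference_study_frame <- function(period_years = 2.5) {
  study_frame(204680, 76807, 11824, period_years)
}

#' GDFT morbidity effect size
#'
#' The effect of goal-directed fluid therapy on postoperative morbidity,
#' expressed as the odds-ratio confidence bounds of a meta-analysis of
#' randomized trials (OR 0.77, 95% CI 0.71 to 0.83). Two interpretations of
#' applying an odds ratio to a baseline proportion are supported:
#'
#' * `"count_scaling"` (default): multiply the complication count directly
#'   by the OR, i.e. treat the OR as a relative risk. This is the arithmetic
#'   the reference analysis uses and reproduces its printed figures, but at
#'   a baseline morbidity of 37.5% it overstates the reduction relative to
#'   the odds-correct transform.
#' * `"odds_transform"`: map the baseline proportion through the odds scale,
#'   `p' = OR * p / (1 - p + OR * p)`, which is exact for an odds ratio.
#'
#' @param or_low Lower odds-ratio bound, in (0, 1]; default 0.71.
#' @param or_high Upper odds-ratio bound, in `[or_low, 1]`; default 0.83.
#' @param interpretation `"count_scaling"` or `"odds_transform"`.
#' @return An object of class `gdft_effect`.
#' @export
#' @examples
#' gdft_effect()                                  # published bounds
#' gdft_effect(0.38, 0.38, "odds_transform")      # a point estimate, odds-correct
gdft_effect <- function(or_low = 0.71, or_high = 0.83,
                        interpretation = c("count_scaling", "odds_transform")) {
  check_number(or_low, "or_low", min = .Machine$double.eps, max = 1)
  check_number(or_high, "or_high", min = or_low, max = 1)
  interpretation <- match.arg(interpretation)
  structure(
    list(or_low = or_low, or_high = or_high, interpretation = interpretation),
    class = "gdft_effect"
  )
}

#' @export
print.gdft_effect <- function(x, ...) {
  cat(sprintf("<gdft_effect> OR %.2f-%.2f (%s), morbidity reduction %.0f-%.0f%%\n",
              x$or_low, x$or_high, x$interpretation,
              100 * (1 - x$or_high), 100 * (1 - x$or_low)))
  invisible(x)
}

#' Per-patient implementation cost of GDFT monitoring
#'
#' Cost model for cardiac-output monitoring: a disposable sensor per patient
#' plus straight-line amortization of the monitor over its lifetime usage
#' (`uses_per_week * weeks_per_year * lifetime_years` patients). With the
#' defaults (US$250 sensor, US$15,000 monitor used twice a week for 3
#' years), the amortization is 15,000/312 = US$48.08 and the total is
#' US$298.08 per patient, commonly rounded to US$300.
#'
#' @param sensor_cost Disposable sensor cost per patient, USD (> 0).
#' @param monitor_price Monitor acquisition price, USD (> 0).
#' @param uses_per_week Patients monitored per week per monitor (> 0).
#' @param lifetime_years Monitor lifetime in years (> 0).
#' @param weeks_per_year Operating weeks per year; default 52.
#' @return An object of class `gdft_impl_cost`.
#' @seealso [implementation_cost_per_patient()]
#' @export
implementation_cost <- function(sensor_cost = 250, monitor_price = 15000,
                                uses_per_week = 2, lifetime_years = 3,
                                weeks_per_year = 52) {
  for (nm in c("sensor_cost", "monitor_price", "uses_per_week",
               "lifetime_years", "weeks_per_year")) {
    check_number(get(nm), nm, min = 0)
  }
  if (uses_per_week * weeks_per_year * lifetime_years <= 0) {
    abort("Monitor usage (uses_per_week x weeks_per_year x lifetime_years) must be positive.")
  }
  structure(
    list(sensor_cost = sensor_cost, monitor_price = monitor_price,
         uses_per_week = uses_per_week, lifetime_years = lifetime_years,
         weeks_per_year = weeks_per_year),
    class = "gdft_impl_cost"
  )
}

#' @export
print.gdft_impl_cost <- function(x, ...) {
  pp <- implementation_cost_per_patient(x)
  cat(sprintf("<gdft_impl_cost> sensor $%.0f + amortization $%.2f = $%.2f/patient\n",
              x$sensor_cost, pp$amortization, pp$total))
  invisible(x)
}
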