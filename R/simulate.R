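#' Synthetic cohort specification
#'
#' Bundles everything the generator needs: the per-procedure parameter table
#' (counts, morbidity, cost moments, LOS quartiles, readmission rates), the
#' complication-group demographic marginals, and the per-group rates of
#' invalid cost records. [default_cohort_spec()] fills all of it with the
#' published estimates, so a cohort generated from the default spec has the
#' statistical structure of the reference population of 204,680 admissions.
#'
#' @param procedures A tibble shaped like [procedure_parameters()].
#' @param demographics A two-row tibble (groups `"with"`, `"without"`) with
#'   columns `age_mean`, `age_sd`, `p_female`, `p_elective`, `cci_mean`.
#' @param invalid_cost_rate Named numeric, probabilities that a record's
#'   cost data is invalid, for groups `with` and `without`.
#' @return An object of class `gdft_cohort_spec`.
#' @export
cohort_spec <- function(procedures, demographics, invalid_cost_rate) {
  stopifnot(is.data.frame(procedures), is.data.frame(demographics))
  needed <- setdiff(names(procedure_parameters()), names(procedures))
  if (length(needed) > 0) {
    abort(sprintf("`procedures` is missing column(s): %s.",
                  paste(needed, collapse = ", ")))
  }
  with(procedures, {
    stopifnot(
      all(n >= 1), all(morbidity > 0 & morbidity < 1),
      all(cost_mean_with > 0), all(cost_sd_with > 0),
      all(cost_mean_without > 0), all(cost_sd_without > 0),
      all(los_q25_with <= los_median_with & los_median_with <= los_q75_with),
      all(los_q25_without <= los_median_without &
            los_median_without <= los_q75_without),
      all(readmit_with > 0 & readmit_with < 1),
      all(readmit_without > 0 & readmit_without < 1)
    )
  })
  stopifnot(
    all(c("with", "without") %in% names(invalid_cost_rate)),
    all(invalid_cost_rate >= 0 & invalid_cost_rate < 1),
    all(c("group", "age_mean", "age_sd", "p_female", "p_elective",
          "cci_mean") %in% names(demographics)),
    all(c("with", "without") %in% demographics$group)
  )
  structure(
    list(procedures = as_tibble(procedures),
         demographics = as_tibble(demographics),
         invalid_cost_rate = invalid_cost_rate[c("with", "without")]),
    class = "gdft_cohort_spec"
  )
}

#' @rdname cohort_spec
#' @details The default invalid-cost rates reproduce the published data
#'   completeness: 73,108 of 76,807 complicated and 127,398 of 127,873
#'   uncomplicated admissions had valid cost data (about 4.8% and 0.4%
#'   invalid respectively).
#' @export
default_cohort_spec <- function() {
  cohort_spec(
    procedures = procedure_parameters(),
    demographics = tibble(
      group = c("with", "without"),
      age_mean = c(68.8, 62.4),
      age_sd = c(16.0, 17.4),
      p_female = c(0.584, 0.590),
      p_elective = c(0.452, 0.605),
      cci_mean = c(2.2, 1.5)
    ),
    invalid_cost_rate = c(with = 1 - 73108 / 76807,
                          without = 1 - 127398 / 127873)
  )
}

#' @export
print.gdft_cohort_spec <- function(x, ...) {
  cat(sprintf("<gdft_cohort_spec> %d procedures, %s admissions total\n",
              nrow(x$procedures), format(sum(x$procedures$n), big.mark = ",")))
  invisible(x)
}

# One RNG substream per (procedure x purpose); seeds are drawn once from a
# master stream so a single integer seed fixes the whole cohort.
substream_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Draw from a normal truncated below at `lower` via inverse-CDF.
rtruncnorm_lower <- function(n, mean, sd, lower) {
  p0 <- pnorm(lower, mean, sd)
  qnorm(runif(n, p0, 1), mean, sd)
}

# Attributes for n_g records of one complication group within one procedure.
generate_group <- function(n_g, proc_row, demo_row, invalid_rate, group) {
  if (n_g == 0) return(NULL)
  suffix <- if (group == "with") "_with" else "_without"
  cm <- proc_row[[paste0("cost_mean", suffix)]]
  cs <- proc_row[[paste0("cost_sd", suffix)]]
  med <- proc_row[[paste0("los_median", suffix)]]
  q25 <- proc_row[[paste0("los_q25", suffix)]]
  q75 <- proc_row[[paste0("los_q75", suffix)]]

  age <- rtruncnorm_lower(n_g, demo_row$age_mean, demo_row$age_sd, 18)
  gender <- ifelse(rbinom(n_g, 1, demo_row$p_female) == 1, "female", "male")
  elective <- rbinom(n_g, 1, demo_row$p_elective) == 1
  cci <- rpois(n_g, demo_row$cci_mean)

  # Gamma by moment matching: shape (m/s)^2, scale s^2/m. Whole-dollar costs.
  cost <- round(rgamma(n_g, shape = (cm / cs)^2, scale = cs^2 / cm))
  cost_valid <- rbinom(n_g, 1, 1 - invalid_rate) == 1
  cost[!cost_valid] <- NA_real_

  # Log-normal matched to median and IQR; 0.6745 is the standard-normal
  # upper quartile. Discretized to whole days, floored at 1.
  sdlog <- (log(q75) - log(q25)) / (2 * 0.6745)
  los <- pmax(1L, as.integer(round(rlnorm(n_g, log(med), sdlog))))
  readmit <- rbinom(n_g, 1, proc_row[[paste0("readmit", suffix)]]) == 1

  tibble(
    procedure = proc_row$procedure, age = age, gender = gender,
    elective = elective, cci = as.integer(cci),
    complication = group == "with", cost = cost, cost_valid = cost_valid,
    los = los, readmit_30d = readmit
  )
}

#' Generate a synthetic patient-level cohort
#'
#' Draws a cohort of surgical admissions with the group- and
#' procedure-level statistical structure of the specification: complication
#' flags are independent Bernoulli draws at the procedure morbidity; total
#' costs are gamma-distributed with the group mean and SD (moment-matched,
#' rounded to whole dollars); length of stay follows a log-normal matched to
#' the group median and IQR, discretized to whole days and floored at 1;
#' 30-day readmission and cost validity are Bernoulli at the group rates;
#' age is normal truncated at 18, gender/elective are Bernoulli and the
#' Charlson index Poisson at the group marginals. No dependence between
#' cost, LOS and readmission is induced beyond shared group membership, and
#' no hospital-level clustering is modeled.
#'
#' Generation is fully deterministic given `seed`: the seed feeds a master
#' stream from which one substream per procedure and one per procedure-group
#' pair are drawn (complication assignment, then each group's attributes).
#'
#' @param spec A [cohort_spec()]; defaults to the published parameterization.
#' @param scale Fraction in (0, 1] by which every procedure's `n` is shrunk
#'   (rounded, minimum 1 admission per procedure) for desk-scale runs.
#' @param seed Single integer seed.
#' @return A validated cohort tibble (see [read_cohort()] for the schema)
#'   with `sum(pmax(1, round(spec$procedures$n * scale)))` rows.
#' @export
#' @examples
#' small <- simulate_cohort(scale = 0.002, seed = 42)
#' dplyr::count(small, procedure, complication)
simulate_cohort <- function(spec = default_cohort_spec(), scale = 1,
                            seed = 1L) {
  if (!inherits(spec, "gdft_cohort_spec")) {
    abort("`spec` must be a gdft_cohort_spec (see cohort_spec()).")
  }
  check_number(scale, "scale", min = .Machine$double.eps, max = 1)
  check_number(seed, "seed", integer = TRUE)

  procs <- spec$procedures
  ns <- pmax(1L, as.integer(round(procs$n * scale)))
  seeds <- matrix(substream_seeds(seed, 3L * nrow(procs)), ncol = 3)
  demo <- spec$demographics
  demo_with <- demo[demo$group == "with", ]
  demo_without <- demo[demo$group == "without", ]

  pieces <- purrr::map(seq_len(nrow(procs)), function(i) {
    row <- procs[i, ]
    set.seed(seeds[i, 1])
    comp <- rbinom(ns[i], 1, row$morbidity) == 1
    set.seed(seeds[i, 2])
    g_with <- generate_group(sum(comp), row, demo_with,
                             spec$invalid_cost_rate[["with"]], "with")
    set.seed(seeds[i, 3])
    g_without <- generate_group(sum(!comp), row, demo_without,
                                spec$invalid_cost_rate[["without"]], "without")
    dplyr::bind_rows(g_with, g_without)
  })
  out <- dplyr::bind_rows(pieces)
  out <- dplyr::mutate(out,
                       patient_id = sprintf("P%07d", dplyr::row_number()),
                       .before = 1)
  validate_cohort(out, strict = TRUE)
}
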