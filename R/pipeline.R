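#' Pipeline run configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Every
#' default reproduces the reference analysis settings: the published effect
#' bounds (OR 0.71-0.83, count-scaling interpretation), a 2.5-year period,
#' the published monitoring cost model, a 3-day excess stay and a 5-day
#' average stay.
#'
#' @param input `"synthetic"` (generate a cohort from
#'   [default_cohort_spec()]), `"frame"` (aggregate mode: no patient-level
#'   data; uses `frame` or [reference_study_frame()] plus
#'   [procedure_parameters()]), or a path to a cohort CSV.
#' @param scale Cohort scale fraction for synthetic input.
#' @param seed Integer seed for synthetic input.
#' @param effect A [gdft_effect()].
#' @param impl_cost An [implementation_cost()].
#' @param period_years Study period length, years.
#' @param excess_los,avg_los Bed-day model inputs, days.
#' @param include_procedure Add procedure to the cost GLM covariates.
#' @param fit_glm Fit the adjusted cost model (cohort modes only).
#' @param frame Optional [study_frame()] for `input = "frame"`.
#' @param output_dir Directory for the report bundle (created on demand).
#' @return A validated list of class `gdft_config`.
#' @export
pipeline_config <- function(input = "synthetic", scale = 1, seed = 1L,
                            effect = gdft_effect(),
                            impl_cost = implementation_cost(),
                            period_years = 2.5, excess_los = 3, avg_los = 5,
                            include_procedure = FALSE, fit_glm = TRUE,
                            frame = NULL,
                            output_dir = tempfile("gdftroi-report-")) {
  if (!is.character(input) || length(input) != 1L) {
    abort("`input` must be \"synthetic\", \"frame\" or a file path.")
  }
  if (!input %in% c("synthetic", "frame") && !file.exists(input)) {
    abort(sprintf("`input` file not found: %s", input))
  }
  check_number(scale, "scale", min = .Machine$double.eps, max = 1)
  check_number(seed, "seed", integer = TRUE)
  check_effect(effect)
  if (!inherits(impl_cost, "gdft_impl_cost")) {
    abort("`impl_cost` must come from implementation_cost().")
  }
  check_number(period_years, "period_years", min = .Machine$double.eps)
  check_number(excess_los, "excess_los", min = .Machine$double.eps)
  check_number(avg_los, "avg_los", min = .Machine$double.eps)
  check_flag(include_procedure, "include_procedure")
  check_flag(fit_glm, "fit_glm")
  if (!is.null(frame)) check_frame(frame)
  structure(
    list(input = input, scale = scale, seed = as.integer(seed),
         effect = effect, impl_cost = impl_cost,
         period_years = period_years, excess_los = excess_los,
         avg_los = avg_los, include_procedure = include_procedure,
         fit_glm = fit_glm, frame = frame, output_dir = output_dir),
    class = "gdft_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar fields map directly to [pipeline_config()] arguments; the effect
#' and implementation-cost blocks use keys `or_low`/`or_high`/
#' `interpretation` and `sensor_cost`/`monitor_price`/`uses_per_week`/
#' `lifetime_years`/`weeks_per_year`; an optional `frame` block carries
#' `n_total`/`n_complications`/`cost_diff`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `gdft_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  eff <- do.call(gdft_effect, raw$effect %||% list())
  ic <- do.call(implementation_cost, raw$impl_cost %||% list())
  frame <- if (!is.null(raw$frame)) {
    do.call(study_frame, c(raw$frame,
                           list(period_years = raw$period_years %||% 2.5)))
  }
  args <- raw[intersect(names(raw),
                        c("input", "scale", "seed", "period_years",
                          "excess_los", "avg_los", "include_procedure",
                          "fit_glm", "output_dir"))]
  do.call(pipeline_config,
          c(args, list(effect = eff, impl_cost = ic, frame = frame)))
}

write_json_doc <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}

#' Run the full budget-impact pipeline
#'
#' End-to-end driver: obtain a cohort (synthetic, from CSV, or skip to
#' aggregate "frame" mode), summarize it, fit the adjusted cost model,
#' project morbidity and savings overall and per procedure, and compute the
#' ROI and bed-day reports. Writes a reproducible bundle to
#' `config$output_dir`:
#'
#' * `summary.csv` — group-by-procedure descriptives (cohort modes only)
#' * `projection.csv` — per-procedure savings plus an `all` row
#' * `adjusted_costs.json` — GLM coefficients, dispersion and LS-means
#'   (cohort modes with `fit_glm = TRUE`)
#' * `roi_bed_days.json` — implementation cost, savings-per-dollar, bed-days
#' * `manifest.json` — the configuration, seed and package version
#'
#' The same configuration always produces the same bundle.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the computed objects (`cohort`, `summary`,
#'   `frame`, `savings`, `per_procedure`, `glm`, `ls_means`, `roi`,
#'   `bed_days`) and `paths` of the written files.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "gdft_config")) {
    abort("`config` must come from pipeline_config().")
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  out <- list()

  if (config$input == "frame") {
    frame <- config$frame %||% reference_study_frame(config$period_years)
    proc_inputs <- procedure_parameters()
  } else {
    cohort <- if (config$input == "synthetic") {
      simulate_cohort(scale = config$scale, seed = config$seed)
    } else {
      read_cohort(config$input, strict = FALSE)
    }
    out$cohort <- cohort
    out$summary <- summarize_cohort(cohort, by_procedure = TRUE)
    paths$summary <- file.path(config$output_dir, "summary.csv")
    readr::write_csv(out$summary, paths$summary, na = "")
    frame <- frame_from_cohort(cohort, config$period_years)
    proc_inputs <- cohort_savings_inputs(cohort)
    if (config$fit_glm) {
      out$glm <- fit_cost_glm(cohort,
                              include_procedure = config$include_procedure)
      out$ls_means <- ls_means(out$glm)
      paths$glm <- file.path(config$output_dir, "adjusted_costs.json")
      write_json_doc(
        list(coefficients = as.list(out$glm$coefficients),
             terms = out$glm$terms,
             dispersion = out$glm$dispersion,
             deviance = out$glm$deviance,
             converged = out$glm$converged,
             n_iterations = out$glm$n_iterations,
             ls_means = as.list(out$ls_means)),
        paths$glm
      )
    }
  }

  out$frame <- frame
  out$savings <- project_savings(frame, config$effect)
  out$burden <- excess_cost_burden(frame)
  out$per_procedure <- per_procedure_savings(proc_inputs, config$effect,
                                             config$period_years)
  all_row <- tibble(
    procedure = "all",
    morbidity = morbidity_pct_1dp(frame$n_complications, frame$n_total),
    cost_diff = frame$cost_diff,
    n = frame$n_total,
    savings_per_patient_low = out$savings$savings_per_patient_low,
    savings_per_patient_high = out$savings$savings_per_patient_high,
    savings_per_year_low = out$savings$savings_per_year_low,
    savings_per_year_high = out$savings$savings_per_year_high
  )
  projection_tbl <- dplyr::bind_rows(all_row, out$per_procedure)
  paths$projection <- file.path(config$output_dir, "projection.csv")
  readr::write_csv(projection_tbl, paths$projection, na = "")

  icpp <- implementation_cost_per_patient(config$impl_cost)
  out$roi <- roi_ratio(out$savings$savings_per_patient_low,
                       out$savings$savings_per_patient_high,
                       icpp$total)
  out$bed_days <- project_bed_days(frame, config$effect,
                                   excess_los = config$excess_los,
                                   avg_los = config$avg_los)
  paths$roi <- file.path(config$output_dir, "roi_bed_days.json")
  write_json_doc(
    list(implementation_cost = as.list(icpp),
         roi = as.list(out$roi),
         bed_days = as.list(out$bed_days),
         burden = as.list(out$burden)),
    paths$roi
  )

  paths$manifest <- file.path(config$output_dir, "manifest.json")
  write_json_doc(
    list(
      input = config$input, scale = config$scale, seed = config$seed,
      effect = unclass(config$effect),
      implementation_cost = unclass(config$impl_cost),
      period_years = config$period_years, excess_los = config$excess_los,
      avg_los = config$avg_los,
      include_procedure = config$include_procedure,
      fit_glm = config$fit_glm,
      frame = if (!is.null(config$frame)) as.list(config$frame),
      package = "gdftroi",
      package_version = as.character(packageVersion("gdftroi"))
    ),
    paths$manifest
  )

  out$paths <- paths
  invisible(out)
}
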