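# Patient-level cohort schema: one row per surgical admission.
cohort_columns <- function() {
  c(patient_id = "character", procedure = "character", age = "numeric",
    gender = "character", elective = "logical", cci = "integer",
    complication = "logical", cost = "numeric", cost_valid = "logical",
    los = "integer", readmit_30d = "logical")
}

# Normalize a procedure label to the canonical string, or NA if unknown.
match_procedure <- function(x) {
  lv <- procedure_levels()
  idx <- match(tolower(trimws(x)), tolower(lv))
  lv[idx]
}

#' Validate a patient-level cohort
#'
#' Checks a data frame of surgical admissions against the cohort schema and
#' its invariants: known procedure label (matched case-insensitively, with
#' surrounding whitespace stripped), `gender` in \{female, male\}, adult age
#' (>= 18; the model covers adult surgery only), non-negative integer
#' Charlson Co-morbidity Index, length of stay >= 1 day, non-negative cost,
#' and the missing-cost convention: `cost` is present if and only if
#' `cost_valid` is `TRUE`.
#'
#' @param cohort A data frame with the columns listed in the Details of
#'   [read_cohort()].
#' @param strict If `TRUE` (default), any invalid row is an error that names
#'   the offending rows; if `FALSE`, invalid rows are dropped with a message
#'   giving the count.
#' @return A validated tibble with canonical procedure and gender labels and
#'   canonical column order.
#' @export
validate_cohort <- function(cohort, strict = TRUE) {
  check_flag(strict, "strict")
  cols <- cohort_columns()
  missing_cols <- setdiff(names(cols), names(cohort))
  if (length(missing_cols) > 0) {
    abort(sprintf("Cohort is missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  d <- as_tibble(cohort)[names(cols)]
  d$patient_id <- as.character(d$patient_id)
  d$procedure <- match_procedure(d$procedure)
  d$gender <- tolower(trimws(as.character(d$gender)))
  d$gender[!d$gender %in% c("female", "male")] <- NA_character_

  problems <- list(
    `unknown procedure label` = is.na(d$procedure),
    `unknown gender label` = is.na(d$gender),
    `age below 18 or missing` = !is.finite(d$age) | d$age < 18,
    `CCI not a non-negative integer` =
      is.na(d$cci) | d$cci < 0 | d$cci != trunc(d$cci),
    `LOS not an integer >= 1` =
      is.na(d$los) | d$los < 1 | d$los != trunc(d$los),
    `missing elective/complication/readmission flag` =
      is.na(d$elective) | is.na(d$complication) | is.na(d$readmit_30d),
    `cost present/missing inconsistent with cost_valid` =
      is.na(d$cost_valid) | (is.na(d$cost) == d$cost_valid),
    `negative cost` = !is.na(d$cost) & d$cost < 0
  )
  bad <- Reduce(`|`, problems)
  if (any(bad)) {
    if (strict) {
      msgs <- purrr::imap_chr(problems, function(p, label) {
        if (!any(p)) return(NA_character_)
        rows <- which(p)
        shown <- paste(utils::head(rows, 5), collapse = ", ")
        if (length(rows) > 5) shown <- paste0(shown, ", ...")
        sprintf("%s: row(s) %s", label, shown)
      })
      abort(c("Invalid cohort rows.", stats::na.omit(msgs)))
    }
    inform(sprintf("Dropped %d invalid cohort row(s).", sum(bad)))
    d <- d[!bad, ]
  }
  d$cci <- as.integer(d$cci)
  d$los <- as.integer(d$los)
  d
}

#' Read a patient-level cohort from CSV
#'
#' Reads a comma-separated, UTF-8 cohort file with a header row and one row
#' per surgical admission, then validates it with [validate_cohort()].
#' Required columns: `patient_id`, `procedure`, `age` (years), `gender`
#' (female/male), `elective`, `cci` (Charlson Co-morbidity Index),
#' `complication` (any in-hospital postoperative complication), `cost`
#' (total USD, index stay + 30-day readmission; empty cell when missing),
#' `cost_valid`, `los` (days), `readmit_30d`. Missing values are empty
#' cells; logical columns are written `TRUE`/`FALSE`.
#'
#' @param path Path to a CSV file.
#' @param strict Passed to [validate_cohort()]: error on invalid rows
#'   (default) or drop them with a message.
#' @return A validated cohort tibble.
#' @seealso [write_cohort()] for the inverse; the pair round-trips losslessly.
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  missing_cols <- setdiff(names(cohort_columns()), header)
  if (length(missing_cols) > 0) {
    abort(sprintf("Cohort file is missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  d <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      procedure = readr::col_character(),
      age = readr::col_double(),
      gender = readr::col_character(),
      elective = readr::col_logical(),
      cci = readr::col_integer(),
      complication = readr::col_logical(),
      cost = readr::col_double(),
      cost_valid = readr::col_logical(),
      los = readr::col_integer(),
      readmit_30d = readr::col_logical(),
      .default = readr::col_guess()
    ),
    na = c("", "NA"),
    show_col_types = FALSE
  )
  validate_cohort(d, strict = strict)
}

#' Write a patient-level cohort to CSV
#'
#' Writes the canonical comma-separated representation read by
#' [read_cohort()]: fixed column order, header row, missing costs as empty
#' cells, logicals as `TRUE`/`FALSE`. Writing the same cohort twice produces
#' byte-identical files.
#'
#' @param cohort A cohort data frame (validated before writing).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  d <- validate_cohort(cohort, strict = TRUE)
  readr::write_csv(d, path, na = "")
  invisible(path)
}
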