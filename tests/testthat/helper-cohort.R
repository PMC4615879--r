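# Hand-built cohorts for unit tests. All fields valid unless overridden.
make_cohort <- function(n, complication, cost = 10000, los = 5,
                        procedure = "colectomy", age = 60, gender = "female",
                        elective = TRUE, cci = 1L, readmit_30d = FALSE,
                        cost_valid = !is.na(cost), id_prefix = "T") {
  tibble::tibble(
    patient_id = paste0(id_prefix, seq_len(n)),
    procedure = rep_len(procedure, n),
    age = rep_len(age, n),
    gender = rep_len(gender, n),
    elective = rep_len(elective, n),
    cci = as.integer(rep_len(cci, n)),
    complication = rep_len(complication, n),
    cost = rep_len(cost, n),
    cost_valid = rep_len(cost_valid, n),
    los = as.integer(rep_len(los, n)),
    readmit_30d = rep_len(readmit_30d, n)
  )
}

# Two-group cohort with explicit per-record cost/los vectors.
two_group_cohort <- function(cost_with, cost_without,
                             los_with = 7L, los_without = 4L,
                             readmit_with = FALSE, readmit_without = FALSE,
                             ...) {
  dplyr::bind_rows(
    make_cohort(length(cost_with), TRUE, cost = cost_with,
                los = los_with, readmit_30d = readmit_with,
                id_prefix = "W", ...),
    make_cohort(length(cost_without), FALSE, cost = cost_without,
                los = los_without, readmit_30d = readmit_without,
                id_prefix = "N", ...)
  )
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of the
# choose(n, m) group assignments (no ties assumed). Independent oracle for
# the rank-sum comparisons.
exact_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  m <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(n, m)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  mu <- m * (n - m) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}
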