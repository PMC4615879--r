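group_label <- function(complication) {
  ifelse(complication, "with_complications", "without_complications")
}

summarize_one <- function(d, scope, n_scope, n_with_scope) {
  valid_cost <- d$cost[d$cost_valid & !is.na(d$cost)]
  tibble(
    scope = scope,
    n = nrow(d),
    n_cost_valid = length(valid_cost),
    morbidity_rate = if (n_scope > 0) 100 * n_with_scope / n_scope else NA_real_,
    cost_mean = if (length(valid_cost) >= 1) mean(valid_cost) else NA_real_,
    cost_sd = if (length(valid_cost) >= 2) sd(valid_cost) else NA_real_,
    los_median = if (nrow(d) > 0) median(d$los) else NA_real_,
    los_q25 = if (nrow(d) > 0) unname(quantile(d$los, 0.25, type = 7)) else NA_real_,
    los_q75 = if (nrow(d) > 0) unname(quantile(d$los, 0.75, type = 7)) else NA_real_,
    readmit_rate = if (nrow(d) > 0) 100 * mean(d$readmit_30d) else NA_real_
  )
}

summarize_scope <- function(d, scope) {
  n_scope <- nrow(d)
  n_with <- sum(d$complication)
  out <- purrr::map(c(TRUE, FALSE), function(g) {
    row <- summarize_one(d[d$complication == g, ], scope, n_scope, n_with)
    dplyr::mutate(row, group = group_label(g), .after = "scope")
  })
  dplyr::bind_rows(out)
}

#' Summarize a cohort by complication group
#'
#' Group-level descriptives in the layout of the reference analysis: one row
#' per complication group (and per procedure when requested) with patient
#' counts, the morbidity rate of the scope, cost mean and SD over records
#' with valid cost data only, length-of-stay median and quartiles (linear
#' interpolation between order statistics), and the 30-day readmission rate.
#' LOS and readmission use all records; cost statistics use the cost-valid
#' subset, mirroring the convention of the source tables.
#'
#' @param cohort A validated cohort tibble.
#' @param by_procedure Also produce per-procedure summaries in addition to
#'   the overall rows.
#' @return A tibble with columns `scope` (`"all"` or the procedure label),
#'   `group`, `n`, `n_cost_valid`, `morbidity_rate` (% of the scope with one
#'   or more complications), `cost_mean`, `cost_sd`, `los_median`,
#'   `los_q25`, `los_q75`, `readmit_rate` (%). Empty groups yield `n = 0`
#'   rows with missing statistics.
#' @export
summarize_cohort <- function(cohort, by_procedure = FALSE) {
  check_flag(by_procedure, "by_procedure")
  if (nrow(cohort) == 0) abort("Cohort is empty.")
  out <- summarize_scope(cohort, "all")
  if (by_procedure) {
    per <- purrr::map(intersect(procedure_levels(), unique(cohort$procedure)),
                      function(p) {
                        summarize_scope(cohort[cohort$procedure == p, ], p)
                      })
    out <- dplyr::bind_rows(out, dplyr::bind_rows(per))
  }
  out
}

split_groups <- function(cohort) {
  list(with = cohort[cohort$complication, ],
       without = cohort[!cohort$complication, ])
}

comparison_row <- function(quantity, test, statistic, p_value) {
  tibble(quantity = quantity, test = test,
         statistic = unname(statistic), p_value = unname(p_value))
}

#' Compare total costs between complication groups
#'
#' Two-sample t test on records with valid cost data; the unequal-variance
#' (Welch) form by default, since the group SDs of skewed hospital costs
#' typically differ severalfold, with the pooled-variance form behind a
#' flag.
#'
#' @param cohort A validated cohort tibble.
#' @param pooled Use the pooled-variance (classical) t test instead of Welch.
#' @return A one-row tibble: `quantity`, `test`, `statistic`, `p_value`.
#' @export
compare_costs <- function(cohort, pooled = FALSE) {
  check_flag(pooled, "pooled")
  g <- split_groups(cohort)
  costs <- purrr::map(g, ~ .x$cost[.x$cost_valid & !is.na(.x$cost)])
  if (any(lengths(costs) < 2)) {
    abort("Each complication group needs at least 2 records with valid cost data.")
  }
  ht <- t.test(costs$with, costs$without, var.equal = pooled)
  comparison_row("cost", if (pooled) "t_test" else "welch_t_test",
                 ht$statistic, ht$p.value)
}

#' Compare length of stay between complication groups
#'
#' Wilcoxon rank-sum test on hospital LOS. The default is the tie-corrected
#' normal approximation with continuity correction (the only option for the
#' heavily tied integer LOS of large cohorts); `method = "exact"` requests
#' the exact distribution, which is available for small, tie-free samples.
#'
#' @param cohort A validated cohort tibble.
#' @param method `"normal"` (default) or `"exact"`.
#' @return A one-row tibble: `quantity`, `test`, `statistic` (the rank-sum
#'   W), `p_value`. If every LOS value is identical across both groups the
#'   test is degenerate and `statistic = 0`, `p_value = 1` is returned.
#' @export
compare_los <- function(cohort, method = c("normal", "exact")) {
  method <- match.arg(method)
  g <- split_groups(cohort)
  if (any(purrr::map_int(g, nrow) == 0)) {
    abort("Each complication group needs at least 1 record.")
  }
  if (length(unique(cohort$los)) == 1) {
    return(comparison_row("los", "wilcoxon_rank_sum", 0, 1))
  }
  ht <- suppressWarnings(
    wilcox.test(g$with$los, g$without$los,
                exact = method == "exact", correct = TRUE)
  )
  comparison_row("los", "wilcoxon_rank_sum", ht$statistic, ht$p.value)
}

#' Compare 30-day readmission rates between complication groups
#'
#' Pearson chi-squared test on the 2x2 group-by-readmission table, without
#' continuity correction by default (immaterial at claims-database cell
#' sizes; available behind the flag).
#'
#' @param cohort A validated cohort tibble.
#' @param correct Apply Yates continuity correction.
#' @return A one-row tibble: `quantity`, `test`, `statistic`, `p_value`.
#' @export
compare_readmission <- function(cohort, correct = FALSE) {
  check_flag(correct, "correct")
  tab <- table(group = group_label(cohort$complication),
               readmitted = cohort$readmit_30d)
  if (!identical(dim(tab), c(2L, 2L)) ||
      any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("Degenerate 2x2 table: both groups and both readmission outcomes must be present.")
  }
  ht <- chisq.test(tab, correct = correct)
  comparison_row("readmission", "chi_squared", ht$statistic, ht$p.value)
}
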