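test_that("summaries conserve counts and compute group statistics", {
  co <- two_group_cohort(cost_with = c(20000, 30000, NA),
                         cost_without = c(8000, 10000, 12000, 14000, 16000),
                         los_with = c(6L, 8L, 10L), los_without = c(3L, 3L, 4L, 4L, 5L))
  co$cost_valid <- !is.na(co$cost)
  s <- summarize_cohort(co)
  expect_equal(sum(s$n), nrow(co))
  w <- s[s$group == "with_complications", ]
  expect_equal(w$n, 3L)
  expect_equal(w$n_cost_valid, 2L)
  expect_equal(w$morbidity_rate, 100 * 3 / 8)
  expect_equal(w$cost_mean, 25000)
  expect_equal(w$los_median, 8)
  wo <- s[s$group == "without_complications", ]
  expect_equal(wo$cost_mean, 12000)
  expect_equal(wo$los_q25, 3)
  expect_equal(wo$los_q75, 4)

  # per-procedure scopes also conserve counts
  mixed <- dplyr::bind_rows(
    co,
    make_cohort(4, c(TRUE, TRUE, FALSE, FALSE), procedure = "gastrectomy",
                id_prefix = "G")
  )
  sp <- summarize_cohort(mixed, by_procedure = TRUE)
  per_proc <- sp[sp$scope != "all", ]
  expect_equal(sum(per_proc$n), nrow(mixed))
})

test_that("degenerate groups are flagged rather than mis-summarized", {
  one_each <- two_group_cohort(cost_with = 20000, cost_without = 9000,
                               los_with = 6L, los_without = 3L)
  s <- summarize_cohort(one_each)
  expect_true(all(is.na(s$cost_sd)))
  expect_equal(s$los_median[s$group == "with_complications"], 6)

  only_with <- make_cohort(3, TRUE)
  s2 <- summarize_cohort(only_with)
  expect_equal(s2$n[s2$group == "without_complications"], 0L)
  expect_true(is.na(s2$cost_mean[s2$group == "without_complications"]))
  expect_error(summarize_cohort(one_each[0, ]), "empty")
})

test_that("cost comparison matches the closed-form Welch t statistic", {
  x <- c(20000, 26000, 31000, 24000, 28000, 35000)
  y <- c(9000, 12000, 15000, 11000)
  co <- two_group_cohort(cost_with = x, cost_without = y)
  res <- compare_costs(co)
  t_manual <- (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
  df_manual <- (var(x) / length(x) + var(y) / length(y))^2 /
    ((var(x) / length(x))^2 / (length(x) - 1) +
       (var(y) / length(y))^2 / (length(y) - 1))
  expect_equal(res$statistic, t_manual)
  expect_equal(res$p_value, 2 * stats::pt(-abs(t_manual), df_manual))

  # identical multisets: statistic 0, p = 1
  same <- two_group_cohort(cost_with = c(1000, 2000, 3000),
                           cost_without = c(3000, 1000, 2000))
  res0 <- compare_costs(same)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  # well-separated normal samples are overwhelmingly significant
  set.seed(1)
  co2 <- two_group_cohort(cost_with = 10000 + 5000 + rnorm(200, sd = 1000),
                          cost_without = 10000 + rnorm(200, sd = 1000))
  expect_lt(compare_costs(co2)$p_value, 1e-4)

  # too few valid costs is an explicit error
  few <- two_group_cohort(cost_with = c(20000, NA, NA), cost_without = c(1, 2))
  few$cost_valid <- !is.na(few$cost)
  expect_error(compare_costs(few), "at least 2")
})

test_that("cost comparison is invariant to record order", {
  co <- two_group_cohort(cost_with = c(20, 30, 40) * 1000,
                         cost_without = c(9, 11, 13, 15) * 1000)
  shuffled <- co[rev(seq_len(nrow(co))), ]
  expect_equal(compare_costs(co), compare_costs(shuffled))
})

test_that("LOS comparison agrees with exact enumeration on small samples", {
  # tie-free case: the exact method equals brute-force enumeration
  x <- c(2L, 5L, 9L)
  y <- c(1L, 3L, 4L, 7L)
  co <- two_group_cohort(cost_with = rep(1000, 3), cost_without = rep(1000, 4),
                         los_with = x, los_without = y)
  res_exact <- compare_los(co, method = "exact")
  expect_equal(res_exact$p_value, exact_rank_sum_p(x, y))
  # the default normal approximation is close on this instance
  res_norm <- compare_los(co)
  expect_lt(abs(res_norm$p_value - res_exact$p_value), 0.1)
})

test_that("separated LOS distributions give vanishing p-values", {
  co <- two_group_cohort(cost_with = rep(1000, 50), cost_without = rep(1000, 50),
                         los_with = 51:100, los_without = 1:50)
  res <- compare_los(co)
  expect_lt(res$p_value, 1e-4)
  expect_equal(res$statistic, 50 * 50)  # complete separation: W = n1*n2
})

test_that("fully tied LOS yields the degenerate result", {
  co <- two_group_cohort(cost_with = rep(1000, 5), cost_without = rep(1000, 5),
                         los_with = 4L, los_without = 4L)
  res <- compare_los(co)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("readmission comparison matches the Pearson chi-squared formula", {
  tab <- matrix(c(13212, 63595, 15217, 112656), nrow = 2, byrow = TRUE)
  co <- dplyr::bind_rows(
    make_cohort(tab[1, 1], TRUE, readmit_30d = TRUE, id_prefix = "a"),
    make_cohort(tab[1, 2], TRUE, readmit_30d = FALSE, id_prefix = "b"),
    make_cohort(tab[2, 1], FALSE, readmit_30d = TRUE, id_prefix = "c"),
    make_cohort(tab[2, 2], FALSE, readmit_30d = FALSE, id_prefix = "d")
  )
  res <- compare_readmission(co)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - expected)^2 / expected)
  expect_equal(res$statistic, x2, tolerance = 1e-10)
  expect_equal(res$p_value, stats::pchisq(x2, df = 1, lower.tail = FALSE))
  expect_lt(res$p_value, 1e-3)

  # balanced table: statistic 0, p = 1
  bal <- dplyr::bind_rows(
    make_cohort(10, TRUE, readmit_30d = c(rep(TRUE, 5), rep(FALSE, 5))),
    make_cohort(10, FALSE, readmit_30d = c(rep(TRUE, 5), rep(FALSE, 5)),
                id_prefix = "x")
  )
  res0 <- compare_readmission(bal)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  # swapping group labels leaves the statistic unchanged
  flipped <- dplyr::mutate(co, complication = !complication)
  expect_equal(compare_readmission(flipped)$statistic, res$statistic)

  # zero margin is an explicit error
  nolab <- make_cohort(6, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                       readmit_30d = FALSE)
  expect_error(compare_readmission(nolab), "egenerate")
})
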