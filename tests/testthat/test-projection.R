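ref_frame <- reference_study_frame()
ref_effect <- gdft_effect()

test_that("morbidity projection reproduces the published arithmetic", {
  proj <- project_morbidity(ref_frame, ref_effect)
  expect_equal(proj$projected_n, c(54533, 63750))
  expect_equal(proj$projected_rate, c(26.6, 31.1))
  expect_equal(proj$averted, c(22274, 13057))

  # OR = 1 is the identity
  id <- project_morbidity(ref_frame, gdft_effect(1, 1))
  expect_equal(id$projected_n, rep(76807, 2))
  expect_equal(id$averted, rep(0, 2))
})

test_that("the odds transform maps the baseline through the odds scale", {
  frame <- study_frame(200000, 75000, 11824)  # p = 0.375
  eff <- gdft_effect(0.71, 0.71, interpretation = "odds_transform")
  proj <- project_morbidity(frame, eff)
  p_expected <- 0.71 * 0.375 / (1 - 0.375 + 0.71 * 0.375)
  expect_equal(round(p_expected, 4), 0.2987)
  expect_equal(proj$projected_n[1], round(200000 * p_expected))
  # the odds transform always projects a weaker reduction than count scaling
  cs <- project_morbidity(frame, gdft_effect(0.71, 0.71))
  expect_gt(proj$projected_n[1], cs$projected_n[1])
})

test_that("count scaling and the odds transform agree at small baselines", {
  for (or in seq(0.71, 1, by = 0.02)) {
    frame <- study_frame(1e6, 1e4, 5000)  # p = 0.01
    cs <- project_morbidity(frame, gdft_effect(or, or))
    ot <- project_morbidity(frame, gdft_effect(or, or, "odds_transform"))
    rel <- abs(cs$projected_rate[1] - ot$projected_rate[1]) /
      max(cs$projected_rate[1], 1e-9)
    expect_lt(rel, 0.01)
  }
})

test_that("savings projection reproduces the published per-patient range", {
  s <- project_savings(ref_frame, ref_effect)
  expect_equal(s$n_projected_low, 54533)
  expect_equal(s$n_projected_high, 63750)
  expect_equal(s$savings_per_patient_low, 754)
  expect_equal(s$savings_per_patient_high, 1286)
  expect_equal(s$savings_total_high, 22274 * 11824)
  expect_equal(s$savings_per_year_high, 22274 * 11824 / 2.5)

  # null effect: all savings zero
  s0 <- project_savings(ref_frame, gdft_effect(1, 1))
  expect_equal(s0$savings_total_low, 0)
  expect_equal(s0$savings_per_patient_high, 0)

  # single-patient frame: the averted count rounds to zero
  s1 <- project_savings(study_frame(1, 1, 100), gdft_effect(0.71, 0.71))
  expect_equal(s1$savings_total_low, 0)
})

test_that("savings are monotone in effect strength, cost and morbidity", {
  base <- project_savings(study_frame(10000, 4000, 8000), gdft_effect(0.8, 0.8))
  stronger <- project_savings(study_frame(10000, 4000, 8000), gdft_effect(0.7, 0.7))
  costlier <- project_savings(study_frame(10000, 4000, 9000), gdft_effect(0.8, 0.8))
  sicker <- project_savings(study_frame(10000, 4500, 8000), gdft_effect(0.8, 0.8))
  expect_gte(stronger$savings_total_low, base$savings_total_low)
  expect_gte(costlier$savings_total_low, base$savings_total_low)
  expect_gte(sicker$savings_total_low, base$savings_total_low)
  expect_gte(stronger$savings_per_patient_low, base$savings_per_patient_low)

  # and across a grid, low <= high throughout
  for (or_low in c(0.5, 0.71, 0.9)) {
    s <- project_savings(study_frame(50000, 20000, 12000),
                         gdft_effect(or_low, 0.95))
    expect_lte(s$savings_total_low, s$savings_total_high)
    expect_lte(s$savings_per_patient_low, s$savings_per_patient_high)
    expect_lte(s$morbidity_projected_low, s$morbidity_projected_high)
  }
})

test_that("per-patient and total savings are mutually consistent", {
  set.seed(42)
  for (i in 1:25) {
    n_total <- sample(1000:300000, 1)
    frame <- study_frame(n_total, sample.int(n_total, 1),
                         stats::runif(1, 1000, 40000))
    s <- project_savings(frame, ref_effect)
    for (bound in c("low", "high")) {
      pp <- s[[paste0("savings_per_patient_", bound)]]
      tot <- s[[paste0("savings_total_", bound)]]
      red <- if (bound == "low") 0.17 else 0.29
      # one dollar of rounding per patient, plus the effect of reporting
      # morbidity to one decimal percent, plus count rounding
      slack <- n_total * (1 + 0.0005 * frame$cost_diff) + frame$cost_diff
      expect_lt(abs(pp * n_total - tot), slack)
    }
  }
})

test_that("excess burden is the complication count times the excess cost", {
  b <- excess_cost_burden(ref_frame)
  expect_equal(b$total, 76807 * 11824)
  expect_gt(b$total, 908e6)
  expect_equal(b$per_year, b$total / 2.5)
  expect_equal(round(b$per_year / 1e6), 363)
  b0 <- excess_cost_burden(study_frame(100, 0, 5000))
  expect_equal(b0$total, 0)
})

test_that("per-procedure savings reproduce all published ranges exactly", {
  pp <- per_procedure_savings(procedure_parameters(), ref_effect)
  published <- tibble::tribble(
    ~procedure, ~lo, ~hi,
    "AAA open repair", 2580, 4401,
    "vascular bypass", 676, 1154,
    "esophagectomy", 3515, 5996,
    "gastrectomy", 520, 888,
    "colectomy", 964, 1644,
    "resection of rectum", 625, 1066,
    "hepatectomy", 994, 1695,
    "pancreatectomy", 1863, 3178,
    "cystectomy", 1517, 2588,
    "femur & hip fracture repair", 354, 604
  )
  merged <- dplyr::left_join(published, pp, by = "procedure")
  expect_equal(merged$savings_per_patient_low, merged$lo)
  expect_equal(merged$savings_per_patient_high, merged$hi)

  # zero morbidity produces zero savings
  zero <- per_procedure_savings(
    tibble::tibble(procedure = "x", morbidity = 0, cost_diff = 10000, n = 100),
    ref_effect)
  expect_equal(zero$savings_per_patient_high, 0)
  expect_equal(zero$savings_per_year_high, 0)
})

test_that("cohort-derived inputs and frames feed the projection", {
  co <- dplyr::bind_rows(
    two_group_cohort(cost_with = c(20, 30) * 1000, cost_without = c(8, 12) * 1000),
    two_group_cohort(cost_with = c(50, 60) * 1000,
                     cost_without = c(20, 30, 40) * 1000,
                     procedure = "esophagectomy")
  )
  co$patient_id <- as.character(seq_len(nrow(co)))
  inputs <- cohort_savings_inputs(co)
  expect_equal(inputs$cost_diff[inputs$procedure == "colectomy"], 15000)
  expect_equal(inputs$morbidity[inputs$procedure == "colectomy"], 0.5)
  frame <- frame_from_cohort(co, 2)
  expect_equal(frame$n_total, nrow(co))
  expect_equal(frame$n_complications, sum(co$complication))
})

test_that("frame and effect constructors validate their inputs", {
  expect_error(study_frame(0, 0, 100), "n_total")
  expect_error(study_frame(100, 200, 100), "n_complications")
  expect_error(study_frame(100, 50, -1), "cost_diff")
  expect_error(gdft_effect(0.9, 0.8), "or_high")
  expect_error(gdft_effect(0, 0.8), "or_low")
  expect_error(project_morbidity(ref_frame, list(or_low = 0.7)), "gdft_effect")
})
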