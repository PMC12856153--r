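# Synthetic cohort generator: determinism, validation, survival law,
# calibration against the published baseline profile.

test_that("identical (spec, seed) regenerates a byte-identical cohort", {
  s <- cohort_spec(5, seed = 1)
  a <- generate_cohort(s)
  b <- generate_cohort(s)
  expect_identical(a$participants, b$participants)
  expect_identical(a$diagnoses, b$diagnoses)
})

test_that("enlarging the cohort appends without reshuffling raw records", {
  small <- generate_cohort(cohort_spec(50, seed = 9))$participants
  large <- generate_cohort(cohort_spec(80, seed = 9))$participants
  raw_cols <- c("age_years", "sex", "townsend", "smoking_status",
                "quit_years", "bmi_kg_m2", "sbp_mmHg", "dbp_mmHg",
                "met_min_week", "sleep_hours", paste0("diet", 1:9),
                "non_hdl_mmol_L", "hba1c_mmol_mol", "on_antihypertensive",
                "on_lipid_lowering", "com_mi")
  expect_identical(small[raw_cols], large[1:50, raw_cols])
})

test_that("invalid specifications name the offending field", {
  expect_error(cohort_spec(0, seed = 1), "n_participants")
  expect_error(cohort_spec(10, seed = 1, horizon_years = -1), "horizon_years")
  expect_error(cohort_spec(10, seed = 1, baseline_hazard_death = 0),
               "baseline_hazard_death")
  expect_error(cohort_spec(10, seed = 1, censoring_rate = -0.1),
               "censoring_rate")
  expect_error(
    cohort_spec(10, seed = 1,
                target_profile = list(bmi_mean = c(1, 2))),
    "bmi_mean"
  )
  expect_error(generate_cohort(list()), "cohort_spec")
})

test_that("participant records satisfy their structural invariants", {
  tc <- tiny_cohort()
  p <- tc$cohort$participants
  expect_true(all(p$met_min_week >= 0))
  expect_true(all(p$sleep_hours > 0 & p$sleep_hours < 24))
  expect_true(all(!is.na(p$censor_day)))
  expect_true(all(is.na(p$death_day) | p$death_day <= p$censor_day))
  expect_true(all(p$censor_day <= 10 * 365.25 + 1))
  expect_true(all(p$quit_years[p$smoking_status == "former"] >= 0))
  expect_true(all(is.na(p$quit_years[p$smoking_status != "former"])))
  d <- tc$cohort$diagnoses
  expect_true(all(d$day <= p$censor_day[match(d$id, p$id)]))
  # every participant carries the AF inclusion code at or before baseline
  af <- d[d$icd10 == "I48", ]
  expect_setequal(af$id, p$id)
  expect_true(all(af$day <= 0))
})

test_that("survival simulation follows the proportional-hazards law", {
  set.seed(77)
  # exponential mean: no censoring, long horizon
  s <- simulate_survival(rep(0, 200000), baseline_rate = 0.2,
                         censoring_rate = 0, horizon_years = 1e6)
  expect_true(all(s$status == "event"))
  expect_equal(mean(s$time_years), 5, tolerance = 0.02)

  # closed-form event fraction under competing exponential censoring
  s2 <- simulate_survival(rep(0, 100000), baseline_rate = 0.05,
                          censoring_rate = 0.02, horizon_years = 10)
  expected <- 0.05 / 0.07 * (1 - exp(-0.7))
  expect_equal(mean(s2$status == "event"), expected, tolerance = 0.005)

  # log(2) in the linear predictor doubles the event rate
  s_ref <- simulate_survival(rep(0, 50000), 0.05, 0, 5)
  s_dbl <- simulate_survival(rep(log(2), 50000), 0.05, 0, 5)
  rate_ref <- sum(s_ref$status == "event") / sum(s_ref$time_years)
  rate_dbl <- sum(s_dbl$status == "event") / sum(s_dbl$time_years)
  expect_equal(rate_dbl / rate_ref, 2, tolerance = 0.05)

  expect_error(simulate_survival(Inf, 0.1, 0.1, 10), "finite")
  expect_error(simulate_survival(0, -1, 0.1, 10), "baseline_rate")
})

test_that("default cohort reproduces the target baseline profile at n = 20,000", {
  co <- generate_cohort(cohort_spec(20000, seed = 2024))
  p <- co$participants
  sc <- score_cohort(p)
  expect_equal(mean(p$age_years), 61.82, tolerance = 0.5 / 61.82)
  expect_lt(abs(mean(p$age_years) - 61.82), 0.5)
  expect_lt(abs(sd(p$age_years) - 6.1), 0.5)
  expect_lt(abs(mean(p$sex == "female") - 0.33), 0.04)

  tp <- default_target_profile()
  for (v in list(c("bmi_kg_m2", "bmi_mean"), c("sbp_mmHg", "sbp_mean"),
                 c("met_min_week", "met_mean"))) {
    obs <- tapply(p[[v[1]]], sc$quartile, mean)
    rel <- abs(obs - tp[[v[2]]]) / tp[[v[2]]]
    expect_true(all(rel < 0.05), info = v[1])
  }
})

test_that("null LE8 effect yields log-rank tests at their nominal level", {
  pvals <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_spec(
      800, seed = 1000 + s,
      effect_log_hr_per_le8_point_death = 0,
      effect_log_hr_per_le8_point_mace = 0
    ))
    sc <- score_cohort(co$participants)
    rec <- derive_survival(co$participants, co$diagnoses,
                           mortality_endpoint())
    top_bot <- sc$quartile %in% c("Q1", "Q4")
    d <- data.frame(time = rec$time_years[top_bot],
                    ev = as.integer(rec$status[top_bot] == "event"),
                    g = droplevels(sc$quartile[top_bot]))
    survival::survdiff(survival::Surv(time, ev) ~ g, data = d)$pvalue
  }, numeric(1))
  # p-values should look uniform: no mass collapse at the low end
  expect_lte(sum(pvals < 0.05), 4)
  expect_gt(mean(pvals), 0.2)
})
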