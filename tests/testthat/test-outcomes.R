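# Endpoint classification, survival derivation, rates, KM, landmark.

test_that("ICD-10 classification honours ranges, enumerations and decimals", {
  mace <- mace_endpoint()
  expect_true(classify_icd10("I21.0", mace))
  expect_true(classify_icd10("I25.9", mace))   # decimal child of I20-I25
  expect_true(classify_icd10("I63", mace))
  expect_true(classify_icd10("I63.4", mace))   # child of enumerated root
  expect_true(classify_icd10("I50.1", mace))
  expect_false(classify_icd10("I50.2", mace))  # only .0/.1/.9 qualify
  expect_false(classify_icd10("I48", mace))
  expect_false(classify_icd10("J18.9", mace))
  expect_true(classify_icd10("I48", af_endpoint()))
  expect_true(classify_icd10("I48.1", af_endpoint()))
  expect_error(classify_icd10("1I48", mace), "malformed")
  expect_error(classify_icd10("I4", mace), "malformed")
})

make_participants <- function() {
  data.frame(
    id = 1:3,
    death_day = c(400L, 400L, NA),
    censor_day = c(400L, 400L, 4000L)
  )
}

test_that("survival derivation takes first qualifying event vs death vs censor", {
  parts <- make_participants()
  diags <- data.frame(
    id = c(2L, 2L, 3L, 1L),
    icd10 = c("I21.0", "I50.9", "J18.9", "I25.1"),
    day = c(200L, 300L, 100L, -30L)  # participant 1's MACE code is prevalent
  )
  mort <- derive_survival(parts, diags, mortality_endpoint())
  expect_equal(mort$time_years, c(400, 400, 3652.5) / 365.25)
  expect_equal(as.character(mort$status), c("event", "event", "censored"))
  expect_equal(mort$time_years[3], 10)

  mace <- derive_survival(parts, diags, mace_endpoint())
  expect_equal(round(mace$time_years, 3), c(1.095, 0.548, 10))
  expect_equal(as.character(mace$status),
               c("competing_death", "event", "censored"))
  expect_equal(attr(mace, "n_prevalent_ignored"), 1L)
})

test_that("inconsistent dates are rejected", {
  parts <- data.frame(id = 1L, death_day = 500L, censor_day = 400L)
  expect_error(derive_survival(parts, NULL, mortality_endpoint()),
               "death_day after censor_day")
  parts2 <- data.frame(id = 1L, death_day = NA, censor_day = NA)
  expect_error(derive_survival(parts2, NULL, mortality_endpoint()),
               "censor_day")
})

test_that("rate engine reproduces published-style rates and intervals", {
  rec <- data.frame(
    time_years = c(2, 3, 5),
    status = factor(c("event", "event", "censored"),
                    levels = c("censored", "event", "competing_death"))
  )
  rt <- rate_table(rec, groups = rep("all", 3))
  expect_equal(rt$events, 2L)
  expect_equal(rt$person_years, 10)
  expect_equal(rt$rate_per_1000, 200)
  expect_equal(rt$ci_low, 200 * exp(-1.959964 / sqrt(2)), tolerance = 1e-6)
  expect_true(rt$ci_low <= rt$rate_per_1000 &
                rt$rate_per_1000 <= rt$ci_high)

  rec0 <- data.frame(
    time_years = rep(10, 10),
    status = factor(rep("censored", 10),
                    levels = c("censored", "event", "competing_death"))
  )
  expect_warning(rt0 <- rate_table(rec0, rep("g", 10)), "zero events")
  expect_equal(c(rt0$rate_per_1000, rt0$ci_low, rt0$ci_high), c(0, 0, 0))
})

test_that("rounding is half-up as in the published tables", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.5, -0.5)), c(1, 2, 3, -1))
  expect_equal(round_half_up(46.189), 46)
  expect_equal(round_half_up(48.526), 49)
})

test_that("Kaplan-Meier estimate matches hand and brute-force computation", {
  rec <- data.frame(
    time_years = c(1, 1.5, 2, 3),
    status = factor(c("event", "censored", "event", "censored"),
                    levels = c("censored", "event", "competing_death"))
  )
  km <- km_curve(rec)
  expect_equal(km$survival[km$time == 0], 1)
  expect_equal(km$survival[km$time == 1], 0.75)
  expect_equal(km$survival[km$time == 2], 0.375)

  flat <- km_curve(data.frame(
    time_years = 1:5,
    status = factor(rep("censored", 5),
                    levels = c("censored", "event", "competing_death"))
  ))
  expect_true(all(flat$survival == 1))

  for (s in 1:200) {
    set.seed(s)
    n <- sample(3:40, 1)
    time <- round(rexp(n, 0.3), 2) + 0.01
    ev <- rbinom(n, 1, 0.7)
    rec <- data.frame(
      time_years = time,
      status = factor(ifelse(ev == 1, "event", "censored"),
                      levels = c("censored", "event", "competing_death"))
    )
    km <- km_curve(rec)
    orc <- oracle_km(time, ev)
    got <- km$survival[match(orc$time, km$time)]
    expect_equal(got, orc$surv, tolerance = 1e-12)
    expect_true(all(diff(km$survival) <= 1e-12))
  }
})

test_that("person-years are conserved under any partition", {
  tc <- tiny_cohort()
  rec <- derive_survival(tc$cohort$participants, tc$cohort$diagnoses,
                         mortality_endpoint())
  rt <- rate_table(rec, tc$scored$quartile)
  expect_equal(sum(rt$person_years), sum(rec$time_years))
  expect_equal(sum(rt$events), sum(rec$status == "event"))
})

test_that("landmark filter drops early records and sets delayed entry", {
  rec <- data.frame(
    id = 1:4,
    time_years = c(1.0, 2.5, 3.0, 1.9),
    status = factor(c("event", "event", "censored", "censored"),
                    levels = c("censored", "event", "competing_death"))
  )
  out <- landmark_filter(rec, 2)
  expect_equal(out$id, c(2L, 3L))
  expect_equal(as.character(out$status), c("event", "censored"))
  expect_true(all(out$entry_years == 2))

  late <- rec[rec$time_years > 2, ]
  expect_equal(nrow(landmark_filter(late, 2)), nrow(late))
  expect_error(landmark_filter(rec, 10), "strictly between")
  expect_error(landmark_filter(rec, 0), "strictly between")
})
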