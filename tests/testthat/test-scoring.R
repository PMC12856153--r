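# LE8 component scoring, composite, and quartile assignment.

test_that("categorical and boundary examples score per the rubric", {
  expect_equal(score_smoking("never"), 100)
  expect_equal(score_smoking("current"), 0)
  expect_equal(score_smoking("former", quit_years = 6), 75)
  expect_equal(score_smoking("former", quit_years = 2), 50)
  expect_equal(score_smoking("former", quit_years = 0.5), 25)
  expect_error(score_smoking("former"), "quit_years")

  expect_equal(score_bmi(24), 100)
  expect_equal(score_bmi(41), 0)
  expect_equal(score_blood_pressure(115, 75, treated = FALSE), 100)
  expect_equal(score_blood_pressure(115, 75, treated = TRUE), 80)
  expect_equal(score_blood_pressure(125, 75), 75)
  expect_equal(score_blood_pressure(125, 85), 50)
  expect_equal(score_physical_activity(0), 0)
  expect_equal(score_physical_activity(600), 100)
  expect_equal(score_sleep(7.5), 100)
  expect_equal(score_sleep(10.5), 40)
  expect_equal(score_non_hdl(3.0), 100)
  expect_equal(score_non_hdl(3.0, treated = TRUE), 80)
  expect_equal(score_non_hdl(6.0, treated = TRUE), 0)
  expect_equal(score_hba1c(35), 100)
  expect_equal(score_hba1c(42), 60)
  expect_equal(score_hba1c(50, diabetic = TRUE), 40)
  expect_equal(score_hba1c(50, diabetic = FALSE), 40) # diabetic-range HbA1c
  expect_equal(score_hba1c(90, diabetic = TRUE), 0)
})

test_that("out-of-range inputs raise errors naming the variable", {
  expect_error(score_bmi(5), "bmi")
  expect_error(score_bmi(NA_real_), "bmi")
  expect_error(score_blood_pressure(300, 80), "sbp")
  expect_error(score_sleep(25), "hours")
  expect_error(score_physical_activity(-1), "met_min_week")
  expect_error(score_smoking("sometimes"), "never/former/current")
})

test_that("scorers agree with an independent band-table oracle on a grid", {
  set.seed(101)
  n <- 10000
  bmi <- runif(n, 10, 80)
  met <- runif(n, 0, 2000)
  slp <- runif(n, 0.5, 23.5)
  chol <- runif(n, 0.5, 9)
  a1c <- runif(n, 20, 120)
  sbp <- runif(n, 60, 260)
  dbp <- runif(n, 30, 159)
  trt <- runif(n) < 0.5
  dia <- runif(n) < 0.3
  expect_equal(score_bmi(bmi),
               vapply(bmi, oracle_score, numeric(1), component = "bmi"))
  expect_equal(score_physical_activity(met),
               vapply(met, oracle_score, numeric(1), component = "activity"))
  expect_equal(score_sleep(slp),
               vapply(slp, oracle_score, numeric(1), component = "sleep"))
  expect_equal(score_non_hdl(chol, trt),
               mapply(function(x, t) oracle_score("non_hdl", x, treated = t),
                      chol, trt))
  expect_equal(score_hba1c(a1c, dia),
               mapply(function(x, d) oracle_score("hba1c", x, diabetic = d),
                      a1c, dia))
  expect_equal(score_blood_pressure(sbp, dbp, trt),
               mapply(oracle_bp, sbp, dbp, trt))
})

test_that("every scorer is monotone in the health-protective direction", {
  grids <- list(
    list(f = score_bmi, x = seq(15, 60, by = 0.5), protective = "low"),
    list(f = score_physical_activity, x = seq(0, 1200, by = 5),
         protective = "high"),
    list(f = function(x) score_non_hdl(x), x = seq(1, 8, by = 0.05),
         protective = "low"),
    list(f = function(x) score_hba1c(x, diabetic = TRUE),
         x = seq(20, 150, by = 1), protective = "low"),
    list(f = function(x) score_blood_pressure(x, 70), x = seq(90, 220, 1),
         protective = "low")
  )
  for (g in grids) {
    pts <- g$f(g$x)
    d <- diff(pts)
    if (g$protective == "high") expect_true(all(d >= 0)) else
      expect_true(all(d <= 0))
  }
  expect_true(score_smoking("never") >=
                score_smoking("former", quit_years = 10))
  expect_true(score_smoking("former", quit_years = 0.2) >
                score_smoking("current"))
  # former-smoker score never decreases with more quit years
  q <- score_smoking(rep("former", 61), quit_years = seq(0, 30, 0.5))
  expect_true(all(diff(q) >= 0))
})

test_that("composite is the mean of eight domains, order-invariant, bounded", {
  full <- c(diet = 100, physical_activity = 100, smoking = 100, sleep = 100,
            bmi = 100, non_hdl = 100, hba1c = 100, blood_pressure = 100)
  expect_equal(composite_le8(full), 100)
  mixed <- c(diet = 80, physical_activity = 80, smoking = 80, sleep = 80,
             bmi = 60, non_hdl = 60, hba1c = 60, blood_pressure = 60)
  expect_equal(composite_le8(mixed), 70)
  set.seed(3)
  perm <- sample(names(mixed))
  expect_equal(composite_le8(mixed[perm]), composite_le8(mixed))
  expect_error(composite_le8(mixed[-1]), "diet")
  expect_error(composite_le8(c(mixed, extra = 1)), "unknown")
  expect_error(composite_le8(replace(mixed, 1, 120)), "component points")
})

test_that("adapted diet score maps cohort quartiles of items met to points", {
  dist <- 1:8
  one <- function(k) {
    items <- c(rep(1, k), rep(0, 9 - k))
    score_diet(items, cohort_distribution = dist)
  }
  expect_equal(one(5)$quartile, 3)
  expect_equal(one(5)$points, 200 / 3)
  expect_equal(one(9)$quartile, 4)
  expect_equal(one(9)$points, 100)
  expect_equal(one(0)$quartile, 1)
  expect_equal(one(0)$points, 0)
  # nine items met land in the top quartile even in a top-heavy cohort
  expect_equal(score_diet(rep(1, 9),
                          cohort_distribution = rep(c(8, 9), 50))$points, 100)
  expect_error(score_diet(c(rep(1, 8), NA)), "missing")
  expect_error(score_diet(rep(1, 8)), "nine")
  # degenerate zero-spread cohort falls back to absolute bands
  expect_warning(fb <- score_diet(c(rep(1, 4), rep(0, 5)),
                                  cohort_distribution = rep(5, 30)),
                 "spread")
  expect_equal(fb$quartile, 2)
})

test_that("quartile assignment cuts at sample quartiles, ties to the lower group", {
  q <- assign_quartiles(1:8)
  expect_equal(as.character(q),
               c("Q1", "Q1", "Q2", "Q2", "Q3", "Q3", "Q4", "Q4"))
  q10 <- assign_quartiles(10:1)
  expect_equal(as.vector(table(q10)), c(3, 3, 2, 2))
  expect_equal(as.character(q10[10]), "Q1")
  expect_warning(qc <- assign_quartiles(rep(5, 8)), "identical")
  expect_true(all(qc == "Q1"))
  expect_error(assign_quartiles(1:3), "at least 4")
  # boundary ties fall into the lower quartile
  qt <- assign_quartiles(c(1, 2, 2, 2, 5, 6, 7, 8))
  expect_equal(sum(qt == "Q1"), 4)
})

test_that("cohort scoring returns bounded components and a full composite", {
  tc <- tiny_cohort()
  sc <- tc$scored
  comp_cols <- c("diet", "physical_activity", "smoking", "sleep", "bmi",
                 "non_hdl", "hba1c", "blood_pressure")
  for (cl in comp_cols) {
    expect_true(all(sc[[cl]] >= 0 & sc[[cl]] <= 100), info = cl)
  }
  expect_equal(sc$composite, rowMeans(sc[comp_cols]))
  expect_equal(nrow(sc), nrow(tc$cohort$participants))
})
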