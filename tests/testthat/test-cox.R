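# Cox models: partial-likelihood optimum vs grid-search oracle, spline
# behaviour, diagnostics, moderation, competing risks.

surv_df <- function(time, event, x) {
  data.frame(
    time_years = time,
    status = factor(ifelse(event == 1, "event", "censored"),
                    levels = c("censored", "event", "competing_death")),
    le8 = x
  )
}

test_that("Newton solution matches the closed-form four-row example", {
  d <- surv_df(1:4, rep(1, 4), c(1, 0, 1, 0))
  fit <- fit_cox(d, exposure_form = "linear")
  # score equation reduces to u^2 - u - 4 = 0 with u = exp(beta)
  beta_closed <- log((1 + sqrt(17)) / 2)
  expect_equal(unname(fit$tidy$coef), beta_closed, tolerance = 1e-6)
  expect_equal(round(beta_closed, 4), 0.9406)
  expect_equal(oracle_cox_grid(1:4, rep(1, 4), c(1, 0, 1, 0)), beta_closed,
               tolerance = 1e-4)
})

test_that("partial-likelihood optimum matches dense grid search on small data", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(3:8, 1)
    d <- rand_surv_data(n, beta = runif(1, -1, 1), seed = s)
    if (sum(d$status == "event") < 2) next
    names(d)[3] <- "le8"
    fit <- tryCatch(fit_cox(d, exposure_form = "linear"),
                    error = function(e) NULL)
    if (is.null(fit) || abs(fit$tidy$coef) > 3.5) next # unstable tiny set
    b_grid <- oracle_cox_grid(d$time_years, as.integer(d$status == "event"),
                              d$le8)
    expect_lt(abs(unname(fit$tidy$coef) - b_grid), 1e-4)
  }
})

test_that("degenerate designs are rejected, null effects estimate near 1", {
  d <- surv_df(1:6, rep(1, 6), rep(2, 6))
  expect_error(fit_cox(d, exposure_form = "linear"), "design error")

  set.seed(5)
  dn <- rand_surv_data(4000, beta = 0, seed = 5)
  names(dn)[3] <- "le8"
  fit <- fit_cox(dn, exposure_form = "linear")
  expect_lt(abs(fit$tidy$hr - 1), 3 * fit$tidy$se + 0.05)
  expect_true(fit$converged)
})

test_that("Efron and Breslow agree when all event times are distinct", {
  d <- rand_surv_data(60, beta = 0.4, seed = 11)
  names(d)[3] <- "le8"
  fe <- fit_cox(d, exposure_form = "linear", ties = "efron")
  fb <- fit_cox(d, exposure_form = "linear", ties = "breslow")
  expect_equal(fe$tidy$coef, fb$tidy$coef, tolerance = 1e-10)
})

test_that("penalised spline hits 4 effective df and collapses to the linear
           fit when the smoothing parameter saturates", {
  tc <- tiny_cohort()
  rec <- derive_survival(tc$cohort$participants, tc$cohort$diagnoses,
                         mortality_endpoint())
  d <- survival_dataset(rec, tc$cohort$participants, tc$scored)

  fs <- fit_cox_pspline(d, target_df = 4)
  expect_lt(abs(fs$effective_df - 4), 0.1)
  expect_equal(fs$n_events, sum(d$status == "event"))

  fl <- fit_cox(d, exposure_form = "linear")
  flim <- fit_cox_pspline(d, theta = 1 - 1e-7)
  grid <- quantile(d$le8, c(0.2, 0.8))
  cv <- hr_curve(flim, grid = as.numeric(grid))
  slope <- diff(cv$log_hr) / diff(cv$exposure)
  expect_lt(abs(slope - fl$tidy$coef), 1e-3)
  expect_lt(abs(flim$linear_coef - fl$tidy$coef), 1e-3)
})

test_that("hazard-ratio curve is 1 at the reference and tracks a decreasing
           truth", {
  tc <- tiny_cohort()
  rec <- derive_survival(tc$cohort$participants, tc$cohort$diagnoses,
                         mortality_endpoint())
  d <- survival_dataset(rec, tc$cohort$participants, tc$scored)
  fs <- fit_cox_pspline(d)
  at_ref <- hr_curve(fs, grid = fs$reference)
  expect_equal(at_ref$hr, 1)
  expect_equal(at_ref$ci_low, 1)
  expect_equal(at_ref$ci_high, 1)

  cv <- hr_curve(fs)
  # truth is log-linear decreasing; the fitted curve should decrease
  # across the well-supported central range
  central <- cv$exposure > quantile(d$le8, 0.1) &
    cv$exposure < quantile(d$le8, 0.9)
  expect_lt(cor(cv$exposure[central], cv$log_hr[central]), -0.95)
  expect_warning(hr_curve(fs, grid = c(0, 70)), "clipping")
})

test_that("Schoenfeld residuals sum to zero and the PH test holds its level", {
  d <- rand_surv_data(300, beta = 0.5, seed = 21)
  names(d)[3] <- "le8"
  fit <- fit_cox(d, exposure_form = "linear")
  res <- residuals(fit$fit, type = "schoenfeld")
  expect_lt(abs(sum(res)), 1e-8 * fit$n_events)
  tab <- schoenfeld_test(fit)
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))

  # type-I error under proportional hazards
  rej <- vapply(1:300, function(s) {
    ds <- rand_surv_data(120, beta = 0.3, seed = 5000 + s)
    names(ds)[3] <- "le8"
    f <- survival::coxph(survival::Surv(time_years, status == "event") ~ le8,
                         data = ds)
    schoenfeld_test(f)$p_value[1] < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.015)
  expect_lt(mean(rej), 0.10)
})

test_that("the PH diagnostic detects an effect that reverses over time", {
  set.seed(31)
  n <- 5000
  x <- rbinom(n, 1, 0.5)
  # piecewise hazard: protective before t = 5, harmful after
  t1 <- rexp(n, 0.08 * exp(-0.7 * x))
  t2 <- 5 + rexp(n, 0.08 * exp(0.7 * x))
  t <- ifelse(t1 <= 5, t1, t2)
  d <- surv_df(pmin(t, 10), as.integer(t <= 10), x)
  fit <- fit_cox(d, exposure_form = "linear")
  expect_lt(schoenfeld_test(fit)$p_value[1], 0.05)
})

test_that("moderation LRT is calibrated under the null and detects slope
           heterogeneity", {
  # null: moderator unrelated to the LE8 effect
  pvals <- vapply(1:15, function(s) {
    d <- rand_surv_data(600, beta = -0.03, seed = 7000 + s)
    names(d)[3] <- "le8"
    d$le8 <- d$le8 * 10 + 65
    set.seed(s)
    d$grp <- factor(sample(c("a", "b"), nrow(d), TRUE))
    lrt_interaction(d, "grp")$p_value
  }, numeric(1))
  expect_lte(sum(pvals < 0.05), 4)

  # power: slope -0.04 in one stratum vs -0.01 in the other
  detected <- vapply(1:10, function(s) {
    set.seed(8000 + s)
    n <- 4000
    grp <- factor(sample(c("healthy", "multimorbid"), n, TRUE))
    le8 <- runif(n, 30, 95)
    slope <- ifelse(grp == "multimorbid", -0.04, -0.01)
    t <- rexp(n, 0.08 * exp(slope * (le8 - 65)))
    d <- data.frame(
      time_years = pmin(t, 10),
      status = factor(ifelse(t <= 10, "event", "censored"),
                      levels = c("censored", "event", "competing_death")),
      le8 = le8, grp = grp
    )
    lrt_interaction(d, "grp")$p_value < 0.05
  }, logical(1))
  expect_gte(sum(detected), 8)

  d <- rand_surv_data(50, seed = 3)
  names(d)[3] <- "le8"
  d$grp <- factor(rep(c("a", "b"), 25))
  d$status[d$grp == "b"] <- "censored"
  expect_error(lrt_interaction(d, "grp"), "stratum error")
})

test_that("Fine-Gray equals the cause-specific model without competing
           events and recovers a known subdistribution hazard ratio", {
  d <- rand_surv_data(400, beta = 0.5, seed = 41)
  names(d)[3] <- "le8"
  fg <- fine_gray(d, exposure_form = "linear")
  cs <- fit_cox(d, exposure_form = "linear")
  expect_lt(abs(fg$tidy$coef - cs$tidy$coef), 1e-6)
  expect_lt(abs(fg$tidy$se - cs$tidy$se), 1e-6)

  dfg <- rand_finegray_data(4000, beta1 = log(0.6), seed = 43)
  fg2 <- fine_gray(dfg, exposure_form = "linear")
  expect_lt(abs(fg2$tidy$coef - log(0.6)), 2 * fg2$tidy$se)

  # cross-check against an independent implementation of the weighted
  # subdistribution estimator
  cr <- cmprsk::crr(dfg$time_years, as.integer(dfg$status) - 1L,
                    cov1 = matrix(dfg$le8), failcode = 1, cencode = 0)
  expect_lt(abs(fg2$tidy$coef - unname(cr$coef)), 1e-4)

  cc <- cuminc_curves(dfg)
  expect_true(all(cc$cif_event + cc$cif_competing_death <= 1 + 1e-12))
  expect_true(all(diff(cc$cif_event) >= -1e-12))

  d0 <- d; d0$status[] <- "censored"
  expect_error(fine_gray(d0), "estimation error")
})
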