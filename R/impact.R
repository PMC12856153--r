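# Population attributable fractions (PAF) and scenario-based potential
# impact fractions (PIF) on a fitted exposure-hazard curve.
#
# Both measures are scenario arithmetic on relative hazards: with HR(x) the
# fitted hazard-ratio curve,
#   PAF = 1 - sum_i HR(x_ref_i) / sum_i HR(x_i)
#   PIF = 1 - sum_i HR(x'_i)    / sum_i HR(x_i)
# where x_ref is a reference exposure applied to everyone and x' a partial
# counterfactual shift. They are hypothetical, scenario-based measures:
# they assume the fitted association is causal, exposure is measured
# without error, and cardiovascular health is stable over follow-up.

IMPACT_CAVEAT <- paste(
  "Hypothetical, scenario-based measure: assumes a causal exposure-hazard",
  "relationship, no residual confounding, and baseline exposure stability."
)

#' Default eligibility thresholds for component impact fractions
#'
#' A participant is eligible for a single-component improvement scenario
#' when that component's score is below its threshold: < 50 points for
#' smoking, diet and blood pressure; < 60 for non-HDL cholesterol and
#' HbA1c; < 70 for BMI, physical activity and sleep.
#' @export
COMPONENT_PIF_THRESHOLDS <- c(
  smoking = 50, diet = 50, blood_pressure = 50,
  non_hdl = 60, hba1c = 60,
  bmi = 70, physical_activity = 70, sleep = 70
)

# Accept either an le8_pspline fit or a plain HR function of exposure.
as_hr_function <- function(fit, reference = NULL) {
  if (is.function(fit)) {
    return(fit)
  }
  if (inherits(fit, "le8_pspline")) {
    if (is.null(reference)) reference <- fit$reference
    curve <- hr_curve(fit, grid = seq(fit$range[1], fit$range[2],
                                      length.out = 512),
                      reference = reference)
    return(stats::approxfun(curve$exposure, curve$hr, rule = 2))
  }
  fail("'fit' must be an le8_pspline model or an HR function")
}

#' Expected relative event load of an exposure distribution
#'
#' The summation kernel shared by PAF and PIF: `sum_i HR(x_i)`.
#'
#' @param hr_function Function returning the hazard ratio at an exposure.
#' @param exposures Numeric vector of exposures.
#' @return A strictly positive scalar.
#' @export
expected_relative_events <- function(hr_function, exposures) {
  hr <- hr_function(exposures)
  if (any(!is.finite(hr))) fail("non-finite hazard ratio in the summation")
  sum(hr)
}

#' Minimum-hazard exposure of a fitted curve
#'
#' Grid search for the exposure value with the lowest fitted hazard within
#' the observed range; the default PAF reference.
#'
#' @param fit An `le8_pspline` fit.
#' @return A scalar exposure value.
#' @export
min_hazard_exposure <- function(fit) {
  grid <- seq(fit$range[1], fit$range[2], length.out = 512)
  curve <- hr_curve(fit, grid = grid)
  grid[which.min(curve$hr)]
}

impact_result <- function(kind, estimate, ci, n_eligible, scenario) {
  structure(
    list(kind = kind, estimate = estimate,
         ci_low = ci[1], ci_high = ci[2],
         n_eligible = n_eligible, scenario = scenario,
         caveat = IMPACT_CAVEAT),
    class = "le8_impact"
  )
}

#' @export
print.le8_impact <- function(x, ...) {
  ci <- if (is.na(x$ci_low)) "" else {
    sprintf(" (95%% CI %.3f-%.3f)", x$ci_low, x$ci_high)
  }
  cat(sprintf("%s = %.4f%s  [n eligible: %d]\n", x$kind, x$estimate, ci,
              x$n_eligible))
  cat("  scenario:", x$scenario, "\n")
  invisible(x)
}

#' Population attributable fraction
#'
#' Proportion of events that would not occur if every participant were at a
#' reference exposure, computed from the fitted hazard-ratio curve:
#' `PAF = 1 - n * HR(x_ref) / sum_i HR(x_i)`. The default reference rule is
#' the minimum-hazard exposure of the fitted curve; alternatives are the
#' top score (100, clipped to the observed range) or the mean exposure of
#' the healthiest cohort quartile.
#'
#' @param fit An `le8_pspline` fit or an HR function.
#' @param exposures Observed exposure values (composite LE8 scores).
#' @param reference_rule `"min_hazard"`, `"score_100"`, `"top_quartile_mean"`,
#'   or a numeric exposure value.
#' @param boot_reps Bootstrap replicates for a percentile confidence
#'   interval (0 = no interval). Resamples exposures against the fixed
#'   fitted curve; see [impact_bootstrap()] for curve-refitting intervals.
#' @param boot_seed Seed for the bootstrap resampling.
#' @return An `le8_impact` result with `estimate`, CI bounds and scenario
#'   metadata.
#' @export
paf <- function(fit, exposures, reference_rule = "min_hazard",
                boot_reps = 0, boot_seed = 1) {
  hrf <- as_hr_function(fit)
  x_ref <- if (is.numeric(reference_rule)) {
    reference_rule
  } else {
    switch(match.arg(reference_rule,
                     c("min_hazard", "score_100", "top_quartile_mean")),
      min_hazard = {
        if (!inherits(fit, "le8_pspline")) {
          fail("rule error: min_hazard reference needs a fitted spline")
        }
        min_hazard_exposure(fit)
      },
      score_100 = if (inherits(fit, "le8_pspline")) {
        min(100, fit$range[2])
      } else 100,
      top_quartile_mean = {
        q <- assign_quartiles(exposures)
        mean(exposures[q == "Q4"])
      }
    )
  }
  if (inherits(fit, "le8_pspline") &&
      (x_ref < fit$range[1] || x_ref > fit$range[2])) {
    fail("rule error: reference exposure outside the fitted support")
  }
  est_fun <- function(x) 1 - length(x) * hrf(x_ref) /
    expected_relative_events(hrf, x)
  ci <- c(NA_real_, NA_real_)
  if (boot_reps > 0) {
    ci <- bootstrap_ci(est_fun, exposures, reps = boot_reps, seed = boot_seed)
  }
  impact_result("PAF", est_fun(exposures), ci, length(exposures),
                sprintf("reference exposure %.2f (%s)", x_ref,
                        if (is.numeric(reference_rule)) "fixed"
                        else reference_rule))
}

#' Potential impact fraction of a partial exposure shift
#'
#' Counterfactual: every participant with exposure below
#' `eligibility_threshold` gains `shift_points` (capped at `cap`); everyone
#' else is unchanged. `PIF = 1 - sum HR(x') / sum HR(x)`.
#'
#' @inheritParams paf
#' @param shift_points Size of the improvement (default +20 points).
#' @param eligibility_threshold Participants below this exposure are shifted
#'   (default 50).
#' @param cap Upper bound of the shifted exposure (default 100).
#' @return An `le8_impact` result.
#' @export
pif <- function(fit, exposures, shift_points = 20,
                eligibility_threshold = 50, cap = 100,
                boot_reps = 0, boot_seed = 1) {
  if (length(exposures) == 0) fail("size error: empty cohort")
  if (shift_points <= 0) fail("'shift_points' must be > 0")
  if (eligibility_threshold <= 0 || eligibility_threshold > 100) {
    fail("'eligibility_threshold' must lie in (0, 100]")
  }
  hrf <- as_hr_function(fit)
  est_fun <- function(x) {
    eligible <- x < eligibility_threshold
    x_new <- ifelse(eligible, pmin(x + shift_points, cap), x)
    1 - expected_relative_events(hrf, x_new) /
      expected_relative_events(hrf, x)
  }
  ci <- c(NA_real_, NA_real_)
  if (boot_reps > 0) {
    ci <- bootstrap_ci(est_fun, exposures, reps = boot_reps, seed = boot_seed)
  }
  impact_result(
    "PIF", est_fun(exposures), ci,
    sum(exposures < eligibility_threshold),
    sprintf("+%g points for exposure < %g (cap %g)", shift_points,
            eligibility_threshold, cap)
  )
}

#' Potential impact fraction of improving one LE8 component
#'
#' Raises a single component score by `shift_points` (capped at 100) for
#' participants whose component score is below its eligibility threshold
#' (< 50 for smoking, diet and blood pressure; < 60 for non-HDL cholesterol
#' and HbA1c; < 70 for BMI, physical activity and sleep), recomputes the
#' composite as the mean of the eight components (so the composite rises by
#' at most `shift_points / 8` points), and evaluates the PIF through the
#' composite hazard-ratio curve.
#'
#' @inheritParams paf
#' @param scored Component scores from [score_cohort()].
#' @param component One of the eight LE8 component names.
#' @param shift_points Component-score improvement (default +20).
#' @param thresholds Named vector of per-component eligibility thresholds
#'   (defaults above).
#' @return An `le8_impact` result.
#' @export
component_pif <- function(fit, scored, component, shift_points = 20,
                          thresholds = COMPONENT_PIF_THRESHOLDS,
                          boot_reps = 0, boot_seed = 1) {
  if (!component %in% LE8_COMPONENTS) {
    fail("unknown LE8 component '", component, "'")
  }
  if (!component %in% names(thresholds)) {
    fail("no eligibility threshold supplied for '", component, "'")
  }
  hrf <- as_hr_function(fit)
  dat <- data.frame(x = scored$composite, comp = scored[[component]])
  est_fun <- function(d) {
    eligible <- d$comp < thresholds[[component]]
    delta <- (pmin(d$comp + shift_points, 100) - d$comp) / 8
    x_new <- ifelse(eligible, d$x + delta, d$x)
    1 - expected_relative_events(hrf, x_new) /
      expected_relative_events(hrf, d$x)
  }
  ci <- c(NA_real_, NA_real_)
  if (boot_reps > 0) {
    ci <- bootstrap_ci(est_fun, dat, reps = boot_reps, seed = boot_seed)
  }
  impact_result(
    "PIF", est_fun(dat), ci,
    sum(dat$comp < thresholds[[component]]),
    sprintf("component %s +%g points for score < %g", component,
            shift_points, thresholds[[component]])
  )
}

#' Nonparametric bootstrap percentile confidence interval
#'
#' Resamples rows (or elements) of `data` with replacement, recomputes the
#' statistic, and returns the 2.5/97.5 percentile bounds. Replicates where
#' the statistic is not finite (e.g. a resample without events) are dropped
#' and counted in attribute `n_dropped`.
#'
#' @param statistic Function of a resampled `data` returning a scalar.
#' @param data Vector or data frame of resampling units (individuals).
#' @param reps Number of replicates (>= 100; default 500).
#' @param seed RNG seed for the resampling.
#' @param conf_level Confidence level (default 0.95).
#' @return Length-2 numeric vector (lower, upper) with attribute
#'   `n_dropped`.
#' @export
bootstrap_ci <- function(statistic, data, reps = 500, seed = 1,
                         conf_level = 0.95) {
  if (reps < 100) fail("'reps' must be at least 100")
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  vals <- vapply(seq_len(reps), function(r) {
    idx <- sample.int(n, n, replace = TRUE)
    res <- tryCatch(
      if (is.data.frame(data)) statistic(data[idx, , drop = FALSE])
      else statistic(data[idx]),
      error = function(e) NA_real_
    )
    if (is.null(res) || !is.finite(res)) NA_real_ else res
  }, numeric(1))
  dropped <- sum(is.na(vals))
  if (dropped == reps) fail("all bootstrap replicates degenerate")
  alpha <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(vals, c(alpha, 1 - alpha), na.rm = TRUE,
                               type = 7))
  attr(ci, "n_dropped") <- dropped
  ci
}

#' Bootstrap impact-fraction interval with curve refitting
#'
#' Full-refit bootstrap for PAF/PIF: each replicate resamples participants,
#' refits the penalised-spline Cox model, and recomputes the impact
#' fraction, so the interval reflects curve-estimation uncertainty as well
#' as exposure-distribution sampling.
#'
#' @param data Survival dataset used to fit the curve (see
#'   [survival_dataset()]).
#' @param statistic Function of (`fit`, resampled `data`) returning the
#'   impact fraction of interest.
#' @param reps,seed,conf_level As in [bootstrap_ci()].
#' @param target_df,adjustment Spline settings for the per-replicate refit.
#' @return Length-2 numeric vector (lower, upper) with attribute
#'   `n_dropped`.
#' @export
impact_bootstrap <- function(data, statistic, reps = 500, seed = 1,
                             conf_level = 0.95, target_df = 4,
                             adjustment = "model3") {
  bootstrap_ci(
    function(d) {
      fit_b <- fit_cox_pspline(d, target_df = target_df,
                               adjustment = adjustment)
      statistic(fit_b, d)
    },
    data, reps = reps, seed = seed, conf_level = conf_level
  )
}
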