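# Cox proportional-hazards modelling of LE8 and outcomes.
#
# All fits go through survival::coxph. The continuous-exposure models use
# penalised cubic B-splines (survival::pspline) with complexity fixed a
# priori at 4 effective degrees of freedom; the linear-trend component of a
# spline fit is extracted by the information-weighted projection of the
# spline coefficients on the basis centres, the same decomposition the
# survival package prints.

ADJUSTMENT_SETS <- list(
  model1 = character(0),
  model2 = c("age_years", "sex", "townsend"),
  model3 = c("age_years", "sex", "townsend", "com_stroke", "com_mi",
             "com_ccs", "com_hf", "com_t2d", "com_depression")
)

#' Assemble a per-endpoint survival analysis dataset
#'
#' Joins the outcome records to the participants' covariates and LE8 scores.
#' Adds `multimorbidity` (any of the six baseline comorbidities) and
#' `age_group` (dichotomised at 60 years).
#'
#' @param records Output of [derive_survival()].
#' @param participants Participant table ([generate_cohort()] schema).
#' @param scored LE8 scores from [score_cohort()].
#' @return Data frame with `id`, `time_years`, `status`, `le8`, `quartile`,
#'   adjustment covariates and moderator columns.
#' @export
survival_dataset <- function(records, participants, scored) {
  i <- match(records$id, participants$id)
  j <- match(records$id, scored$id)
  if (anyNA(i) || anyNA(j)) fail("records contain ids absent from the cohort")
  com <- c("com_stroke", "com_mi", "com_ccs", "com_hf", "com_t2d",
           "com_depression")
  out <- data.frame(
    id = records$id,
    time_years = records$time_years,
    status = records$status,
    le8 = scored$composite[j],
    # unordered factor so Cox fits use treatment contrasts vs Q1
    quartile = factor(as.character(scored$quartile[j]),
                      levels = paste0("Q", 1:4)),
    age_years = participants$age_years[i],
    sex = factor(participants$sex[i], levels = c("female", "male")),
    townsend = participants$townsend[i],
    participants[i, com]
  )
  if ("entry_years" %in% names(records)) out$entry_years <- records$entry_years
  out$multimorbidity <- factor(
    ifelse(rowSums(out[com]) > 0, "multimorbid", "none"),
    levels = c("none", "multimorbid")
  )
  out$age_group <- factor(
    ifelse(out$age_years >= 60, "60plus", "under60"),
    levels = c("under60", "60plus")
  )
  rownames(out) <- NULL
  out
}

# Internal: Surv() response supporting delayed entry, plus rhs assembly.
cox_formula <- function(data, exposure_term, adjustment) {
  covars <- ADJUSTMENT_SETS[[match.arg(adjustment, names(ADJUSTMENT_SETS))]]
  miss <- setdiff(covars, names(data))
  if (length(miss)) fail("data lacks adjustment covariates: ",
                         paste(miss, collapse = ", "))
  resp <- if ("entry_years" %in% names(data)) {
    "survival::Surv(entry_years, time_years, status == \"event\")"
  } else {
    "survival::Surv(time_years, status == \"event\")"
  }
  stats::as.formula(
    paste(resp, "~", paste(c(exposure_term, covars), collapse = " + "))
  )
}

check_design <- function(formula, data) {
  mm <- stats::model.matrix(formula, data)
  mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  const <- apply(mm, 2, function(z) max(z) == min(z))
  if (any(const)) {
    fail("design error: constant covariate column '",
         colnames(mm)[const][1], "'")
  }
  if (qr(mm)$rank < ncol(mm)) {
    fail("design error: rank-deficient design matrix")
  }
  invisible(TRUE)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximises the partial likelihood (Efron tie handling by default) for the
#' LE8 exposure as cohort quartiles (reference Q1, the least healthy) or as
#' a linear term, with one of three adjustment sets: `model1` (unadjusted),
#' `model2` (age, sex, Townsend deprivation index), `model3` (model2 plus
#' the six baseline comorbidities).
#'
#' @param data Survival dataset from [survival_dataset()] (any data frame
#'   with `time_years`, `status`, the exposure and covariates works).
#' @param exposure Name of the exposure column (default `"le8"`; ignored
#'   for `exposure_form = "quartile"`, which uses `quartile`).
#' @param exposure_form `"quartile"` or `"linear"`.
#' @param adjustment `"model1"`, `"model2"` or `"model3"`.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return An object of class `le8_cox`: list with the `coxph` `fit`, a
#'   `tidy` coefficient table (term, coef, se, HR, CI, p), `n_events`,
#'   `loglik` and `converged`.
#' @export
fit_cox <- function(data, exposure = "le8",
                    exposure_form = c("quartile", "linear"),
                    adjustment = "model1",
                    ties = c("efron", "breslow")) {
  exposure_form <- match.arg(exposure_form)
  ties <- match.arg(ties)
  term <- if (exposure_form == "quartile") "quartile" else exposure
  if (!term %in% names(data)) fail("exposure column '", term, "' not found")
  if (sum(data$status == "event") < 1) fail("no events in the data")
  f <- cox_formula(data, term, adjustment)
  check_design(f, data)
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(f, data = data, ties = ties, model = TRUE,
                    x = FALSE, y = TRUE),
    warning = function(w) {
      if (grepl("converge|infinite|loglik", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (any(!is.finite(fit$coefficients)) ||
      any(sqrt(diag(fit$var)) > 1e3)) {
    fail("divergence: monotone likelihood (separation) suspected")
  }
  sm <- summary(fit)
  tidy <- data.frame(
    term = rownames(sm$coefficients),
    coef = sm$coefficients[, "coef"],
    se = sm$coefficients[, "se(coef)"],
    hr = sm$conf.int[, "exp(coef)"],
    ci_low = sm$conf.int[, "lower .95"],
    ci_high = sm$conf.int[, "upper .95"],
    p = sm$coefficients[, "Pr(>|z|)"],
    row.names = NULL
  )
  structure(
    list(fit = fit, tidy = tidy, n_events = fit$nevent,
         loglik = fit$loglik[2], converged = converged,
         exposure_form = exposure_form, adjustment = adjustment),
    class = "le8_cox"
  )
}

#' @export
print.le8_cox <- function(x, digits = 3, ...) {
  cat("Cox model (", x$adjustment, ", ", x$exposure_form, " exposure), ",
      x$n_events, " events\n", sep = "")
  print(cbind(x$tidy[1], round(x$tidy[-1], digits)))
  invisible(x)
}

# locate the pspline term and its coefficient columns in a coxph fit
pspline_term_info <- function(fit) {
  labs <- names(fit$pterms)
  k <- which(fit$pterms != 0)
  if (length(k) != 1) fail("expected exactly one penalised spline term")
  asgn <- fit$assign
  idx <- if (is.list(asgn)) asgn[[labs[k]]] else which(asgn == k)
  list(label = labs[k], term_index = k, col_index = idx)
}

#' Fit a penalised-spline Cox model for the continuous LE8 score
#'
#' Models the exposure with a penalised cubic B-spline whose smoothing
#' parameter is chosen so the effective degrees of freedom hit `target_df`
#' (a priori 4), on top of one of the three adjustment sets. The linear
#' trend of the fitted curve and its standard error are extracted by the
#' information-weighted projection of the spline coefficients onto the
#' basis centres.
#'
#' @inheritParams fit_cox
#' @param target_df Target effective degrees of freedom of the spline
#'   (default 4).
#' @param theta Optional fixed smoothing parameter in (0, 1); overrides the
#'   degrees-of-freedom search (values near 1 approach the infinite-penalty
#'   limit, i.e. a linear fit).
#' @param nterm Number of spline intervals (default 8 basis functions
#'   before penalisation minus degree adjustments; passed to
#'   [survival::pspline()]).
#' @return An object of class `le8_pspline`: the `coxph` `fit`, the spline
#'   `effective_df`, `linear_coef` and `se_linear`, the exposure `range`,
#'   `reference` (sample median exposure) and bookkeeping needed to
#'   evaluate the hazard-ratio curve.
#' @export
fit_cox_pspline <- function(data, exposure = "le8", target_df = 4,
                            theta = NULL, nterm = 8, adjustment = "model1",
                            ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (!exposure %in% names(data)) fail("exposure column '", exposure, "' not found")
  x <- data[[exposure]]
  if (length(unique(x)) < 10) {
    fail("exposure needs at least 10 distinct values for a spline fit")
  }
  spline_term <- if (is.null(theta)) {
    sprintf("survival::pspline(%s, df = %g, nterm = %d)", exposure,
            target_df, nterm)
  } else {
    sprintf("survival::pspline(%s, theta = %.15g, nterm = %d)", exposure,
            theta, nterm)
  }
  f <- cox_formula(data, spline_term, adjustment)
  fit <- survival::coxph(f, data = data, ties = ties, model = TRUE, y = TRUE)
  info <- pspline_term_info(fit)
  eff_df <- fit$df[info$term_index]
  if (is.null(theta) && abs(eff_df - target_df) > 0.15) {
    fail("spec error: smoothing search stopped at effective df ",
         round(eff_df, 2), ", target ", target_df,
         "; increase nterm")
  }
  # linear-trend decomposition: GLS projection of the spline coefficients
  # on (1, cbase) with weight matrix var^{-1}
  pf <- fit$printfun[[info$term_index]]
  cbase <- eval(formals(pf)$cbase)
  beta <- fit$coefficients[info$col_index]
  V <- fit$var[info$col_index, info$col_index]
  X <- cbind(1, cbase)
  Vi_X <- solve(V, X)
  cmat <- solve(t(X) %*% Vi_X, t(Vi_X))[2, ]
  linear_coef <- sum(cmat * beta)
  se_linear <- sqrt(drop(t(cmat) %*% V %*% cmat))
  structure(
    list(
      fit = fit, exposure = exposure, adjustment = adjustment,
      effective_df = as.numeric(eff_df),
      theta = fit$history[[info$label]]$theta,
      linear_coef = linear_coef, se_linear = se_linear,
      p_linear = 2 * stats::pnorm(-abs(linear_coef / se_linear)),
      range = range(x), reference = stats::median(x),
      n_events = fit$nevent, loglik = fit$loglik[2],
      col_index = info$col_index, term_label = info$label
    ),
    class = "le8_pspline"
  )
}

#' @export
print.le8_pspline <- function(x, digits = 4, ...) {
  cat("Penalised-spline Cox model (", x$adjustment, "), ",
      x$n_events, " events\n", sep = "")
  cat("  effective df:", round(x$effective_df, 2), "\n")
  cat("  linear trend: beta =", signif(x$linear_coef, digits),
      ", SE =", signif(x$se_linear, 2),
      ", p =", format.pval(x$p_linear, digits = 2), "\n")
  invisible(x)
}

# basis rows (spline columns only) for new exposure values
pspline_basis <- function(object, x) {
  nd <- object$fit$model[1, , drop = FALSE]
  nd <- nd[rep(1, length(x)), , drop = FALSE]
  # rebuild a plain data frame carrying the exposure; other covariates keep
  # the template row's values, which cancel in curve contrasts
  plain <- data.frame(row.names = seq_along(x))
  for (nm in names(nd)) {
    v <- nd[[nm]]
    if (inherits(v, "coxph.penalty") || is.matrix(v)) next
    if (inherits(v, "Surv")) next
    plain[[nm]] <- rep(v[1], length(x))
  }
  plain[[object$exposure]] <- x
  tt <- stats::delete.response(stats::terms(object$fit))
  mm <- stats::model.matrix(tt, plain)
  asgn <- attr(mm, "assign")
  keep <- which(asgn == which(attr(tt, "term.labels") == object$term_label))
  mm[, keep, drop = FALSE]
}

#' Hazard-ratio curve from a penalised-spline fit
#'
#' Evaluates `HR(x) = exp(f(x) - f(reference))` on a grid with pointwise
#' delta-method confidence intervals from the basis-contrast covariance.
#' Grid values outside the observed exposure range are clipped to it with a
#' warning.
#'
#' @param object An `le8_pspline` fit.
#' @param grid Exposure values at which to evaluate the curve (default 200
#'   points across the observed range).
#' @param reference Reference exposure (default: the fit's stored sample
#'   median); `HR(reference) = 1` exactly.
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame with `exposure`, `log_hr`, `hr`, `ci_low`, `ci_high`.
#' @export
hr_curve <- function(object, grid = NULL, reference = NULL,
                     conf_level = 0.95) {
  if (!inherits(object, "le8_pspline")) fail("'object' must be an le8_pspline fit")
  if (is.null(reference)) reference <- object$reference
  if (is.null(grid)) {
    grid <- seq(object$range[1], object$range[2], length.out = 200)
  }
  if (any(grid < object$range[1] | grid > object$range[2])) {
    warning("grid extends beyond the observed exposure range; clipping")
    grid <- pmin(pmax(grid, object$range[1]), object$range[2])
  }
  if (reference < object$range[1] || reference > object$range[2]) {
    fail("reference exposure outside the fitted support")
  }
  B <- pspline_basis(object, grid)
  Bref <- pspline_basis(object, reference)
  D <- sweep(B, 2, Bref[1, ])
  beta <- object$fit$coefficients[object$col_index]
  V <- object$fit$var[object$col_index, object$col_index]
  log_hr <- drop(D %*% beta)
  se <- sqrt(pmax(rowSums((D %*% V) * D), 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(
    exposure = grid,
    log_hr = log_hr,
    hr = exp(log_hr),
    ci_low = exp(log_hr - z * se),
    ci_high = exp(log_hr + z * se)
  )
}

#' Proportional-hazards diagnostic from Schoenfeld residuals
#'
#' Per-term score tests of the proportional-hazards assumption
#' ([survival::cox.zph()]), with the correlation between each scaled
#' Schoenfeld residual series and the (km-transformed) event-time scale.
#'
#' @param object An `le8_cox` or `le8_pspline` fit.
#' @param transform Time transform passed to [survival::cox.zph()].
#' @return Data frame with `term`, `chisq`, `df`, `p_value`; coefficient-
#'   level time correlations are attached as attribute `correlations`.
#' @export
schoenfeld_test <- function(object, transform = "km") {
  fit <- if (inherits(object, c("le8_cox", "le8_pspline"))) object$fit else object
  if (fit$nevent < 2) fail("need at least two events for the diagnostic")
  zph <- survival::cox.zph(fit, transform = transform)
  tab <- as.data.frame(zph$table)
  out <- data.frame(
    term = rownames(tab),
    chisq = tab$chisq,
    df = tab$df,
    p_value = tab$p,
    row.names = NULL
  )
  cors <- tryCatch(
    suppressWarnings(apply(zph$y, 2, function(col) stats::cor(zph$x, col))),
    error = function(e) NULL
  )
  attr(out, "correlations") <- cors
  out
}

#' Likelihood-ratio moderation test for the LE8 effect
#'
#' Compares the penalised-spline model with a moderator main effect against
#' the model additionally allowing the LE8 trend to differ by moderator
#' level (exposure-by-moderator interaction). The chi-square is twice the
#' partial-log-likelihood difference; its degrees of freedom are the
#' difference in total effective degrees of freedom, rounded (approximate,
#' as usual for penalised fits).
#'
#' @inheritParams fit_cox_pspline
#' @param moderator Name of a factor column with >= 2 levels, each with
#'   events (e.g. `"age_group"`, `"sex"`, `"multimorbidity"`).
#' @return A list with `chi_square`, `df`, `p_value` and the two fits.
#' @export
lrt_interaction <- function(data, moderator, exposure = "le8", target_df = 4,
                            adjustment = "model1") {
  if (!moderator %in% names(data)) fail("moderator '", moderator, "' not found")
  mod <- as.factor(data[[moderator]])
  if (nlevels(droplevels(mod)) < 2) fail("moderator needs at least 2 levels")
  ev_by <- tapply(data$status == "event", mod, sum)
  if (any(ev_by == 0, na.rm = TRUE)) {
    fail("stratum error: moderator level '",
         names(ev_by)[which(ev_by == 0)[1]], "' has zero events")
  }
  spline_term <- sprintf("survival::pspline(%s, df = %g)", exposure, target_df)
  # the trend-by-moderator terms are built as explicit product columns so
  # they combine cleanly with the penalised spline term
  data <- droplevels(data)
  mod <- droplevels(mod)
  int_cols <- character(0)
  for (lv in levels(mod)[-1]) {
    nm <- paste0(".trend_", make.names(lv))
    data[[nm]] <- data[[exposure]] * (mod == lv)
    int_cols <- c(int_cols, nm)
  }
  f_main <- cox_formula(data, c(spline_term, moderator), adjustment)
  f_int <- cox_formula(data, c(spline_term, moderator, int_cols), adjustment)
  fit_main <- survival::coxph(f_main, data = data)
  fit_int <- survival::coxph(f_int, data = data)
  eff_df <- function(f) {
    if (is.null(f$df)) length(f$coefficients) else sum(f$df)
  }
  chi <- max(0, 2 * (fit_int$loglik[2] - fit_main$loglik[2]))
  df <- max(1L, as.integer(round(eff_df(fit_int) - eff_df(fit_main))))
  list(
    chi_square = chi,
    df = df,
    p_value = stats::pchisq(chi, df, lower.tail = FALSE),
    fit_main = fit_main,
    fit_interaction = fit_int
  )
}

#' Fine-Gray subdistribution-hazard model for MACE
#'
#' Fits the subdistribution hazard of the event of interest treating deaths
#' without prior MACE as competing risks, via censoring-distribution
#' weighted risk sets ([survival::finegray()] expansion followed by a
#' weighted Cox fit). With zero competing events the estimates coincide
#' with the cause-specific model.
#'
#' @inheritParams fit_cox
#' @return An `le8_cox`-style object for the subdistribution hazard.
#' @export
fine_gray <- function(data, exposure = "le8",
                      exposure_form = c("quartile", "linear"),
                      adjustment = "model1") {
  exposure_form <- match.arg(exposure_form)
  if (sum(data$status == "event") < 1) {
    fail("estimation error: no events of interest")
  }
  term <- if (exposure_form == "quartile") "quartile" else exposure
  d <- data
  d$status <- factor(as.character(d$status),
                     levels = c("censored", "event", "competing_death"))
  fg <- survival::finegray(
    survival::Surv(time_years, status) ~ ., data = d, etype = "event"
  )
  f <- stats::as.formula(
    paste("survival::Surv(fgstart, fgstop, fgstatus) ~",
          paste(c(term, ADJUSTMENT_SETS[[adjustment]]), collapse = " + "))
  )
  fit <- survival::coxph(f, data = fg, weights = fgwt, ties = "efron")
  sm <- summary(fit)
  tidy <- data.frame(
    term = rownames(sm$coefficients),
    coef = sm$coefficients[, "coef"],
    se = sm$coefficients[, "se(coef)"],
    hr = exp(sm$coefficients[, "coef"]),
    ci_low = exp(sm$coefficients[, "coef"] - 1.96 * sm$coefficients[, "se(coef)"]),
    ci_high = exp(sm$coefficients[, "coef"] + 1.96 * sm$coefficients[, "se(coef)"]),
    p = sm$coefficients[, "Pr(>|z|)"],
    row.names = NULL
  )
  structure(
    list(fit = fit, tidy = tidy, n_events = sum(data$status == "event"),
         loglik = fit$loglik[2], converged = TRUE,
         exposure_form = exposure_form, adjustment = adjustment,
         model = "fine-gray"),
    class = "le8_cox"
  )
}

#' Cumulative incidence of event and competing death
#'
#' Aalen-Johansen cumulative incidence functions for the two causes.
#'
#' @param records Survival records with the three-level `status`.
#' @return Data frame with `time`, `cif_event`, `cif_competing_death`.
#' @export
cuminc_curves <- function(records) {
  d <- data.frame(
    time = records$time_years,
    status = factor(as.character(records$status),
                    levels = c("censored", "event", "competing_death"))
  )
  fit <- survival::survfit(survival::Surv(time, status) ~ 1, data = d)
  states <- fit$states
  data.frame(
    time = fit$time,
    cif_event = fit$pstate[, which(states == "event")],
    cif_competing_death = fit$pstate[, which(states == "competing_death")]
  )
}
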