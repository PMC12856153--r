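# Endpoint derivation from ICD-10-coded diagnosis records, person-time and
# crude event rates, Kaplan-Meier curves, and the landmark filter.

#' Endpoint definitions
#'
#' `mace_endpoint()` is the composite of ischaemic heart disease (I20-I25),
#' myocardial infarction (I21-I23), stroke (I60, I61, I63, I64) and heart
#' failure (I50.0, I50.1, I50.9); range patterns include all decimal
#' children, enumerated decimal codes match exactly. `af_endpoint()` is the
#' atrial-fibrillation inclusion code I48. `mortality_endpoint()` has no
#' code set: death dates define it.
#'
#' @return An object of class `le8_endpoint` with `name` and `code_sets`.
#' @export
mace_endpoint <- function() {
  structure(
    list(
      name = "mace",
      code_sets = c("I20-I25", "I21-I23", "I60", "I61", "I63", "I64",
                    "I50.0", "I50.1", "I50.9")
    ),
    class = "le8_endpoint"
  )
}

#' @rdname mace_endpoint
#' @export
af_endpoint <- function() {
  structure(list(name = "af", code_sets = "I48"), class = "le8_endpoint")
}

#' @rdname mace_endpoint
#' @export
mortality_endpoint <- function() {
  structure(list(name = "all_cause_mortality", code_sets = character(0)),
            class = "le8_endpoint")
}

# Root (letter + two digits) of an ICD-10 code, validating syntax.
icd10_root <- function(code) {
  ok <- grepl("^[A-Z][0-9]{2}(\\.[0-9]{1,2})?$", code)
  if (any(!ok)) {
    fail("malformed ICD-10 code: '", code[!ok][1],
         "' (expected letter + two digits, optional decimal)")
  }
  substr(code, 1, 3)
}

#' Classify an ICD-10 code against an endpoint definition
#'
#' Range patterns such as `"I21-I23"` match any code whose three-character
#' root falls in the range, including all decimal children; enumerated
#' patterns with a decimal (`"I50.0"`) match that exact code only;
#' enumerated root patterns (`"I63"`) match the root and its children.
#'
#' @param code Character vector of ICD-10 codes (letter + two digits,
#'   optional decimal).
#' @param endpoint An `le8_endpoint`, e.g. [mace_endpoint()].
#' @return Logical vector: does the code qualify for the endpoint?
#' @export
#' @examples
#' classify_icd10(c("I21.0", "I50.2", "I48"), mace_endpoint())
classify_icd10 <- function(code, endpoint) {
  if (!inherits(endpoint, "le8_endpoint")) {
    fail("'endpoint' must be an le8_endpoint object")
  }
  root <- icd10_root(code)
  hit <- rep(FALSE, length(code))
  for (pat in endpoint$code_sets) {
    if (grepl("-", pat, fixed = TRUE)) {
      bounds <- strsplit(pat, "-", fixed = TRUE)[[1]]
      hit <- hit | (root >= bounds[1] & root <= bounds[2])
    } else if (grepl(".", pat, fixed = TRUE)) {
      hit <- hit | code == pat
    } else {
      hit <- hit | root == pat
    }
  }
  hit
}

#' Derive per-endpoint survival records
#'
#' Follow-up runs from baseline (day 0) to the first qualifying event, death,
#' censoring, or the administrative horizon, whichever comes first. For the
#' MACE endpoint, death without a prior MACE is recorded as
#' `competing_death`. Qualifying diagnoses dated at or before baseline are
#' prevalent disease, not outcome events; their count is attached as
#' attribute `n_prevalent_ignored`.
#'
#' @param participants Participant table with `id`, `censor_day` and
#'   (optionally missing) `death_day`.
#' @param diagnoses Long diagnosis table with `id`, `icd10`, `day`.
#' @param endpoint [mortality_endpoint()] or [mace_endpoint()].
#' @param horizon_years Administrative horizon (default 10).
#' @return A data frame (`id`, `time_years`, `status`) with status levels
#'   `censored`, `event` and, for MACE, `competing_death`.
#' @export
derive_survival <- function(participants, diagnoses, endpoint,
                            horizon_years = 10) {
  if (anyNA(participants$censor_day)) {
    fail("every participant needs a censor_day")
  }
  horizon_day <- horizon_years * DAYS_PER_YEAR
  death <- participants$death_day
  if (!is.null(death) && any(!is.na(death) & death > participants$censor_day)) {
    fail("data inconsistency: death_day after censor_day")
  }
  end_admin <- pmin(participants$censor_day, horizon_day)

  if (endpoint$name == "all_cause_mortality") {
    has_death <- !is.na(death) & death <= end_admin
    time_day <- ifelse(has_death, death, end_admin)
    status <- ifelse(has_death, "event", "censored")
    n_prev <- 0L
  } else {
    qual <- diagnoses[classify_icd10(diagnoses$icd10, endpoint), , drop = FALSE]
    if (any(qual$day > 0 &
            qual$day > participants$censor_day[match(qual$id, participants$id)])) {
      fail("data inconsistency: diagnosis after censor_day")
    }
    n_prev <- sum(qual$day <= 0)
    qual <- qual[qual$day > 0, , drop = FALSE]
    first <- tapply(qual$day, factor(qual$id, levels = participants$id), min)
    first <- as.numeric(first)
    death_eff <- ifelse(is.na(death), Inf, death)
    ev_day <- ifelse(is.na(first), Inf, first)
    has_event <- ev_day <= pmin(death_eff, end_admin)
    has_comp <- !has_event & death_eff <= end_admin
    time_day <- pmin(ev_day, death_eff, end_admin)
    status <- ifelse(has_event, "event",
                     ifelse(has_comp, "competing_death", "censored"))
  }
  out <- data.frame(
    id = participants$id,
    time_years = time_day / DAYS_PER_YEAR,
    status = factor(status, levels = c("censored", "event", "competing_death"))
  )
  attr(out, "n_prevalent_ignored") <- n_prev
  attr(out, "endpoint") <- endpoint$name
  out
}

#' Crude event rates per 1000 person-years by group
#'
#' Events and person-years are totalled per group; the rate is
#' `1000 * events / person_years` with a 95 % confidence interval from the
#' normal approximation to the log Poisson rate,
#' `rate * exp(+/- 1.96 / sqrt(events))` (`method = "lognormal"`, the
#' default, which reproduces the published tables). Alternatives: `"normal"`
#' (count-scale normal approximation) and `"exact"` (Garwood chi-square).
#' Rounded columns use half-up rounding to the integer.
#'
#' @param records Survival records from [derive_survival()] (or any data
#'   frame with `time_years` and `status`).
#' @param groups Grouping factor (e.g. LE8 quartile), one value per record.
#' @param method Confidence-interval method, see above.
#' @param conf_level Confidence level (default 0.95).
#' @return A data frame with one row per group: `group`, `events`,
#'   `person_years`, `rate_per_1000`, `ci_low`, `ci_high` and half-up
#'   rounded `rate_rounded`, `ci_low_rounded`, `ci_high_rounded`.
#' @export
rate_table <- function(records, groups,
                       method = c("lognormal", "normal", "exact"),
                       conf_level = 0.95) {
  method <- match.arg(method)
  groups <- as.factor(groups)
  if (length(groups) != nrow(records)) {
    fail("'groups' must have one value per record")
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  events <- tapply(records$status == "event", groups, sum)
  py <- tapply(records$time_years, groups, sum)
  if (any(is.na(py) | py <= 0)) {
    fail("undefined rate: a group has zero person-years")
  }
  rate <- 1000 * events / py
  if (method == "lognormal") {
    lo <- ifelse(events > 0, rate * exp(-z / sqrt(events)), 0)
    hi <- ifelse(events > 0, rate * exp(z / sqrt(events)), 0)
  } else if (method == "normal") {
    lo <- pmax(1000 * (events - z * sqrt(events)) / py, 0)
    hi <- 1000 * (events + z * sqrt(events)) / py
  } else {
    lo <- 1000 * stats::qchisq((1 - conf_level) / 2, 2 * events) / 2 / py
    hi <- 1000 * stats::qchisq(1 - (1 - conf_level) / 2, 2 * (events + 1)) / 2 / py
    lo[events == 0] <- 0
  }
  if (any(events == 0)) {
    warning("group with zero events: degenerate (0, 0) confidence interval")
    hi[events == 0] <- 0
  }
  data.frame(
    group = levels(groups),
    events = as.integer(events),
    person_years = as.numeric(py),
    rate_per_1000 = as.numeric(rate),
    ci_low = as.numeric(lo),
    ci_high = as.numeric(hi),
    rate_rounded = round_half_up(as.numeric(rate)),
    ci_low_rounded = round_half_up(as.numeric(lo)),
    ci_high_rounded = round_half_up(as.numeric(hi)),
    row.names = NULL
  )
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate via [survival::survfit()]; `competing_death`
#' records (if present) are treated as censored, matching the cause-specific
#' Kaplan-Meier display.
#'
#' @param records Survival records (`time_years`, `status`).
#' @param groups Optional grouping factor for stratified curves.
#' @return A data frame with `group` (if stratified), `time`, `n_risk`,
#'   `n_event`, `survival`, including the `time = 0, survival = 1` origin.
#' @export
km_curve <- function(records, groups = NULL) {
  if (nrow(records) < 1) fail("need at least one record")
  ev <- as.integer(records$status == "event")
  df <- data.frame(time = records$time_years, ev = ev)
  if (is.null(groups)) {
    fit <- survival::survfit(survival::Surv(time, ev) ~ 1, data = df)
    grp <- NULL
  } else {
    df$g <- as.factor(groups)
    fit <- survival::survfit(survival::Surv(time, ev) ~ g, data = df)
    grp <- if (is.null(fit$strata)) {
      rep(levels(df$g)[1], length(fit$time))
    } else {
      rep(sub("^g=", "", names(fit$strata)), fit$strata)
    }
  }
  out <- data.frame(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    survival = fit$surv
  )
  if (!is.null(grp)) {
    out <- cbind(group = grp, out)
    origin <- do.call(rbind, lapply(unique(grp), function(g) {
      data.frame(group = g, time = 0, n_risk = sum(df$g == g), n_event = 0,
                 survival = 1)
    }))
    out <- rbind(origin, out)
    out <- out[order(out$group, out$time), ]
  } else {
    out <- rbind(
      data.frame(time = 0, n_risk = nrow(df), n_event = 0, survival = 1),
      out
    )
  }
  rownames(out) <- NULL
  out
}

#' Two-year landmark filter
#'
#' Removes participants whose record ends (event or censoring) at or before
#' the landmark; survivors are retained on the original time scale with a
#' delayed-entry column `entry_years` set to the landmark, so downstream Cox
#' fits condition risk sets on landmark survival.
#'
#' @param records Survival records (`time_years`, `status`).
#' @param landmark_years Landmark time, in (0, horizon) (default 2).
#' @param horizon_years Follow-up horizon used for validation (default 10).
#' @return The filtered records with an `entry_years` column.
#' @export
landmark_filter <- function(records, landmark_years = 2, horizon_years = 10) {
  if (landmark_years <= 0 || landmark_years >= horizon_years) {
    fail("'landmark_years' must lie strictly between 0 and the horizon")
  }
  keep <- records$time_years > landmark_years
  out <- records[keep, , drop = FALSE]
  out$entry_years <- landmark_years
  rownames(out) <- NULL
  out
}
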