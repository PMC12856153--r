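# Life's Essential 8 component scoring.
#
# Each component is scored 0-100 from the rubric band table; the composite
# LE8 is the unweighted mean of the eight components. The diet component is
# an adapted nine-item score: the count of healthy food habits met is ranked
# against the cohort and the cohort quartile mapped to {0, 100/3, 200/3, 100}.

#' The eight LE8 domain names
#'
#' Canonical component order used throughout the package.
#' @export
LE8_COMPONENTS <- c(
  "diet", "physical_activity", "smoking", "sleep",
  "bmi", "non_hdl", "hba1c", "blood_pressure"
)

#' Score smoking status
#'
#' Never smokers receive 100 points, current smokers 0, and former smokers a
#' graded score by years since quitting (>= 5 years: 75; 1 to < 5 years: 50;
#' < 1 year: 25).
#'
#' @param status Character vector with values `"never"`, `"former"`,
#'   `"current"`.
#' @param quit_years Years since quitting; required (non-missing) wherever
#'   `status == "former"`, ignored otherwise.
#' @param rubric Rubric table, see [le8_rubric()].
#' @return Numeric vector of points in \[0, 100\].
#' @export
#' @examples
#' score_smoking(c("never", "current", "former"), quit_years = c(NA, NA, 6))
score_smoking <- function(status, quit_years = NULL, rubric = le8_rubric()) {
  if (!all(status %in% c("never", "former", "current"))) {
    fail("'status' must be one of never/former/current")
  }
  former <- status == "former"
  if (any(former)) {
    if (is.null(quit_years) || anyNA(quit_years[former])) {
      fail("'quit_years' is required for former smokers")
    }
    check_numeric_range(quit_years[former], "quit_years", 0, 100)
  }
  out <- rep(NA_real_, length(status))
  out[status == "never"] <- rubric_constant("smoking_status", "never", rubric)
  out[status == "current"] <- rubric_constant("smoking_status", "current", rubric)
  if (any(former)) {
    out[former] <- rubric_band(quit_years[former], "smoking_former_quit_years", rubric)
  }
  out
}

#' Score body-mass index
#'
#' @param bmi Body-mass index in kg/m^2; must lie in the physiologic range
#'   10-80.
#' @inheritParams score_smoking
#' @return Numeric vector of points in \[0, 100\].
#' @export
score_bmi <- function(bmi, rubric = le8_rubric()) {
  check_numeric_range(bmi, "bmi", 10, 80)
  rubric_band(bmi, "bmi", rubric)
}

#' Score physical activity
#'
#' Activity volume is scored from MET-minutes per week. The bands are the
#' minute bands of the published rubric expressed in MET-minutes at a
#' moderate-intensity equivalent of 4 MET (150 min/week of moderate activity
#' corresponds to 600 MET-min/week).
#'
#' @param met_min_week MET-minutes per week, non-negative.
#' @inheritParams score_smoking
#' @return Numeric vector of points in \[0, 100\].
#' @export
score_physical_activity <- function(met_min_week, rubric = le8_rubric()) {
  check_numeric_range(met_min_week, "met_min_week", 0, Inf)
  rubric_band(met_min_week, "physical_activity_met_min", rubric)
}

#' Score sleep duration
#'
#' @param hours Average sleep per 24 h including naps; must lie in (0, 24).
#' @inheritParams score_smoking
#' @return Numeric vector of points in \[0, 100\].
#' @export
score_sleep <- function(hours, rubric = le8_rubric()) {
  check_numeric_range(hours, "hours", 1e-9, 24 - 1e-9)
  rubric_band(hours, "sleep_hours", rubric)
}

#' Score blood pressure
#'
#' The blood-pressure category is the worse (lower-scoring) of the systolic
#' and diastolic bands; antihypertensive treatment deducts 20 points, with
#' the result floored at 0.
#'
#' @param sbp Systolic blood pressure, mmHg (60-260).
#' @param dbp Diastolic blood pressure, mmHg (30-160).
#' @param treated Logical; on antihypertensive medication.
#' @inheritParams score_smoking
#' @return Numeric vector of points in \[0, 100\].
#' @export
#' @examples
#' score_blood_pressure(115, 75, treated = FALSE)
score_blood_pressure <- function(sbp, dbp, treated = FALSE,
                                 rubric = le8_rubric()) {
  check_numeric_range(sbp, "sbp", 60, 260)
  check_numeric_range(dbp, "dbp", 30, 160)
  treated <- check_flag(treated, "treated", length(sbp))
  pts <- pmin(
    rubric_band(sbp, "bp_sbp", rubric),
    rubric_band(dbp, "bp_dbp", rubric)
  )
  ded <- rubric_constant("treatment_deduction", "blood_pressure", rubric)
  pmax(pts - ded * treated, 0)
}

#' Score non-HDL cholesterol
#'
#' @param non_hdl_mmol_L Non-HDL cholesterol in mmol/L (0.5-15); the band
#'   cut points are the published mg/dL thresholds (130/160/190/220)
#'   converted at 38.67 mg/dL per mmol/L.
#' @param treated Logical; on lipid-lowering medication (deducts 20 points,
#'   floored at 0).
#' @inheritParams score_smoking
#' @return Numeric vector of points in \[0, 100\].
#' @export
score_non_hdl <- function(non_hdl_mmol_L, treated = FALSE,
                          rubric = le8_rubric()) {
  check_numeric_range(non_hdl_mmol_L, "non_hdl_mmol_L", 0.5, 15)
  treated <- check_flag(treated, "treated", length(non_hdl_mmol_L))
  pts <- rubric_band(non_hdl_mmol_L, "non_hdl_mmol_l", rubric)
  ded <- rubric_constant("treatment_deduction", "non_hdl", rubric)
  pmax(pts - ded * treated, 0)
}

#' Score blood glucose (HbA1c)
#'
#' Participants without diabetes score 100 below 39 mmol/mol (5.7 %) and 60
#' in the prediabetic band 39 to < 48 mmol/mol; with diagnosed diabetes (or
#' HbA1c in the diabetic range, >= 48 mmol/mol) the score is capped at 40
#' and graded down by glycaemic control.
#'
#' @param hba1c_mmol_mol Glycated haemoglobin in mmol/mol (15-195).
#' @param diabetic Logical; diagnosed diabetes (type-2 diabetes comorbidity
#'   or glucose-lowering medication).
#' @inheritParams score_smoking
#' @return Numeric vector of points in \[0, 100\].
#' @export
score_hba1c <- function(hba1c_mmol_mol, diabetic = FALSE,
                        rubric = le8_rubric()) {
  check_numeric_range(hba1c_mmol_mol, "hba1c_mmol_mol", 15, 195)
  diabetic <- check_flag(diabetic, "diabetic", length(hba1c_mmol_mol))
  use_diab <- diabetic | hba1c_mmol_mol >= 48
  out <- rep(NA_real_, length(hba1c_mmol_mol))
  if (any(!use_diab)) {
    out[!use_diab] <- rubric_band(hba1c_mmol_mol[!use_diab],
                                  "hba1c_nondiabetic", rubric)
  }
  if (any(use_diab)) {
    out[use_diab] <- rubric_band(hba1c_mmol_mol[use_diab],
                                 "hba1c_diabetic", rubric)
  }
  out
}

# Quartile of a count value relative to a cohort distribution of counts.
# Group sizes follow the largest-remainder rule (extra members to the lowest
# quartiles); boundary cut values are the first member of the next group, so
# ties go to the *upper* group. This keeps "all nine items met" in the top
# quartile even when the cohort is concentrated there. A zero-spread
# distribution falls back to fixed absolute bands (0-2, 3-4, 5-6, 7-9).
diet_quartile <- function(values, distribution) {
  if (length(distribution) < 1) fail("cohort 'distribution' must be nonempty")
  check_numeric_range(values, "items_met", 0, 9)
  check_numeric_range(distribution, "distribution", 0, 9)
  if (length(unique(distribution)) == 1 || length(distribution) < 4) {
    warning("diet item-count distribution has no usable spread; ",
            "falling back to absolute bands 0-2/3-4/5-6/7-9")
    return(findInterval(values, c(0, 3, 5, 7)))
  }
  n <- length(distribution)
  sizes <- n %/% 4 + (seq_len(4) <= n %% 4)
  cuts <- cumsum(sizes)[1:3]
  srt <- sort(distribution)
  v <- srt[cuts + 1]
  1L + (values >= v[1]) + (values >= v[2]) + (values >= v[3])
}

#' Score the adapted nine-item diet component
#'
#' The diet score counts how many of nine healthy food-habit criteria a
#' participant meets (processed meat, red meat, oily fish, alcohol, spread
#' type, wholegrain cereal, salt use, water, fruit and vegetables; each
#' pre-coded as met / not met). The count is ranked against the cohort's
#' distribution of counts and the cohort quartile mapped to points
#' \{0, 100/3, 200/3, 100\}.
#'
#' @param items A vector of nine 0/1 indicators for one participant, or an
#'   n x 9 matrix / data frame of indicators. Missing items are an error
#'   (complete-case rule).
#' @param cohort_distribution Integer vector of items-met counts across the
#'   reference cohort (defaults to the counts of `items` itself when `items`
#'   is a matrix).
#' @inheritParams score_smoking
#' @return A data frame with columns `items_met`, `quartile` (1-4) and
#'   `points`.
#' @export
score_diet <- function(items, cohort_distribution = NULL,
                       rubric = le8_rubric()) {
  if (is.vector(items) && !is.list(items)) items <- matrix(items, nrow = 1)
  items <- as.matrix(items)
  if (ncol(items) != 9) fail("'items' must supply exactly nine food-habit indicators")
  if (anyNA(items)) fail("missing diet item (complete-case rule)")
  if (!all(items %in% c(0, 1, FALSE, TRUE))) {
    fail("diet items must be binary (0/1) indicators")
  }
  items_met <- as.integer(rowSums(items))
  if (is.null(cohort_distribution)) cohort_distribution <- items_met
  q <- diet_quartile(items_met, cohort_distribution)
  pts <- vapply(paste0("q", 1:4), rubric_constant,
                numeric(1), table = "diet_quartile_points", rubric = rubric)
  data.frame(items_met = items_met, quartile = q, points = unname(pts[q]))
}

#' Composite LE8 score
#'
#' Arithmetic mean of the eight component scores. The composite is invariant
#' to component ordering and bounded in \[0, 100\].
#'
#' @param components A named numeric vector (one participant) or data frame /
#'   matrix (one row per participant) whose names are exactly the eight LE8
#'   domains: `r paste(LE8_COMPONENTS, collapse = ", ")`.
#' @return Numeric vector of composite scores.
#' @export
#' @examples
#' composite_le8(c(diet = 80, physical_activity = 80, smoking = 80,
#'   sleep = 80, bmi = 60, non_hdl = 60, hba1c = 60, blood_pressure = 60))
composite_le8 <- function(components) {
  if (is.vector(components) && !is.list(components)) {
    components <- as.data.frame(as.list(components))
  }
  components <- as.data.frame(components)
  nm <- names(components)
  if (anyDuplicated(nm)) fail("duplicate LE8 component: ", nm[duplicated(nm)][1])
  missing <- setdiff(LE8_COMPONENTS, nm)
  extra <- setdiff(nm, LE8_COMPONENTS)
  if (length(missing) || length(extra)) {
    fail("components must be exactly the eight LE8 domains; missing: [",
         paste(missing, collapse = ", "), "], unknown: [",
         paste(extra, collapse = ", "), "]")
  }
  m <- as.matrix(components[LE8_COMPONENTS])
  check_numeric_range(as.numeric(m), "component points", 0, 100)
  rowMeans(m)
}

#' Assign cohort quartiles of the composite LE8 score
#'
#' Cuts at the empirical 25/50/75th percentiles with tied boundary values
#' assigned to the lower quartile; with all-distinct values the group sizes
#' follow the largest-remainder rule (extra members to the lowest
#' quartiles), e.g. 23,758 distinct scores split 5940/5940/5939/5939.
#' Q1 is the least-healthy (lowest-score) quartile.
#'
#' @param composites Numeric vector of at least four finite composite scores.
#' @return Ordered factor with levels `Q1 < Q2 < Q3 < Q4`.
#' @export
#' @examples
#' assign_quartiles(1:8)
assign_quartiles <- function(composites) {
  if (length(composites) < 4) {
    fail("need at least 4 values to form quartiles, got ", length(composites))
  }
  check_numeric_range(composites, "composites", -Inf, Inf)
  lev <- paste0("Q", 1:4)
  if (length(unique(composites)) == 1) {
    warning("all composite values identical; assigning every record to Q1")
    return(factor(rep("Q1", length(composites)), levels = lev, ordered = TRUE))
  }
  n <- length(composites)
  sizes <- n %/% 4 + (seq_len(4) <= n %% 4)
  cuts <- cumsum(sizes)[1:3]
  srt <- sort(composites)
  v <- srt[cuts]
  g <- 1L + (composites > v[1]) + (composites > v[2]) + (composites > v[3])
  factor(lev[g], levels = lev, ordered = TRUE)
}

#' Score a whole cohort
#'
#' Computes the eight LE8 component scores, the composite, and the cohort
#' quartile for every participant of a cohort table as produced by
#' [generate_cohort()] (or read from its CSV export).
#'
#' @param cohort Cohort data frame; see [generate_cohort()] for the schema.
#' @param diet_reference Optional items-met distribution used as the diet
#'   quartile reference (defaults to the cohort itself).
#' @inheritParams score_smoking
#' @return A data frame with `id`, the eight component columns, `composite`
#'   and `quartile`.
#' @export
score_cohort <- function(cohort, diet_reference = NULL, rubric = le8_rubric()) {
  need <- c("id", "smoking_status", "quit_years", "bmi_kg_m2", "sbp_mmHg",
            "dbp_mmHg", "met_min_week", "sleep_hours", "non_hdl_mmol_L",
            "hba1c_mmol_mol", "on_antihypertensive", "on_lipid_lowering",
            "on_glucose_lowering", "com_t2d", paste0("diet", 1:9))
  miss <- setdiff(need, names(cohort))
  if (length(miss)) fail("cohort is missing columns: ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(cohort[setdiff(need, "quit_years")])
  cc <- cc & (cohort$smoking_status != "former" | !is.na(cohort$quit_years))
  if (any(!cc)) {
    message(sum(!cc), " participant(s) dropped for missing LE8 inputs (complete-case rule)")
    cohort <- cohort[cc, , drop = FALSE]
  }
  diet <- score_diet(cohort[paste0("diet", 1:9)], diet_reference, rubric)
  comp <- data.frame(
    diet = diet$points,
    physical_activity = score_physical_activity(cohort$met_min_week, rubric),
    smoking = score_smoking(cohort$smoking_status, cohort$quit_years, rubric),
    sleep = score_sleep(cohort$sleep_hours, rubric),
    bmi = score_bmi(cohort$bmi_kg_m2, rubric),
    non_hdl = score_non_hdl(cohort$non_hdl_mmol_L, cohort$on_lipid_lowering, rubric),
    hba1c = score_hba1c(cohort$hba1c_mmol_mol,
                        cohort$com_t2d | cohort$on_glucose_lowering, rubric),
    blood_pressure = score_blood_pressure(cohort$sbp_mmHg, cohort$dbp_mmHg,
                                          cohort$on_antihypertensive, rubric)
  )
  out <- cbind(data.frame(id = cohort$id), comp)
  out$composite <- composite_le8(comp)
  out$quartile <- assign_quartiles(out$composite)
  out
}
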