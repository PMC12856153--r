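# End-to-end study pipeline: simulate (or ingest) -> score -> outcomes ->
# rates/KM -> Cox models -> diagnostics -> moderation -> PAF/PIF ->
# sensitivity analyses, with every stage's tables written as CSV plus a
# plain-text run manifest.

#' Configure a pipeline run
#'
#' @param out_dir Output directory for result tables and the manifest.
#' @param n_participants,seed Cohort size and master seed for simulation
#'   (ignored when `input_dir` is given).
#' @param input_dir Optional directory with `participants.csv` and
#'   `diagnoses.csv` to analyse instead of simulating.
#' @param cohort Optional pre-built `le8_cohort` object (overrides both).
#' @param horizon_years Follow-up horizon (default 10).
#' @param landmark_years Landmark for the sensitivity analysis, strictly
#'   inside (0, horizon).
#' @param adjustments Character vector of models to fit
#'   (subset of `model1`, `model2`, `model3`).
#' @param boot_reps Bootstrap replicates for PAF/PIF intervals.
#' @param boot_refit Refit the spline per bootstrap replicate (`TRUE`) or
#'   resample against the fixed curve (fast mode, default).
#' @param pif_shift,pif_threshold Overall-scenario shift (+points) and
#'   eligibility threshold.
#' @param spec Optional full [cohort_spec()] overriding the simulation
#'   defaults.
#' @param verbose Print stage progress.
#' @return A validated `le8_run_config` object.
#' @export
pipeline_config <- function(out_dir,
                            n_participants = 23758,
                            seed = 20260101,
                            input_dir = NULL,
                            cohort = NULL,
                            horizon_years = 10,
                            landmark_years = 2,
                            adjustments = c("model1", "model2", "model3"),
                            boot_reps = 500,
                            boot_refit = FALSE,
                            pif_shift = 20,
                            pif_threshold = 50,
                            spec = NULL,
                            verbose = TRUE) {
  if (landmark_years <= 0 || landmark_years >= horizon_years) {
    fail("invalid config: 'landmark_years' must lie in (0, horizon_years)")
  }
  if (!all(adjustments %in% names(ADJUSTMENT_SETS))) {
    fail("invalid config: unknown adjustment model")
  }
  if (boot_reps != 0 && boot_reps < 100) {
    fail("invalid config: 'boot_reps' must be 0 or >= 100")
  }
  if (is.null(spec) && is.null(input_dir) && is.null(cohort)) {
    spec <- cohort_spec(n_participants, seed, horizon_years = horizon_years)
  }
  structure(
    list(out_dir = out_dir, input_dir = input_dir, cohort = cohort,
         spec = spec, horizon_years = horizon_years,
         landmark_years = landmark_years, adjustments = adjustments,
         boot_reps = boot_reps, boot_refit = boot_refit,
         pif_shift = pif_shift, pif_threshold = pif_threshold,
         seed = seed, verbose = verbose),
    class = "le8_run_config"
  )
}

write_table <- function(x, dir, name) {
  utils::write.csv(x, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
}

tidy_or_na <- function(fit) fit$tidy

#' Run the full analysis pipeline
#'
#' Executes every stage of the study on a simulated or supplied cohort and
#' writes the result tables under `config$out_dir`: baseline
#' characteristics by quartile, per-endpoint rate tables and Kaplan-Meier
#' curves, quartile/linear/penalised-spline Cox models for each adjustment
#' set, proportional-hazards diagnostics, moderation tests, PAF and PIF
#' (overall and per component), the 2-year landmark reanalysis and the
#' Fine-Gray competing-risk model for MACE, plus `manifest.txt` recording
#' the configuration hash, seed and package version. A stage failure aborts
#' downstream stages but already-written tables are preserved.
#'
#' @param config An `le8_run_config` from [pipeline_config()].
#' @return Invisibly, a list with the key in-memory results.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "le8_run_config")) {
    fail("'config' must come from pipeline_config()")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (config$verbose) message("[le8af] ", ...)

  # --- stage 1: cohort -------------------------------------------------
  say("stage 1/7: cohort")
  cohort <- if (!is.null(config$cohort)) {
    config$cohort
  } else if (!is.null(config$input_dir)) {
    cc <- read_cohort_csv(config$input_dir)
    structure(list(participants = cc$participants, diagnoses = cc$diagnoses,
                   spec = NULL), class = "le8_cohort")
  } else {
    generate_cohort(config$spec)
  }
  write_cohort_csv(cohort, config$out_dir)

  # --- stage 2: scoring ------------------------------------------------
  say("stage 2/7: LE8 scoring")
  scored <- score_cohort(cohort$participants)
  write_table(scored, config$out_dir, "scored")
  write_table(baseline_table(cohort$participants, scored),
              config$out_dir, "baseline_by_quartile")

  # --- stage 3: outcomes, rates, KM -----------------------------------
  say("stage 3/7: outcomes, rates, Kaplan-Meier")
  endpoints <- list(mortality = mortality_endpoint(), mace = mace_endpoint())
  data_by_ep <- list()
  for (ep in names(endpoints)) {
    rec <- derive_survival(cohort$participants, cohort$diagnoses,
                           endpoints[[ep]], config$horizon_years)
    d <- survival_dataset(rec, cohort$participants, scored)
    data_by_ep[[ep]] <- d
    write_table(rate_table(rec, d$quartile), config$out_dir,
                paste0("rates_", ep))
    write_table(km_curve(rec, d$quartile), config$out_dir,
                paste0("km_", ep))
  }

  # --- stage 4: Cox models --------------------------------------------
  say("stage 4/7: Cox models (quartile, linear, spline)")
  spline_fits <- list()
  cox_rows <- list()
  for (ep in names(endpoints)) {
    d <- data_by_ep[[ep]]
    for (adj in config$adjustments) {
      fq <- fit_cox(d, exposure_form = "quartile", adjustment = adj)
      tq <- tidy_or_na(fq)
      tq$model <- adj; tq$endpoint <- ep; tq$exposure <- "quartile"
      fl <- fit_cox(d, exposure_form = "linear", adjustment = adj)
      tl <- tidy_or_na(fl)
      tl$model <- adj; tl$endpoint <- ep; tl$exposure <- "linear"
      fs <- fit_cox_pspline(d, adjustment = adj)
      ts <- data.frame(
        term = "le8 (spline linear trend)", coef = fs$linear_coef,
        se = fs$se_linear, hr = exp(fs$linear_coef),
        ci_low = exp(fs$linear_coef - 1.96 * fs$se_linear),
        ci_high = exp(fs$linear_coef + 1.96 * fs$se_linear),
        p = fs$p_linear, model = adj, endpoint = ep, exposure = "pspline"
      )
      cox_rows <- c(cox_rows, list(tq, tl, ts))
      spline_fits[[paste(ep, adj, sep = "_")]] <- fs
    }
  }
  write_table(do.call(rbind, cox_rows), config$out_dir, "cox_models")
  final_adj <- config$adjustments[length(config$adjustments)]
  for (ep in names(endpoints)) {
    fs <- spline_fits[[paste(ep, final_adj, sep = "_")]]
    write_table(hr_curve(fs), config$out_dir, paste0("hr_curve_", ep))
  }

  # --- stage 5: diagnostics + moderation ------------------------------
  say("stage 5/7: diagnostics and moderation")
  diag_rows <- list()
  mod_rows <- list()
  for (ep in names(endpoints)) {
    d <- data_by_ep[[ep]]
    ph <- schoenfeld_test(fit_cox(d, exposure_form = "quartile",
                                  adjustment = final_adj))
    ph$endpoint <- ep
    diag_rows[[ep]] <- ph
    for (m in c("age_group", "sex", "multimorbidity")) {
      lr <- lrt_interaction(d, m, adjustment = final_adj)
      mod_rows[[paste(ep, m)]] <- data.frame(
        endpoint = ep, moderator = m, chi_square = lr$chi_square,
        df = lr$df, p_value = lr$p_value
      )
    }
  }
  write_table(do.call(rbind, diag_rows), config$out_dir, "ph_diagnostics")
  write_table(do.call(rbind, mod_rows), config$out_dir, "moderation")

  # --- stage 6: PAF / PIF ---------------------------------------------
  say("stage 6/7: attributable and impact fractions")
  impact_rows <- list()
  comp_rows <- list()
  for (ep in names(endpoints)) {
    d <- data_by_ep[[ep]]
    fs <- spline_fits[[paste(ep, final_adj, sep = "_")]]
    le8 <- d$le8
    if (config$boot_refit && config$boot_reps > 0) {
      pa <- paf(fs, le8)
      pa_ci <- impact_bootstrap(
        d, function(fb, db) paf(fb, db$le8)$estimate,
        reps = config$boot_reps, seed = config$seed,
        adjustment = final_adj
      )
      pa$ci_low <- pa_ci[1]; pa$ci_high <- pa_ci[2]
      pi_ <- pif(fs, le8, shift_points = config$pif_shift,
                 eligibility_threshold = config$pif_threshold)
      pi_ci <- impact_bootstrap(
        d, function(fb, db) pif(fb, db$le8,
                                shift_points = config$pif_shift,
                                eligibility_threshold = config$pif_threshold)$estimate,
        reps = config$boot_reps, seed = config$seed + 1,
        adjustment = final_adj
      )
      pi_$ci_low <- pi_ci[1]; pi_$ci_high <- pi_ci[2]
    } else {
      reps <- config$boot_reps
      pa <- paf(fs, le8, boot_reps = reps, boot_seed = config$seed)
      pi_ <- pif(fs, le8, shift_points = config$pif_shift,
                 eligibility_threshold = config$pif_threshold,
                 boot_reps = reps, boot_seed = config$seed + 1)
    }
    impact_rows[[ep]] <- data.frame(
      endpoint = ep,
      measure = c("PAF", "PIF"),
      estimate = c(pa$estimate, pi_$estimate),
      ci_low = c(pa$ci_low, pi_$ci_low),
      ci_high = c(pa$ci_high, pi_$ci_high),
      n_eligible = c(pa$n_eligible, pi_$n_eligible),
      scenario = c(pa$scenario, pi_$scenario),
      caveat = IMPACT_CAVEAT
    )
    sc_d <- scored[match(d$id, scored$id), ]
    for (comp in LE8_COMPONENTS) {
      cp <- component_pif(fs, sc_d, comp,
                          boot_reps = config$boot_reps,
                          boot_seed = config$seed + 2)
      comp_rows[[paste(ep, comp)]] <- data.frame(
        endpoint = ep, component = comp, pif = cp$estimate,
        ci_low = cp$ci_low, ci_high = cp$ci_high,
        n_eligible = cp$n_eligible
      )
    }
  }
  write_table(do.call(rbind, impact_rows), config$out_dir, "impact_overall")
  write_table(do.call(rbind, comp_rows), config$out_dir, "impact_components")

  # --- stage 7: sensitivity analyses ----------------------------------
  say("stage 7/7: landmark and competing-risk sensitivity")
  d_land <- data_by_ep$mortality
  rec_land <- landmark_filter(d_land[c("id", "time_years", "status")],
                              config$landmark_years, config$horizon_years)
  d_lm <- survival_dataset(rec_land, cohort$participants, scored)
  f_lm <- fit_cox(d_lm, exposure_form = "quartile", adjustment = final_adj)
  t_lm <- tidy_or_na(f_lm); t_lm$analysis <- "landmark_mortality"
  f_fg <- fine_gray(data_by_ep$mace, exposure_form = "quartile",
                    adjustment = final_adj)
  t_fg <- tidy_or_na(f_fg); t_fg$analysis <- "fine_gray_mace"
  write_table(rbind(t_lm, t_fg), config$out_dir, "sensitivity")

  manifest(config, config$out_dir)
  say("done: tables in ", config$out_dir)
  invisible(list(
    cohort = cohort, scored = scored, data = data_by_ep,
    spline_fits = spline_fits, impact = impact_rows,
    component_pif = comp_rows
  ))
}

#' Baseline characteristics by LE8 quartile
#'
#' Mean (SD) summaries of the main continuous measurements and frequencies
#' (%) of categorical ones, stratified by cohort quartile of the composite
#' LE8 score.
#'
#' @param participants Participant table.
#' @param scored Output of [score_cohort()].
#' @return A data frame with one row per characteristic.
#' @export
baseline_table <- function(participants, scored) {
  q <- scored$quartile[match(participants$id, scored$id)]
  msd <- function(v) {
    m <- tapply(v, q, mean); s <- tapply(v, q, stats::sd)
    sprintf("%.2f (%.1f)", c(m, mean(v)), c(s, stats::sd(v)))
  }
  npct <- function(flag) {
    k <- tapply(flag, q, sum); n <- tapply(flag, q, length)
    sprintf("%d (%.0f%%)", c(k, sum(flag)), 100 * c(k / n, mean(flag)))
  }
  rows <- list(
    n = c(as.vector(table(q)), length(q)),
    age_years = msd(participants$age_years),
    female = npct(participants$sex == "female"),
    townsend = msd(participants$townsend),
    bmi = msd(participants$bmi_kg_m2),
    sbp = msd(participants$sbp_mmHg),
    dbp = msd(participants$dbp_mmHg),
    met_min_week = msd(participants$met_min_week),
    smoking_current = npct(participants$smoking_status == "current"),
    smoking_former = npct(participants$smoking_status == "former"),
    smoking_never = npct(participants$smoking_status == "never"),
    hba1c = msd(participants$hba1c_mmol_mol),
    non_hdl = msd(participants$non_hdl_mmol_L),
    antihypertensive = npct(participants$on_antihypertensive),
    lipid_lowering = npct(participants$on_lipid_lowering),
    glucose_lowering = npct(participants$on_glucose_lowering),
    le8_composite = msd(scored$composite)
  )
  out <- data.frame(
    characteristic = names(rows),
    do.call(rbind, lapply(rows, as.character))
  )
  names(out)[2:6] <- c("Q1_least_healthy", "Q2", "Q3", "Q4_healthiest",
                       "total")
  rownames(out) <- NULL
  out
}

# Plain-text manifest: configuration hash, seed, versions.
manifest <- function(config, dir) {
  cfg <- config[setdiff(names(config), c("cohort", "verbose"))]
  tmp <- tempfile()
  dput(cfg, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  lines <- c(
    "le8af run manifest",
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste0("config_md5: ", hash),
    paste0("seed: ", config$seed),
    paste0("package_version: ", as.character(utils::packageVersion("le8af"))),
    paste0("r_version: ", R.version.string),
    paste0("survival_version: ",
           as.character(utils::packageVersion("survival")))
  )
  writeLines(lines, file.path(dir, "manifest.txt"))
  invisible(lines)
}
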