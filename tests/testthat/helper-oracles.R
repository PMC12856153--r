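# Independent oracles used across the suite. These re-derive expected
# results by brute force (nested if-else band tables, explicit risk-set
# recomputation, dense grid search, per-individual loops) and share no code
# with the package implementation they check.

# --- scoring rubric, independently coded as nested conditionals ----------
oracle_score <- function(component, x, treated = FALSE, diabetic = FALSE,
                         status = NULL, quit = NULL) {
  switch(component,
    bmi = if (x < 25) 100 else if (x < 30) 70 else if (x < 35) 30
          else if (x < 40) 15 else 0,
    activity = if (x >= 600) 100 else if (x >= 480) 90 else if (x >= 360) 80
               else if (x >= 240) 60 else if (x >= 120) 40
               else if (x >= 4) 20 else 0,
    sleep = if (x >= 7 && x < 9) 100 else if (x >= 9 && x < 10) 90
            else if (x >= 6 && x < 7) 70 else if ((x >= 5 && x < 6) || x >= 10) 40
            else if (x >= 4 && x < 5) 20 else 0,
    non_hdl = max(0, (if (x < 3.36) 100 else if (x < 4.14) 60
                      else if (x < 4.91) 40 else if (x < 5.69) 20 else 0) -
                     20 * treated),
    hba1c = if (diabetic || x >= 48) {
      if (x < 53) 40 else if (x < 64) 30 else if (x < 75) 20
      else if (x < 86) 10 else 0
    } else if (x < 39) 100 else 60,
    smoking = if (status == "never") 100 else if (status == "current") 0
              else if (quit >= 5) 75 else if (quit >= 1) 50 else 25,
    stop("unknown component")
  )
}

oracle_bp <- function(sbp, dbp, treated = FALSE) {
  cat_s <- if (sbp < 120) 1 else if (sbp < 130) 2 else if (sbp < 140) 3
           else if (sbp < 160) 4 else 5
  cat_d <- if (dbp < 80) 1 else if (dbp < 90) 3 else if (dbp < 100) 4 else 5
  pts <- c(100, 75, 50, 25, 0)[max(cat_s, cat_d)]
  max(0, pts - 20 * treated)
}

# --- product-limit estimator by explicit risk sets -----------------------
oracle_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = tt, surv = NA_real_)
  for (k in seq_along(tt)) {
    at_risk <- sum(time >= tt[k])
    d <- sum(time == tt[k] & event == 1)
    s <- s * (1 - d / at_risk)
    out$surv[k] <- s
  }
  out
}

# --- Cox partial log-likelihood (Breslow, valid for distinct times) ------
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
  }
  ll
}

# dense two-stage grid search of the partial-likelihood maximum
oracle_cox_grid <- function(time, event, x, lim = 4) {
  g1 <- seq(-lim, lim, by = 1e-3)
  ll1 <- vapply(g1, oracle_cox_loglik, numeric(1), time, event, x)
  b1 <- g1[which.max(ll1)]
  g2 <- seq(b1 - 2e-3, b1 + 2e-3, by = 1e-5)
  ll2 <- vapply(g2, oracle_cox_loglik, numeric(1), time, event, x)
  g2[which.max(ll2)]
}

# --- impact-fraction closed forms and loops ------------------------------
levin_paf <- function(p_exposed, hr) {
  p_exposed * (hr - 1) / (1 + p_exposed * (hr - 1))
}

loop_pif <- function(hrf, x, shift, threshold, cap = 100) {
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    xi <- x[i]
    xn <- if (xi < threshold) min(xi + shift, cap) else xi
    num <- num + hrf(xn)
    den <- den + hrf(xi)
  }
  1 - num / den
}

# --- small random survival datasets --------------------------------------
rand_surv_data <- function(n, beta = 0.5, seed = 1) {
  set.seed(seed)
  x <- round(stats::rnorm(n), 2)
  t <- stats::rexp(n, 0.5 * exp(beta * x))
  # jitter to keep event times distinct (Breslow oracle assumption)
  t <- t + seq_len(n) * 1e-9
  ev <- stats::rbinom(n, 1, 0.8)
  data.frame(
    time_years = t,
    status = factor(ifelse(ev == 1, "event", "censored"),
                    levels = c("censored", "event", "competing_death")),
    x = x
  )
}

# Fine-Gray simulation: subdistribution model for cause 1 with
# F1(t|x) = 1 - (1 - p(1 - exp(-t)))^exp(beta*x)  (Fine & Gray 1999 style)
rand_finegray_data <- function(n, beta1, p = 0.6, seed = 1) {
  set.seed(seed)
  x <- stats::rbinom(n, 1, 0.5)
  eta <- exp(beta1 * x)
  p_c1 <- 1 - (1 - p)^eta
  cause <- ifelse(stats::runif(n) < p_c1, 1L, 2L)
  v <- stats::runif(n)
  inner <- (1 - v * p_c1)^(1 / eta)
  t1 <- -log(1 - (1 - inner) / p)
  t2 <- stats::rexp(n, 1)
  time <- ifelse(cause == 1, t1, t2)
  cens <- stats::runif(n, 0.5, 6)
  obs <- pmin(time, cens)
  status <- ifelse(time <= cens, cause, 0L)
  data.frame(
    time_years = obs,
    status = factor(c("censored", "event", "competing_death")[status + 1L],
                    levels = c("censored", "event", "competing_death")),
    le8 = x
  )
}

# small synthetic cohort shared by several tests (built once per run)
tiny_cohort <- local({
  cache <- NULL
  function(n = 1500, seed = 42) {
    if (is.null(cache)) {
      co <- generate_cohort(cohort_spec(n, seed = seed))
      sc <- score_cohort(co$participants)
      cache <<- list(cohort = co, scored = sc)
    }
    cache
  }
})
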