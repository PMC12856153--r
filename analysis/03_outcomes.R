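#!/usr/bin/env Rscript
# Stage 3: derive all-cause mortality and MACE survival records from the
# ICD-10 diagnosis stream, tabulate crude rates per 1000 person-years by
# LE8 quartile, and export Kaplan-Meier curves.

library(le8af)

cohort <- read_cohort_csv("results/study")
scored <- read.csv("results/study/scored.csv")
scored$quartile <- factor(scored$quartile, levels = paste0("Q", 1:4))

for (ep in c("mortality", "mace")) {
  endpoint <- if (ep == "mortality") mortality_endpoint() else mace_endpoint()
  rec <- derive_survival(cohort$participants, cohort$diagnoses, endpoint)
  write.csv(rec, sprintf("results/study/surv_%s.csv", ep), row.names = FALSE)
  q <- scored$quartile[match(rec$id, scored$id)]
  rt <- rate_table(rec, q)
  write.csv(rt, sprintf("results/study/rates_%s.csv", ep), row.names = FALSE)
  km <- km_curve(rec, q)
  write.csv(km, sprintf("results/study/km_%s.csv", ep), row.names = FALSE)
  cat(sprintf("\n%s: %d events, %.0f person-years (prevalent codes ignored: %d)\n",
              ep, sum(rec$status == "event"), sum(rec$time_years),
              attr(rec, "n_prevalent_ignored")))
  cat("  rate/1000py (95% CI) by quartile:",
      sprintf("%d (%d-%d)", rt$rate_rounded, rt$ci_low_rounded,
              rt$ci_high_rounded), "\n")
}
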