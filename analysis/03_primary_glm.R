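#!/usr/bin/env Rscript
# Primary inference: 2x2 mixed GLM on DMN strength (group, stress,
# interaction), within-group simple effects with percent differences,
# between-group contrasts at each condition, covariate-adjusted interaction,
# and delta-strength/severity correlations.
#
# Reads results/strengths.csv + results/subjects.csv, writes
# results/report.json, results/report.txt.

library(netstress)

strengths <- read.csv("results/strengths.csv")
subjects <- read.csv("results/subjects.csv")

wide <- reshape(strengths[, c("subject", "scan_label", "value")],
                idvar = "subject", timevar = "scan_label",
                direction = "wide")
stopifnot(setequal(wide$subject, subjects$subject_id))
m <- match(subjects$subject_id, wide$subject)

cohort <- cohort_table(
  subjects$subject_id, subjects$group,
  strength_pre = wide$value.pre[m], strength_post = wide$value.post[m],
  covariates = subjects[, c("age", "sex_male", "motion_pre", "motion_post",
                            "antidepressant", "comorbid_substance",
                            "comorbid_alcohol", "comorbid_gad",
                            "comorbid_panic", "comorbid_ocd",
                            "comorbid_social_anxiety")],
  scores = subjects[, c("qids", "pcl5_total", "caps_reexperiencing",
                        "caps_avoidance", "caps_negative_mood",
                        "caps_arousal")])

report <- run_analysis(
  cohort,
  covariates = c("motion_pre", "motion_post", "age", "sex_male",
                 "antidepressant", "comorbid_substance", "comorbid_alcohol",
                 "comorbid_gad", "comorbid_panic", "comorbid_ocd",
                 "comorbid_social_anxiety"),
  seed = 17L)

print(report)
write_report(report, "results", cohort = cohort)
cat("wrote results/report.json, results/report.txt, results/strengths.csv\n")
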