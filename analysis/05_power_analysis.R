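#!/usr/bin/env Rscript
# Power analysis for the 2x2 design at the study's group sizes: minimum
# detectable Cohen's d for the stress (paired, n = 52), group (between
# groups on two-scan averages) and interaction (between groups on
# difference scores) effects at 80/85/90% power, under both the exact
# noncentral-t evaluation and the normal approximation.
#
# Writes results/power_table.csv.

library(netstress)

dir.create("results", showWarnings = FALSE)
tabs <- lapply(c("nct", "normal"), function(m) {
  tab <- power_table(28, 24, method = m)
  tab$method <- m
  tab
})
tab <- do.call(rbind, tabs)
write.csv(tab, "results/power_table.csv", row.names = FALSE)

cat("minimum detectable Cohen's d (n = 28 + 24, two-tailed alpha = 0.05):\n")
print(tab, digits = 3, row.names = FALSE)
cat("\nthe design detects a small stress effect, a medium group effect and\n")
cat("a large interaction effect; 0.79 at 80% power is the interaction\n")
cat("decrement injected by analysis/01_simulate_cohort.R\n")
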