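#!/usr/bin/env Rscript
# Build Fisher-z connectomes from the simulated scans and extract DMN
# network-restricted strength per subject and scan.
#
# Reads scratch/sim_scans/*.tsv + results/atlas.tsv (from 01), writes
# results/strengths.csv (subject, scan_label, network, n_nodes, value).

library(netstress)

atlas <- read_atlas("results/atlas.tsv")
subjects <- read.csv("results/subjects.csv")
files <- list.files("scratch/sim_scans", pattern = "\\.tsv$",
                    full.names = TRUE)
if (!length(files)) stop("no scans found; run analysis/01_simulate_cohort.R first")

rows <- lapply(files, function(f) {
  stem <- sub("\\.tsv$", "", basename(f))
  subj <- sub("_(pre|post)$", "", stem)
  scan <- sub("^.*_", "", stem)
  ts <- read_timeseries(f, scan_label = scan)
  s <- scan_strength(ts, atlas, "DMN")
  data.frame(subject = subj, scan_label = scan, network = "DMN",
             n_nodes = s$n_nodes, value = s$value)
})
strengths <- do.call(rbind, rows)
write.csv(strengths, "results/strengths.csv", row.names = FALSE)

wide <- reshape(strengths[, c("subject", "scan_label", "value")],
                idvar = "subject", timevar = "scan_label",
                direction = "wide")
cat(sprintf("DMN strength over %d subjects: pre %.3f (SD %.3f), post %.3f (SD %.3f)\n",
            nrow(wide), mean(wide$value.pre), sd(wide$value.pre),
            mean(wide$value.post), sd(wide$value.post)))
cat("wrote results/strengths.csv\n")
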