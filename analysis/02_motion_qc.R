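#!/usr/bin/env Rscript
# Stage 2 — motion quality control.
#
# Emulates the recruitment-to-analysis funnel: 36 children and 21 adults are
# "scanned", 11 children and 1 adult with excessive head motion. Volumes
# with a framewise motion metric above the boxplot upper fence
# (Q75 + 1.5 IQR) are flagged; participants with more than 15% flagged
# volumes, or any rotation series beyond 1.5, are excluded. Writes the
# exclusion report under results/qc/.

library(affrsa)

dir.create("results/qc", recursive = TRUE, showWarnings = FALSE)

cohort <- simulate_motion_cohort(n_children = 36, n_adults = 21,
                                 high_motion_children = 11,
                                 high_motion_adults = 1,
                                 n_volumes = 510, seed = 1L)
qc <- qc_cohort(cohort$motion)
write.csv(qc, "results/qc/qc_report.csv", row.names = FALSE)

cat(sprintf("recruited %d participants; excluded %d; effective N = %d\n",
            nrow(qc), sum(!qc$kept), sum(qc$kept)))
excl <- qc[!qc$kept, ]
cat("exclusions:\n")
for (i in seq_len(nrow(excl))) {
  cat(sprintf("  %s: %s\n", excl$participant_id[i], excl$reason[i]))
}

# spike regressors for one example participant, as they enter the GLM
m <- cohort$motion[[1]]
flags <- flag_outliers(m$metric)
cat(sprintf("example participant: %d/%d volumes flagged (%.1f%%), %d spike regressors\n",
            sum(flags), length(flags), 100 * mean(flags),
            ncol(spike_regressors(flags))))
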