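#!/usr/bin/env Rscript
# Stage 6 — replication experiments (reduced scale).
#
# Two simulation experiments over replicate studies:
#   (a) parameter recovery — with the power-sized recovery grid planted,
#       how often do all the qualitative contrasts come back with the right
#       sign and Bonferroni-adjusted significance? (20 replicates here; the
#       acceptance script runs 100)
#   (b) Type-I error — with no representational structure planted, how
#       often does the ROI x age interaction reject at alpha = 0.05?
#       (100 null studies here; the acceptance script runs 500)

library(affrsa)

dir.create("results/replication", recursive = TRUE, showWarnings = FALSE)
fams <- default_contrast_families()

cat("(a) sign-pattern recovery, 20 replicate studies\n")
hits <- 0
for (rep in 1:20) {
  cfg <- simulation_config(rois = c(AMY = 24, NAcc = 24, vmPFC = 24),
                           similarity = recovery_grid())
  st <- simulate_study(cfg, seed = 600 + rep)
  ct <- bonferroni_contrasts(st$similarity, fams$roi_by_age)
  ok <- all(ct[ct$label %in% c("AMY, child vs adult", "NAcc, child vs adult",
                               "vmPFC, child vs adult"), "mean_difference"] > 0) &&
    all(ct[ct$label %in% c("child, AMY vs vmPFC",
                           "child, NAcc vs vmPFC"), "mean_difference"] < 0) &&
    all(ct$p_adjusted[abs(ct$t) > 4] < 0.05)
  if (ok) hits <- hits + 1
}
cat(sprintf("  qualitative ROI pattern recovered in %d/20 replicates\n", hits))

cat("(b) Type-I error of the ROI x age interaction, 100 null studies\n")
rej <- 0
for (rep in 1:100) {
  cfg <- simulation_config(rois = c(AMY = 24, NAcc = 24, vmPFC = 24),
                           similarity = similarity_grid(a = 0),
                           participant_sd = 0)
  st <- simulate_study(cfg, seed = 700 + rep)
  a <- mixed_anova(st$similarity)
  if (a$p[a$effect == "age_group:roi"] < 0.05) rej <- rej + 1
}
cat(sprintf("  rejection rate at alpha = 0.05: %.1f%% (nominal 5%%)\n",
            100 * rej / 100))

writeLines(c(sprintf("recovery_hits_of_20\t%d", hits),
             sprintf("null_rejections_of_100\t%d", rej)),
           "results/replication/summary.tsv")
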