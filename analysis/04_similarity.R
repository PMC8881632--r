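#!/usr/bin/env Rscript
# Stage 4 — representational similarity.
#
# Computes the dependent measure for the full simulated cohort: for every
# participant and ROI, all within-valence inter-movie clip pairs are
# correlated (Spearman with midranks, pairwise-complete over voxels) and
# Fisher Z transformed. The stated design gives 28 pairs per valence, hence
# 252 records per participant and 11,340 for the 45-participant cohort.
# Writes the long-format table under results/similarity/.

library(affrsa)

dir.create("results/similarity", recursive = TRUE, showWarnings = FALSE)

config <- simulation_config(seed = 1L)
study <- simulate_study(config)
sim <- study$similarity
write_similarity_tsv(sim, "results/similarity/similarity.tsv")

cat(sprintf("similarity records: %d (%d participants x 3 ROIs x 3 valences x 28 pairs)\n",
            nrow(sim), length(unique(sim$participant_id))))
cat(sprintf("missing records: %d\n", sum(is.na(sim$z))))

cell_means <- aggregate(z ~ age_group + roi, sim, mean)
cat("\nmean Fisher-Z similarity by age group and ROI:\n")
print(cell_means, row.names = FALSE, digits = 3)
cat("\nmean Fisher-Z similarity by age group and valence:\n")
print(aggregate(z ~ age_group + valence, sim, mean), row.names = FALSE,
      digits = 3)
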