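# Small configurations used across test files. Voxel counts are reduced and
# participant heterogeneity is off unless a test is about it.

tiny_config <- function(...) {
  simulation_config(n_children = 3, n_adults = 2,
                    rois = c(AMY = 8, NAcc = 6, vmPFC = 5),
                    participant_sd = 0, ...)
}

small_study_config <- function(...) {
  simulation_config(rois = c(AMY = 24, NAcc = 24, vmPFC = 24), ...)
}

tiny_geometry <- function() {
  volume_geometry(c(9, 9, 5), c(2, 2, 2), origin_mm = c(-8, -8, -4))
}

# Directly constructed similarity table with controllable cell means and
# noise, for unit-testing the inferential layer in isolation.
make_similarity_table <- function(n_child = 6, n_adult = 4, n_pairs = 10,
                                  cell_mean = function(grp, roi, val) 0,
                                  participant_sd = 0, noise_sd = 0.1,
                                  seed = 1) {
  set.seed(seed)
  ids <- c(sprintf("child_%02d", seq_len(n_child)),
           sprintf("adult_%02d", seq_len(n_adult)))
  grps <- rep(c("child", "adult"), c(n_child, n_adult))
  ages <- c(sample(48:131, n_child, replace = TRUE),
            sample(240:528, n_adult, replace = TRUE))
  rows <- list()
  for (p in seq_along(ids)) {
    u <- rnorm(1, 0, participant_sd)
    for (roi in c("AMY", "NAcc", "vmPFC")) {
      for (val in c("positive", "negative", "neutral")) {
        mu <- cell_mean(grps[p], roi, val)
        rows[[length(rows) + 1]] <- data.frame(
          participant_id = ids[p], age_group = grps[p],
          age_months = ages[p], roi = roi, valence = val,
          clip_a = sprintf("a%02d", seq_len(n_pairs)),
          clip_b = sprintf("b%02d", seq_len(n_pairs)),
          rho = NA_real_,
          z = mu + u + rnorm(n_pairs, 0, noise_sd),
          n_voxels_used = 20L, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
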