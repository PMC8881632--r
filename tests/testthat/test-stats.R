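test_that("mixed ANOVA df bookkeeping holds on complete balanced designs", {
  tab <- make_similarity_table(n_child = 6, n_adult = 4, n_pairs = 10)
  a <- mixed_anova(tab)
  n_obs <- nrow(tab)
  n_part <- 10
  within_resid <- a$df[a$stratum == "within" & a$effect == "Residuals"]
  between_resid <- a$df[a$stratum == "participant" & a$effect == "Residuals"]
  expect_equal(within_resid, n_obs - n_part - 16)
  expect_equal(between_resid, n_part - 2)
  # all stratum dfs plus the grand mean account for every observation
  expect_equal(sum(a$df) + 1, n_obs)
  expect_true(all(a$sum_sq >= -1e-12))
  # age is tested in the participant stratum, within effects in the other
  expect_equal(a$stratum[a$effect == "age_group"], "participant")
  expect_true(all(a$stratum[grepl("roi|valence", a$effect)] == "within"))
})

test_that("a constant response yields zero effect sums of squares", {
  tab <- make_similarity_table(noise_sd = 0,
                               cell_mean = function(g, r, v) 0.3)
  a <- mixed_anova(tab)
  expect_true(all(abs(a$sum_sq[a$effect != "Residuals"]) < 1e-20))
})

test_that("a planted ROI main effect dominates the within-stratum F values", {
  wins <- 0
  for (rep in 1:30) {
    tab <- make_similarity_table(
      n_child = 5, n_adult = 5, n_pairs = 6,
      cell_mean = function(g, r, v) c(AMY = 0, NAcc = 0.08, vmPFC = 0.16)[[r]],
      noise_sd = 0.15, seed = 100 + rep)
    a <- mixed_anova(tab)
    w <- a[a$stratum == "within" & a$effect != "Residuals", ]
    if (which.max(w$F) == which(w$effect == "roi")) wins <- wins + 1
  }
  expect_gte(wins, 29)
})

test_that("missing cells error with the offending cell named, or drop on request", {
  tab <- make_similarity_table()
  cut <- !(tab$participant_id == "child_01" & tab$roi == "AMY" &
             tab$valence == "negative")
  expect_error(mixed_anova(tab[cut, ]), "child_01.*AMY\\.negative")
  a <- suppressMessages(mixed_anova(tab[cut, ], on_missing_cell = "drop"))
  expect_equal(a$df[a$stratum == "participant" & a$effect == "Residuals"], 7)
  # one age group only cannot be analysed
  expect_error(mixed_anova(tab[tab$age_group == "child", ]), "both levels")
})

test_that("bonferroni adjustment caps at one and keeps p_adj >= p", {
  tab <- make_similarity_table(seed = 5)
  fams <- default_contrast_families()
  for (fam in fams) {
    ct <- bonferroni_contrasts(tab, fam)
    expect_true(all(ct$p_adjusted >= ct$p))
    expect_true(all(ct$p_adjusted <= 1))
    expect_equal(ct$p_adjusted, pmin(1, length(fam) * ct$p))
  }
  one <- bonferroni_contrasts(tab, fams$roi_by_age[1], m = 1)
  expect_equal(one$p_adjusted, one$p) # equality only when m = 1
  nine <- bonferroni_contrasts(tab, fams$roi_by_age[1], m = 9)
  expect_equal(nine$p_adjusted, min(1, 9 * nine$p))
})

test_that("contrast t statistics match two-sample oracles", {
  tab <- make_similarity_table(
    seed = 9, cell_mean = function(g, r, v) ifelse(g == "child", 0.2, 0.1))
  fam <- list(list(label = "vmPFC, child vs adult",
                   side_a = data.frame(age_group = "child", roi = "vmPFC"),
                   side_b = data.frame(age_group = "adult", roi = "vmPFC")))
  za <- tab$z[tab$age_group == "child" & tab$roi == "vmPFC"]
  zb <- tab$z[tab$age_group == "adult" & tab$roi == "vmPFC"]
  # pooled-variance route vs a hand-computed pooled-error oracle
  ct <- bonferroni_contrasts(tab, fam, se_method = "pooled")
  expect_equal(ct$t, oracle_pooled_t(za, zb), tolerance = 1e-12)
  expect_equal(ct$df, length(za) + length(zb) - 2)
  # Welch route vs the reference implementation
  ctw <- bonferroni_contrasts(tab, fam, se_method = "welch")
  ref <- t.test(za, zb)
  expect_equal(ctw$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ctw$df, unname(ref$parameter), tolerance = 1e-9)
  expect_equal(ctw$p, ref$p.value, tolerance = 1e-12)
  expect_equal(ctw$mean_difference, mean(za) - mean(zb))
  # referencing an absent cell errors
  bad <- list(list(label = "missing",
                   side_a = data.frame(age_group = "child", roi = "nope"),
                   side_b = data.frame(age_group = "adult", roi = "vmPFC")))
  expect_error(bonferroni_contrasts(tab, bad), "no records")
})

test_that("interaction contrasts pool the crossed cells", {
  tab <- make_similarity_table(seed = 11)
  fam <- default_contrast_families()$roi_interaction[2] # AMY / vmPFC
  ct <- bonferroni_contrasts(tab, fam)
  ia <- (tab$age_group == "child" & tab$roi == "AMY") |
    (tab$age_group == "adult" & tab$roi == "vmPFC")
  ib <- (tab$age_group == "adult" & tab$roi == "AMY") |
    (tab$age_group == "child" & tab$roi == "vmPFC")
  expect_equal(ct$mean_difference, mean(tab$z[ia]) - mean(tab$z[ib]))
})

test_that("the multilevel ICC recovers planted variance ratios", {
  # planted between/within variances
  tab <- make_similarity_table(n_child = 40, n_adult = 2, n_pairs = 30,
                               participant_sd = 0.2, noise_sd = 0.4,
                               seed = 77)
  ml <- age_multilevel(tab)
  expect_equal(ml$icc, 0.2^2 / (0.2^2 + 0.4^2), tolerance = 0.35)
  expect_false(ml$singular)
  # zero between-participant variance: ICC near zero
  tab0 <- make_similarity_table(n_child = 30, n_adult = 2, n_pairs = 30,
                                participant_sd = 0, noise_sd = 0.4,
                                seed = 78)
  ml0 <- age_multilevel(tab0)
  expect_lt(ml0$icc, 0.02)
  expect_error(age_multilevel(tab[tab$participant_id %in%
                                    c("child_01", "child_02"), ]),
               "at least 3")
})

test_that("krippendorff alpha matches brute-force coincidence oracles", {
  # perfect agreement: 3 raters x 24 items
  perfect <- matrix(rep(rep(c("positive", "negative", "neutral"), 8), 3),
                    ncol = 3)
  expect_equal(krippendorff_alpha(perfect), 1)
  # toy 2-rater x 4-item nominal matrix
  toy <- cbind(r1 = c("a", "a", "b", "b"), r2 = c("a", "b", "b", "b"))
  expect_equal(krippendorff_alpha(toy), oracle_krippendorff(toy))
  # randomized instances, with and without missingness
  set.seed(55)
  for (i in 1:100) {
    n_items <- sample(4:15, 1)
    n_raters <- sample(2:5, 1)
    m <- matrix(sample(c("pos", "neg", "neu"), n_items * n_raters,
                       replace = TRUE), n_items, n_raters)
    if (runif(1) < 0.5) m[sample(length(m), n_items %/% 2)] <- NA
    if (all(rowSums(!is.na(m)) < 2)) next
    expect_equal(krippendorff_alpha(m), oracle_krippendorff(m),
                 tolerance = 1e-12)
  }
  # an entirely missing rater column leaves alpha unchanged
  m <- matrix(sample(c("pos", "neg", "neu"), 36, replace = TRUE), 12, 3)
  m_aug <- cbind(m, NA)
  expect_equal(krippendorff_alpha(m_aug), krippendorff_alpha(m))
  expect_error(krippendorff_alpha(m[, 1, drop = FALSE]), "2 raters")
  expect_error(krippendorff_alpha(matrix(c("a", NA, NA, "b"), 2, 2)),
               "pairable")
})

test_that("simulated ratings land near the emulated inter-rater agreement", {
  cfg <- simulation_config()
  sch <- generate_schedule(cfg, 2)
  alphas <- vapply(1:30, function(s) {
    krippendorff_alpha(generate_ratings(sch, seed = s))
  }, numeric(1))
  expect_gt(mean(alphas), 0.8)
  expect_lt(mean(alphas), 0.98)
})
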