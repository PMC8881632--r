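test_that("the study design yields 28 inter-movie pairs per valence", {
  cfg <- simulation_config()
  sch <- generate_schedule(cfg, 1)
  pairs <- valid_pairs(sch)
  expect_equal(as.integer(table(pairs$valence)[c("positive", "negative",
                                                 "neutral")]),
               rep(28L, 3))
  expect_false(any(pairs$clip_a == pairs$clip_b))
})

test_that("same-film pairs are excluded and shared-film counts match enumeration", {
  # two same-valence clips from one film: nothing to compare
  two <- data.frame(clip_id = c("a", "b"), film_id = c("f", "f"),
                    valence = c("positive", "positive"))
  expect_equal(nrow(valid_pairs(two)), 0)
  # 4 same-valence clips from 3 films (one film contributes two): C(4,2) - 1
  four <- data.frame(clip_id = letters[1:4],
                     film_id = c("f1", "f1", "f2", "f3"),
                     valence = "negative")
  expect_equal(nrow(valid_pairs(four)), 5)
  # random configurations vs brute-force enumeration with the film filter
  set.seed(21)
  for (i in 1:100) {
    n <- sample(2:12, 1)
    clips <- data.frame(
      clip_id = sprintf("c%02d", 1:n),
      film_id = sprintf("f%d", sample.int(max(2, n %/% 2), n, replace = TRUE)),
      valence = sample(c("positive", "negative", "neutral"), n,
                       replace = TRUE))
    expect_equal(nrow(valid_pairs(clips)), oracle_pairs(clips))
  }
})

test_that("distinct-film same-valence pair count is v(v-1)/2", {
  for (v in c(2, 5, 8)) {
    clips <- data.frame(clip_id = sprintf("c%d", 1:v),
                        film_id = sprintf("f%d", 1:v), valence = "positive")
    expect_equal(nrow(valid_pairs(clips)), v * (v - 1) / 2)
  }
})

test_that("spearman similarity matches brute-force midrank oracles", {
  expect_equal(spearman_similarity(1:10, 1:10)$rho, 1)
  expect_equal(spearman_similarity(1:10, 10:1)$rho, -1)
  s <- spearman_similarity(c(1, 2, 2, 4), c(2, 1, 3, 4))
  expect_equal(s$rho, oracle_spearman(c(1, 2, 2, 4), c(2, 1, 3, 4)))
  set.seed(33)
  for (i in 1:100) {
    n <- sample(4:40, 1)
    x <- sample(1:8, n, replace = TRUE) + rnorm(n, sd = 0.01)
    y <- sample(1:8, n, replace = TRUE)
    if (runif(1) < 0.5) x[sample(n, 2)] <- NA # pairwise-complete path
    s <- spearman_similarity(x, y)
    expect_equal(s$rho, oracle_spearman(x, y), tolerance = 1e-12)
    expect_equal(s$n_used, sum(is.finite(x) & is.finite(y)))
    # cross-check against the reference implementation
    expect_equal(s$rho,
                 suppressWarnings(cor(x, y, method = "spearman",
                                      use = "pairwise.complete.obs")),
                 tolerance = 1e-12)
  }
})

test_that("degenerate similarity yields missing values with a warning", {
  expect_warning(s <- spearman_similarity(c(1, 2, NA, NA), c(1, NA, 2, 3)),
                 "fewer than 3")
  expect_true(is.na(s$rho))
  expect_warning(s <- spearman_similarity(rep(1, 5), 1:5), "zero rank")
  expect_true(is.na(s$rho))
})

test_that("similarity is symmetric and invariant to monotone transforms", {
  set.seed(13)
  for (i in 1:20) {
    x <- rnorm(15)
    y <- rnorm(15)
    expect_equal(spearman_similarity(x, y)$rho,
                 spearman_similarity(y, x)$rho)
    expect_equal(spearman_similarity(exp(3 * x) + 2, y)$rho,
                 spearman_similarity(x, y)$rho, tolerance = 1e-12)
  }
})

test_that("fisher z matches the closed form, is odd, and clamps at the ends", {
  expect_equal(fisher_z(0), 0)
  set.seed(3)
  for (r in c(runif(50, -0.999, 0.999))) {
    expect_equal(fisher_z(r), oracle_fisher_z(r), tolerance = 1e-10)
    expect_equal(fisher_z(-r), -fisher_z(r))
  }
  expect_equal(fisher_z(0.5), oracle_fisher_z(0.5))
  expect_true(is.finite(fisher_z(1)))
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_error(fisher_z(1.2), "outside")
  expect_true(is.na(fisher_z(NA)))
})

test_that("the similarity table has the design-determined shape and labels", {
  cfg <- tiny_config()
  sch <- generate_schedule(cfg, 10)
  pat <- generate_patterns(cfg, sch, seed = 10)
  sim <- build_similarity_table(pat, sch)
  expect_equal(nrow(sim), 5 * 3 * 3 * 28) # participants x ROIs x valences x pairs
  counts <- table(sim$participant_id, sim$roi, sim$valence)
  expect_true(all(counts == 28))
  expect_true(all(table(sim$participant_id, sim$roi) == 84))
  expect_true(all(table(sim$participant_id) == 252))
  # grouping labels come from the roster
  roster <- pat$participants
  m <- merge(unique(sim[, c("participant_id", "age_group", "age_months")]),
             roster[, c("participant_id", "age_group", "age_months")],
             by = "participant_id")
  expect_equal(m$age_group.x, m$age_group.y)
  expect_equal(m$age_months.x, m$age_months.y)
})

test_that("the table is invariant to clip column order and flags missing clips", {
  cfg <- tiny_config()
  sch <- generate_schedule(cfg, 14)
  pat <- generate_patterns(cfg, sch, seed = 14)
  sim0 <- build_similarity_table(pat, sch)
  perm <- pat
  for (pid in names(perm$patterns)) {
    for (roi in names(perm$patterns[[pid]])) {
      mat <- perm$patterns[[pid]][[roi]]
      perm$patterns[[pid]][[roi]] <- mat[, sample(ncol(mat))]
    }
  }
  sim1 <- build_similarity_table(perm, sch)
  expect_equal(sim0, sim1)
  # a dropped clip pattern flags its pairs as missing, not silently dropped
  drop1 <- pat
  drop1$patterns[["child_01"]][["AMY"]] <-
    drop1$patterns[["child_01"]][["AMY"]][, -1, drop = FALSE]
  gone <- colnames(pat$patterns[["child_01"]][["AMY"]])[1]
  sim2 <- build_similarity_table(drop1, sch)
  expect_equal(nrow(sim2), nrow(sim0))
  aff <- sim2$participant_id == "child_01" & sim2$roi == "AMY" &
    (sim2$clip_a == gone | sim2$clip_b == gone)
  expect_true(all(is.na(sim2$rho[aff])))
  expect_false(anyNA(sim2$rho[sim2$participant_id == "child_01" &
                                sim2$roi == "AMY" & !aff]))
})

test_that("the fast complete-data path equals the per-pair path", {
  cfg <- tiny_config()
  sch <- generate_schedule(cfg, 15)
  pat <- generate_patterns(cfg, sch, seed = 15)
  sim_fast <- build_similarity_table(pat, sch)
  mat <- pat$patterns[["child_02"]][["NAcc"]]
  pairs <- valid_pairs(sch)
  for (r in sample(nrow(pairs), 20)) {
    s <- spearman_similarity(mat[, pairs$clip_a[r]], mat[, pairs$clip_b[r]])
    row <- sim_fast[sim_fast$participant_id == "child_02" &
                      sim_fast$roi == "NAcc" &
                      sim_fast$clip_a == pairs$clip_a[r] &
                      sim_fast$clip_b == pairs$clip_b[r], ]
    expect_equal(row$rho, s$rho, tolerance = 1e-12)
  }
})

test_that("similarity tables round-trip through TSV", {
  cfg <- tiny_config()
  sch <- generate_schedule(cfg, 16)
  sim <- build_similarity_table(generate_patterns(cfg, sch, seed = 16), sch)
  path <- tempfile(fileext = ".tsv")
  write_similarity_tsv(sim, path)
  back <- read_similarity_tsv(path)
  expect_equal(back$rho, sim$rho, tolerance = 1e-12)
  expect_equal(back$clip_a, sim$clip_a)
  unlink(path)
})
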