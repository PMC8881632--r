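test_that("unconvolved task columns are boxcars over the clip volumes", {
  sch <- data.frame(order_id = 1, clip_id = "clip_a", film_id = "f1",
                    valence = "positive", onset_s = 10, duration_s = 20)
  d <- build_design(sch, tr_s = 2, n_volumes = 30, hrf = NULL)
  col <- d$X[, "clip_a"]
  expect_equal(which(col == 1), 6:15) # volumes at t = 10..28 s
  expect_true(all(col %in% c(0, 1)))
})

test_that("the full 24-clip design has 24 non-overlapping task columns", {
  cfg <- simulation_config()
  sch <- generate_schedule(cfg, 8)
  one <- sch[sch$order_id == 1, ]
  d <- build_design(one, cfg$tr_s, cfg$n_volumes, hrf = NULL)
  expect_length(d$task_cols, 24)
  boxes <- d$X[, d$task_cols]
  expect_true(all(rowSums(boxes) <= 1)) # pairwise overlap zero
})

test_that("convolved columns equal the direct convolution oracle", {
  tr <- 2
  oversample <- 16
  dt <- tr / oversample
  n_vol <- 60
  sch <- data.frame(order_id = 1, clip_id = "c1", film_id = "f",
                    valence = "neutral", onset_s = 8, duration_s = 24)
  d <- build_design(sch, tr_s = tr, n_volumes = n_vol)
  # direct discrete convolution on the same fine grid, then decimation
  tfine <- (seq_len(n_vol * oversample) - 1) * dt
  box <- as.numeric(tfine >= 8 & tfine < 32)
  kern <- hrf_double_gamma(seq(0, 32, by = dt))
  direct <- oracle_convolve(box, kern) * dt
  expect_equal(d$X[, "c1"], direct[seq(1, length(tfine), by = oversample)],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("rank-deficient designs error with the collinear columns named", {
  sch <- data.frame(order_id = 1, clip_id = "c1", film_id = "f",
                    valence = "neutral", onset_s = 4, duration_s = 10)
  conf <- matrix(1, nrow = 30, ncol = 1, dimnames = list(NULL, "ones"))
  expect_error(build_design(sch, 2, 30, confounds = conf),
               "rank deficient.*(ones|intercept)")
})

test_that("high-pass filtering removes slow components and keeps fast ones", {
  tr <- 2
  n <- 510
  t_s <- (0:(n - 1)) * tr
  expect_equal(highpass(rep(5, n), 100, tr), rep(0, n))
  slow <- sin(2 * pi * t_s / 500) # period 500 s >> 100 s cutoff
  amp <- function(x, period) {
    2 * abs(mean(x * exp(-2i * pi * t_s / period)))
  }
  filtered <- highpass(slow, 100, tr)
  expect_lt(amp(filtered, 500), 0.1 * amp(slow, 500)) # > 90% attenuation
  fast <- sin(2 * pi * t_s / 20) # period 20 s << 100 s cutoff
  expect_gt(amp(highpass(fast, 100, tr), 20), 0.95 * amp(fast, 20))
  expect_error(highpass(fast, 3.9, tr), "twice the TR")
})

test_that("OLS recovers exact and oracle solutions", {
  set.seed(5)
  X <- cbind(task = rep(c(0, 1), each = 10), intercept = 1)
  Y <- 2 * X[, "task"] + 5
  b <- fit_glm(matrix(Y), X)
  expect_equal(unname(b["task", 1]), 2)
  # random small instances vs the normal-equation oracle
  for (i in 1:100) {
    X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
    Y <- matrix(rnorm(20), 10, 2)
    expect_equal(unname(fit_glm(Y, X)), unname(oracle_ols(X, Y)),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # residual orthogonality
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("x", 1:4)))
  Y <- matrix(rnorm(100), 50, 2)
  b <- fit_glm(Y, X)
  expect_lt(max(abs(crossprod(X, attr(b, "residuals")))), 1e-9)
  Yna <- Y; Yna[3, 2] <- NA
  expect_error(fit_glm(Yna, X), "voxel indices: 2")
})

test_that("noiseless simulated BOLD returns the planted betas exactly", {
  cfg <- tiny_config(noise_sd = 0)
  sch <- generate_schedule(cfg, 6)
  pat <- generate_patterns(cfg, sch, seed = 6)
  run <- generate_bold(pat, "adult_01", sch, cfg, seed = 6, drift = TRUE)
  est <- estimate_patterns(run, sch, cfg)
  for (roi in names(est)) {
    planted <- pat$patterns[["adult_01"]][[roi]][, colnames(est[[roi]])]
    expect_equal(est[[roi]], planted, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("nuisance columns orthogonal to the task leave task betas unchanged", {
  cfg <- tiny_config(noise_sd = 0.5)
  sch <- generate_schedule(cfg, 9)
  one <- sch[sch$order_id == 1, ]
  d0 <- build_design(one, cfg$tr_s, cfg$n_volumes)
  set.seed(1)
  Y <- matrix(rnorm(cfg$n_volumes * 3), ncol = 3)
  b0 <- fit_glm(Y, d0)
  # orthogonalise a random confound against the current design
  raw <- rnorm(cfg$n_volumes)
  ortho <- raw - d0$X %*% solve(crossprod(d0$X), crossprod(d0$X, raw))
  d1 <- build_design(one, cfg$tr_s, cfg$n_volumes,
                     confounds = cbind(ortho = ortho))
  b1 <- fit_glm(Y, d1)
  expect_equal(b0, b1, tolerance = 1e-8, ignore_attr = TRUE)
})
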