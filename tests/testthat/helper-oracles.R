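# Independent brute-force oracles, kept deliberately naive and separate from
# the package's implementation paths.

# Midranks by counting: rank_i = 1 + #{j: x_j < x_i} + (#{j != i: x_j = x_i}) / 2
oracle_midranks <- function(x) {
  vapply(seq_along(x), function(i) {
    1 + sum(x < x[i]) + (sum(x == x[i]) - 1) / 2
  }, numeric(1))
}

# Pearson correlation from explicit sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Spearman with midranks on pairwise-complete positions
oracle_spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  oracle_pearson(oracle_midranks(x[ok]), oracle_midranks(y[ok]))
}

# Fisher Z via the closed logarithm form
oracle_fisher_z <- function(r) 0.5 * log((1 + r) / (1 - r))

# Type-7 quantile by direct linear interpolation of sorted order statistics
oracle_quantile7 <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_boxplot_threshold <- function(x) {
  q1 <- oracle_quantile7(x, 0.25)
  q3 <- oracle_quantile7(x, 0.75)
  q3 + 1.5 * (q3 - q1)
}

# OLS via the normal equations
oracle_ols <- function(X, Y) solve(t(X) %*% X) %*% t(X) %*% Y

# Krippendorff's alpha by direct enumeration of within-item pairs
oracle_krippendorff <- function(ratings) {
  ratings <- as.matrix(ratings)
  pairs_obs <- list()
  for (u in seq_len(nrow(ratings))) {
    vals <- ratings[u, !is.na(ratings[u, ])]
    m <- length(vals)
    if (m < 2) next
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (i != j) {
          pairs_obs[[length(pairs_obs) + 1]] <-
            c(vals[i], vals[j], 1 / (m - 1))
        }
      }
    }
  }
  if (!length(pairs_obs)) stop("no pairable values")
  df <- do.call(rbind, pairs_obs)
  w <- as.numeric(df[, 3])
  disagree <- sum(w[df[, 1] != df[, 2]])
  n_total <- sum(w)
  counts <- tapply(w, df[, 1], sum)
  counts <- counts + 0 # named numeric
  d_o <- disagree / n_total
  d_e <- (n_total^2 - sum(counts^2)) / (n_total * (n_total - 1))
  1 - d_o / d_e
}

# Brute-force same-valence different-film pair enumeration
oracle_pairs <- function(clips) {
  clips <- unique(clips[, c("clip_id", "film_id", "valence")])
  out <- 0
  n <- nrow(clips)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (clips$valence[i] == clips$valence[j] &&
          clips$film_id[i] != clips$film_id[j]) {
        out <- out + 1
      }
    }
  }
  out
}

# Direct discrete convolution of a boxcar with a kernel
oracle_convolve <- function(box, kern) {
  n <- length(box)
  out <- numeric(n)
  for (t in seq_len(n)) {
    for (k in seq_len(min(t, length(kern)))) {
      out[t] <- out[t] + box[t - k + 1] * kern[k]
    }
  }
  out
}

# Pooled two-sample t statistic from explicit formulas
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}
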