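#' Canonical double-gamma haemodynamic response function
#'
#' The standard difference-of-gammas impulse response: a response gamma with
#' its mode near `peak_s` minus a scaled undershoot gamma with its mode near
#' `undershoot_s`, normalised to unit peak.
#'
#' @param t Time points in seconds (>= 0; negative times return 0).
#' @param peak_s,undershoot_s Delays of the response and undershoot lobes.
#' @param ratio Undershoot amplitude relative to the response.
#' @return Numeric vector of HRF values at `t`.
#' @export
hrf_double_gamma <- function(t, peak_s = 6, undershoot_s = 16, ratio = 1 / 6) {
  h <- dgamma(t, shape = peak_s, scale = 1) -
    ratio * dgamma(t, shape = undershoot_s, scale = 1)
  h[t < 0] <- 0
  h / max(h)
}

# HRF-convolved regressor for one event, sampled at volume times.
# Oversamples the boxcar on a fine grid, convolves, reads off at t = v * tr.
# The identity kernel (hrf = NULL) returns the boxcar itself.
convolve_event <- function(onset_s, duration_s, tr_s, n_volumes,
                           hrf = hrf_double_gamma, oversample = 16L) {
  dt <- tr_s / oversample
  n_fine <- n_volumes * oversample
  tfine <- (seq_len(n_fine) - 1) * dt
  box <- as.numeric(tfine >= onset_s & tfine < onset_s + duration_s)
  if (is.null(hrf)) {
    sig <- box
  } else {
    kern <- hrf(seq(0, 32, by = dt))
    sig <- convolve(box, rev(kern), type = "open")[seq_len(n_fine)] * dt
  }
  sig[seq(1, n_fine, by = oversample)]
}

#' Build a per-participant design matrix
#'
#' Assembles 24 task regressors (one HRF-convolved boxcar per clip, in the
#' participant's presentation order), an optional nuisance block (white
#' matter and CSF series, six motion parameters, their first derivatives,
#' spike columns) and an intercept.
#'
#' @param schedule One order's rows of a `clip_schedule` (clip onsets and
#'   durations must fit inside the run).
#' @param tr_s Repetition time (s).
#' @param n_volumes Number of volumes.
#' @param confounds Optional numeric matrix of nuisance columns
#'   (`n_volumes` rows).
#' @param hrf HRF function of time in seconds, or `NULL` for an identity
#'   kernel (unconvolved boxcars).
#' @return List of class `design_matrix` with `X` (the full matrix), and
#'   `task_cols` (names of the clip columns).
#' @export
build_design <- function(schedule, tr_s, n_volumes, confounds = NULL,
                         hrf = hrf_double_gamma) {
  s <- schedule[order(schedule$onset_s), ]
  if (length(unique(s$order_id)) != 1) {
    stop("pass a single order's schedule rows to build_design()")
  }
  run_s <- n_volumes * tr_s
  over <- s$onset_s + s$duration_s > run_s
  if (any(over)) {
    stop("clips extend past the end of the run: ",
         paste(s$clip_id[over], collapse = ", "))
  }
  task <- vapply(seq_len(nrow(s)), function(i) {
    convolve_event(s$onset_s[i], s$duration_s[i], tr_s, n_volumes, hrf = hrf)
  }, numeric(n_volumes))
  colnames(task) <- s$clip_id
  X <- task
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    stopifnot(nrow(confounds) == n_volumes)
    if (is.null(colnames(confounds))) {
      colnames(confounds) <- sprintf("confound_%02d", seq_len(ncol(confounds)))
    }
    X <- cbind(X, confounds)
  }
  X <- cbind(X, intercept = 1)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  structure(list(X = X, task_cols = colnames(task)),
            class = "design_matrix")
}

#' High-pass filter timeseries by discrete cosine projection
#'
#' Removes the mean, a linear trend, and all discrete cosine basis
#' components with period longer than `cutoff_s`, the standard fMRI
#' drift-removal basis. Exactly annihilates any drift lying in that span
#' and passes faster components essentially unchanged.
#'
#' @param x Numeric vector or matrix (timepoints in rows).
#' @param cutoff_s High-pass cutoff period in seconds (must exceed
#'   `2 * tr_s`).
#' @param tr_s Sampling interval in seconds.
#' @return Filtered data with the same shape as `x`.
#' @export
highpass <- function(x, cutoff_s, tr_s) {
  if (cutoff_s <= 2 * tr_s) {
    stop(sprintf("cutoff (%.1f s) must exceed twice the TR (%.1f s)",
                 cutoff_s, 2 * tr_s))
  }
  x <- as.matrix(x)
  n <- nrow(x)
  lin <- seq_len(n) - (n + 1) / 2
  basis <- cbind(lin / sqrt(sum(lin^2)), dct_drift_basis(n, tr_s, cutoff_s))
  basis <- qr.Q(qr(basis)) # orthonormalise linear against the cosine set
  centered <- sweep(x, 2, colMeans(x))
  centered <- centered - basis %*% crossprod(basis, centered)
  drop(centered)
}

# Orthonormal DCT-II drift columns with period > cutoff_s (excluding the
# constant, handled by mean removal).
dct_drift_basis <- function(n, tr_s, cutoff_s) {
  k_max <- floor(2 * n * tr_s / cutoff_s)
  if (k_max < 1) return(matrix(0, n, 0))
  t_idx <- seq_len(n) - 0.5
  basis <- vapply(seq_len(k_max), function(k) {
    b <- cos(pi * k * t_idx / n)
    b / sqrt(sum(b^2))
  }, numeric(n))
  matrix(basis, nrow = n)
}

#' Ordinary least-squares fit of voxel timeseries on a design
#'
#' Fits every voxel column of `Y` against the same design matrix and returns
#' the coefficients of the task (clip) columns — the per-clip beta pattern.
#'
#' @param Y `n_volumes x n_voxels` matrix of voxel timeseries.
#' @param design A [build_design()] result, or a plain numeric matrix (then
#'   all columns are treated as task columns).
#' @return `n_task_columns x n_voxels` matrix of beta estimates (rows named
#'   by clip). Attribute `residuals` carries the residual matrix.
#' @export
fit_glm <- function(Y, design) {
  Y <- as.matrix(Y)
  bad <- which(!apply(is.finite(Y), 2, all))
  if (length(bad)) {
    stop("non-finite values in voxel timeseries at voxel indices: ",
         paste(bad, collapse = ", "))
  }
  if (inherits(design, "design_matrix")) {
    X <- design$X
    task_cols <- design$task_cols
  } else {
    X <- as.matrix(design)
    if (is.null(colnames(X))) {
      colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
    }
    task_cols <- colnames(X)
  }
  if (nrow(X) != nrow(Y)) {
    stop(sprintf("design has %d rows but timeseries has %d",
                 nrow(X), nrow(Y)))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient")
  coefs <- qr.coef(qrX, Y)
  betas <- coefs[task_cols, , drop = FALSE]
  attr(betas, "residuals") <- Y - X %*% coefs
  betas
}
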