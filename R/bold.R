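#' Simulate a participant's BOLD run from planted patterns
#'
#' Builds each ROI voxel's timeseries as the sum over clips of the voxel's
#' planted beta times the HRF-convolved boxcar for that clip (the same
#' regressor construction used by [build_design()], so a noiseless run is an
#' exact linear model), plus optional slow drift and Gaussian scanner noise,
#' together with simulated motion and white-matter / CSF nuisance series.
#'
#' Drift is drawn from the discrete-cosine components with period longer
#' than the configured high-pass cutoff, so the [highpass()] stage removes
#' it exactly.
#'
#' @param patterns `roi_patterns` from [generate_patterns()].
#' @param participant_id Which participant's run to simulate.
#' @param schedule Full `clip_schedule`; the participant's assigned order is
#'   used.
#' @param config The [simulation_config()].
#' @param seed Integer seed.
#' @param noise_sd Scanner noise sd; defaults to `config$noise_sd`.
#' @param drift Logical: add slow drift?
#' @param spike_volumes Volumes at which to inject motion spikes.
#' @return List of class `bold_run`: `bold` (named list of
#'   `n_volumes x n_voxels` matrices, one per ROI), `motion`
#'   (a [simulate_motion()] result), `wm`, `csf` (nuisance series),
#'   `order_id`, `participant_id`.
#' @export
generate_bold <- function(patterns, participant_id, schedule, config,
                          seed = config$seed, noise_sd = config$noise_sd,
                          drift = TRUE, spike_volumes = integer()) {
  stopifnot(inherits(patterns, "roi_patterns"))
  p_row <- patterns$participants[
    patterns$participants$participant_id == participant_id, ]
  if (nrow(p_row) != 1) stop("unknown participant: ", participant_id)
  sched <- schedule[schedule$order_id == p_row$order_id, ]
  sched <- sched[order(sched$onset_s), ]
  pat <- patterns$patterns[[participant_id]]
  missing_clips <- setdiff(sched$clip_id, colnames(pat[[1]]))
  if (length(missing_clips)) {
    stop("patterns do not cover all scheduled clips; missing: ",
         paste(missing_clips, collapse = ", "))
  }
  n <- config$n_volumes
  regressors <- vapply(seq_len(nrow(sched)), function(i) {
    convolve_event(sched$onset_s[i], sched$duration_s[i], config$tr_s, n)
  }, numeric(n))
  colnames(regressors) <- sched$clip_id
  p_index <- which(patterns$participants$participant_id == participant_id)
  run_seed <- derive_seed(seed, 100L + p_index)
  with_seed(run_seed, {
    bold <- lapply(names(pat), function(roi) {
      betas <- pat[[roi]][, sched$clip_id, drop = FALSE] # voxels x clips
      signal <- regressors %*% t(betas)                  # volumes x voxels
      v_count <- ncol(signal)
      if (drift) {
        basis <- dct_drift_basis(n, config$tr_s, config$highpass_cutoff_s)
        if (ncol(basis) > 0) {
          coefs <- matrix(rnorm(ncol(basis) * v_count, sd = 2),
                          ncol = v_count)
          signal <- signal + basis %*% coefs
        }
        signal <- signal + outer(seq_len(n) / n,
                                 rnorm(v_count, sd = 0.5))
      }
      if (noise_sd > 0) {
        signal <- signal + matrix(rnorm(n * v_count, sd = noise_sd),
                                  nrow = n)
      }
      signal
    })
    names(bold) <- names(pat)
    motion <- simulate_motion(n, seed = derive_seed(run_seed, 7L),
                              spike_volumes = spike_volumes)
    wm <- rnorm(n, sd = 0.3)
    csf <- rnorm(n, sd = 0.3)
    structure(list(bold = bold, motion = motion, wm = wm, csf = csf,
                   order_id = p_row$order_id,
                   participant_id = participant_id),
              class = "bold_run")
  })
}

#' Nuisance confound matrix for a simulated run
#'
#' Assembles the standard nuisance block: white matter and CSF series, six
#' motion parameters, their first differences, and one spike column per
#' flagged outlier volume.
#'
#' @param run A `bold_run` from [generate_bold()].
#' @return Numeric matrix with `n_volumes` rows.
#' @export
run_confounds <- function(run) {
  mp <- cbind(run$motion$translations, run$motion$rotations)
  colnames(mp) <- c(sprintf("trans_%s", c("x", "y", "z")),
                    sprintf("rot_%s", c("x", "y", "z")))
  dmp <- rbind(0, diff(mp))
  colnames(dmp) <- paste0("d_", colnames(mp))
  spikes <- spike_regressors(flag_outliers(run$motion$metric))
  cbind(wm = run$wm, csf = run$csf, mp, dmp, spikes)
}

#' Estimate per-clip ROI beta patterns from a simulated run
#'
#' The participant-level estimation stage: high-pass filters data and design
#' (task and continuous nuisance columns alike), fits the 24-regressor GLM
#' per voxel by ordinary least squares, and returns one beta vector per clip
#' per ROI — the estimated counterpart of the planted patterns.
#'
#' @param run A `bold_run`.
#' @param schedule Full `clip_schedule`.
#' @param config The [simulation_config()].
#' @param confounds Nuisance matrix; defaults to [run_confounds()].
#' @return Named list (per ROI) of voxels x clips beta matrices, clip
#'   columns sorted by clip id.
#' @export
estimate_patterns <- function(run, schedule, config,
                              confounds = run_confounds(run)) {
  sched <- schedule[schedule$order_id == run$order_id, ]
  design <- build_design(sched, config$tr_s, config$n_volumes,
                         confounds = confounds)
  # filter data and design identically; spike columns stay unfiltered
  spike_cols <- grepl("^spike_", colnames(design$X))
  keep <- !spike_cols & colnames(design$X) != "intercept"
  Xf <- design$X
  Xf[, keep] <- highpass(Xf[, keep, drop = FALSE],
                         config$highpass_cutoff_s, config$tr_s)
  design$X <- Xf
  lapply(run$bold, function(Y) {
    Yf <- highpass(Y, config$highpass_cutoff_s, config$tr_s)
    betas <- fit_glm(Yf, design) # task clips x voxels
    betas <- t(betas)
    betas[, order(colnames(betas)), drop = FALSE]
  })
}
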