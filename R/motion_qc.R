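#' Boxplot-rule outlier threshold for a motion metric
#'
#' Returns `Q75 + 1.5 * IQR` of the per-volume motion metric, the upper-fence
#' rule used by FSL's motion outlier tool. Quantiles use linear interpolation
#' between order statistics ([stats::quantile()] type 7), the convention this
#' package declares and tests against a brute-force oracle.
#'
#' @param metric Numeric per-volume motion series (length >= 4).
#' @return Scalar threshold; volumes strictly above it are outliers.
#' @export
outlier_threshold <- function(metric) {
  if (length(metric) < 4) {
    stop("need at least 4 volumes to estimate an outlier threshold")
  }
  q <- quantile(metric, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] + 1.5 * (q[2] - q[1])
}

#' Flag motion-outlier volumes
#'
#' @inheritParams outlier_threshold
#' @param threshold Threshold; defaults to [outlier_threshold()] of the
#'   series.
#' @return Logical vector, `TRUE` where `metric > threshold` (strict).
#' @export
flag_outliers <- function(metric, threshold = outlier_threshold(metric)) {
  metric > threshold
}

#' Spike regressors from outlier flags
#'
#' One unit indicator column per flagged volume, for inclusion in the GLM so
#' that motion-corrupted volumes are regressed out rather than deleted.
#'
#' @param flags Logical per-volume outlier flags.
#' @return `n_volumes x n_flagged` 0/1 matrix (zero columns if none flagged).
#' @export
spike_regressors <- function(flags) {
  idx <- which(flags)
  out <- matrix(0, nrow = length(flags), ncol = length(idx))
  if (length(idx)) {
    out[cbind(idx, seq_along(idx))] <- 1
    colnames(out) <- sprintf("spike_%03d", idx)
  }
  out
}

#' Participant-level motion exclusion rule
#'
#' A participant is excluded when more than 15% of volumes are motion
#' outliers, or when any of the three rotation series exceeds 1.5 (both
#' comparisons strict, so a participant at exactly the limit is kept). The
#' rotation limit is applied on the scale the series are stored in; the
#' source convention mixes rotation with mm, so the series are treated
#' agnostically.
#'
#' @param outlier_fraction Proportion of volumes flagged as outliers.
#' @param max_abs_rotation Maximum absolute value over the three rotation
#'   series.
#' @param fraction_limit,rotation_limit Exclusion limits (defaults 0.15 and
#'   1.5).
#' @return List with `keep` (logical) and `reason` (`NA` when kept, else the
#'   violated rule, outlier fraction checked first).
#' @export
exclude_participant <- function(outlier_fraction, max_abs_rotation,
                                fraction_limit = 0.15, rotation_limit = 1.5) {
  stopifnot(outlier_fraction >= 0, outlier_fraction <= 1,
            max_abs_rotation >= 0)
  if (outlier_fraction > fraction_limit) {
    return(list(keep = FALSE, reason = sprintf(
      "outlier fraction %.3f exceeds %.2f", outlier_fraction, fraction_limit)))
  }
  if (max_abs_rotation > rotation_limit) {
    return(list(keep = FALSE, reason = sprintf(
      "rotation %.3f exceeds %.2f", max_abs_rotation, rotation_limit)))
  }
  list(keep = TRUE, reason = NA_character_)
}

#' Simulate a participant's motion trace
#'
#' Produces a framewise RMS intensity-difference style metric (non-negative,
#' weakly autocorrelated) plus three translation and three rotation series,
#' with optional injected spikes emulating abrupt head movement.
#'
#' @param n_volumes Number of volumes.
#' @param seed Integer seed.
#' @param spike_volumes Integer volume indices at which to inject motion
#'   spikes.
#' @param spike_size Spike magnitude added to the metric (and, scaled, to the
#'   rotations).
#' @param baseline_sd Scale of ordinary frame-to-frame motion.
#' @return List with `metric` (length `n_volumes`), `translations` and
#'   `rotations` (`n_volumes x 3` matrices), and `spike_volumes`.
#' @export
simulate_motion <- function(n_volumes, seed = 1L, spike_volumes = integer(),
                            spike_size = 2, baseline_sd = 0.05) {
  with_seed(seed, {
    metric <- abs(baseline_sd * (rnorm(n_volumes) +
                                   0.5 * c(0, rnorm(n_volumes - 1))))
    translations <- apply(matrix(rnorm(3 * n_volumes, sd = baseline_sd),
                                 ncol = 3), 2, cumsum) / sqrt(n_volumes)
    rotations <- apply(matrix(rnorm(3 * n_volumes, sd = baseline_sd / 2),
                              ncol = 3), 2, cumsum) / sqrt(n_volumes)
    if (length(spike_volumes)) {
      stopifnot(all(spike_volumes >= 1), all(spike_volumes <= n_volumes))
      metric[spike_volumes] <- metric[spike_volumes] + spike_size
      rotations[spike_volumes, 1] <- rotations[spike_volumes, 1] +
        spike_size / 2
    }
    list(metric = metric, translations = translations, rotations = rotations,
         spike_volumes = sort(unique(as.integer(spike_volumes))))
  })
}

#' Apply motion QC across a simulated cohort
#'
#' Flags outlier volumes per participant with the boxplot rule and applies
#' the participant exclusion rule, reproducing the bookkeeping identity
#' effective N = recruited N - excluded N.
#'
#' @param motion Named list of [simulate_motion()] results, one per
#'   participant.
#' @return Data frame with one row per participant: `participant_id`,
#'   `outlier_fraction`, `max_abs_rotation`, `kept`, `reason`.
#' @export
qc_cohort <- function(motion) {
  stopifnot(is.list(motion), !is.null(names(motion)))
  rows <- lapply(names(motion), function(pid) {
    m <- motion[[pid]]
    flags <- flag_outliers(m$metric)
    frac <- mean(flags)
    rot <- max(abs(m$rotations))
    verdict <- exclude_participant(frac, rot)
    data.frame(participant_id = pid, outlier_fraction = frac,
               max_abs_rotation = rot, kept = verdict$keep,
               reason = verdict$reason, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
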