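#' Simulate the participant roster
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return Data frame with `participant_id`, `age_group`, `age_months` and
#'   the assigned counterbalancing `order_id`.
#' @export
generate_participants <- function(config, seed = config$seed) {
  n <- config$n_children + config$n_adults
  with_seed(derive_seed(seed, 11L), {
    age <- c(
      round(runif(config$n_children, config$child_age_months[1],
                  config$child_age_months[2])),
      round(runif(config$n_adults, config$adult_age_months[1],
                  config$adult_age_months[2]))
    )
    data.frame(
      participant_id = c(sprintf("child_%02d", seq_len(config$n_children)),
                         sprintf("adult_%02d", seq_len(config$n_adults))),
      age_group = rep(c("child", "adult"),
                      c(config$n_children, config$n_adults)),
      age_months = as.integer(age),
      order_id = sample(rep_len(1:3, n)),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate voxel patterns with planted within-valence similarity
#'
#' For each participant, ROI and clip, draws one voxel beta vector under the
#' mixing model `pattern = sqrt(a) * template + sqrt(1 - a) * clip_noise`,
#' where the valence template (per participant x ROI x valence) and the
#' per-clip noise are independent unit-variance Gaussian fields over voxels.
#' Under this model the expected Pearson correlation between two same-valence
#' patterns is exactly the planted `a` for that (age group, ROI, valence)
#' cell, and patterns of different valences are uncorrelated in expectation.
#'
#' Two participant-level modifiers act on `a` before mixing: a random offset
#' with sd `config$participant_sd`, shared by all of a participant's cells
#' (clustering similarity by participant), and for children an optional
#' linear age trend `config$child_age_slope` (per month, centred on the
#' child age midpoint). The effective `a` is clamped into `[0, 1]`.
#'
#' @param config A [simulation_config()]; `config$similarity` supplies `a`.
#' @param schedule A `clip_schedule` from [generate_schedule()].
#' @param participants Roster from [generate_participants()] (regenerated
#'   from `seed` if `NULL`).
#' @param seed Integer seed.
#' @return Object of class `roi_patterns`: list with `participants`,
#'   `rois`, and `patterns[[participant_id]][[roi]]`, each a voxels x 24
#'   matrix with clip ids as column names.
#' @export
generate_patterns <- function(config, schedule, participants = NULL,
                              seed = config$seed) {
  validate_config(config)
  if (is.null(participants)) {
    participants <- generate_participants(config, seed)
  }
  clips <- unique(schedule[, c("clip_id", "valence")])
  clips <- clips[order(clips$clip_id), ]
  a_lookup <- config$similarity
  key <- function(g, r, v) paste(g, r, v, sep = ".")
  a_map <- setNames(a_lookup$a,
                    key(a_lookup$age_group, a_lookup$roi, a_lookup$valence))
  with_seed(derive_seed(seed, 23L), {
    patterns <- lapply(seq_len(nrow(participants)), function(p) {
      grp <- participants$age_group[p]
      offset <- rnorm(1, 0, config$participant_sd)
      if (grp == "child" && config$child_age_slope != 0) {
        offset <- offset + config$child_age_slope *
          (participants$age_months[p] - mean(config$child_age_months))
      }
      per_roi <- lapply(names(config$rois), function(roi) {
        v_count <- config$rois[[roi]]
        templates <- matrix(rnorm(v_count * length(VALENCE_LEVELS)),
                            nrow = v_count,
                            dimnames = list(NULL, VALENCE_LEVELS))
        mat <- vapply(seq_len(nrow(clips)), function(ci) {
          a <- a_map[[key(grp, roi, clips$valence[ci])]]
          if (is.null(a) || is.na(a)) {
            stop("no planted similarity level for cell ",
                 key(grp, roi, clips$valence[ci]))
          }
          a <- min(1, max(0, a + offset))
          sqrt(a) * templates[, clips$valence[ci]] +
            sqrt(1 - a) * rnorm(v_count)
        }, numeric(v_count))
        colnames(mat) <- clips$clip_id
        mat
      })
      names(per_roi) <- names(config$rois)
      per_roi
    })
    names(patterns) <- participants$participant_id
    structure(list(participants = participants, rois = config$rois,
                   patterns = patterns),
              class = "roi_patterns")
  })
}

#' @export
print.roi_patterns <- function(x, ...) {
  cat(sprintf(
    "ROI patterns: %d participants (%d children, %d adults), %d ROIs, %d clips\n",
    nrow(x$participants), sum(x$participants$age_group == "child"),
    sum(x$participants$age_group == "adult"), length(x$rois),
    ncol(x$patterns[[1]][[1]])))
  invisible(x)
}

#' Simulate correlated same-valence pattern pairs
#'
#' A direct Monte-Carlo probe of the pattern mixing model: generates
#' `n_pairs` independent pairs of same-template patterns and returns their
#' Pearson correlations. Used to verify that the planted `a` is calibrated
#' (the empirical mean correlation converges to `a`).
#'
#' @param a Planted similarity level in `[0, 1]`.
#' @param n_voxels Voxels per pattern.
#' @param n_pairs Number of independent pairs.
#' @param seed Integer seed.
#' @return Numeric vector of `n_pairs` Pearson correlations.
#' @export
simulate_pattern_pairs <- function(a, n_voxels, n_pairs, seed = 1L) {
  stopifnot(a >= 0, a <= 1, n_voxels >= 2)
  with_seed(seed, {
    vapply(seq_len(n_pairs), function(i) {
      template <- rnorm(n_voxels)
      x <- sqrt(a) * template + sqrt(1 - a) * rnorm(n_voxels)
      y <- sqrt(a) * template + sqrt(1 - a) * rnorm(n_voxels)
      cor(x, y)
    }, numeric(1))
  })
}
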