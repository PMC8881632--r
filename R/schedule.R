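#' Planted similarity levels per age group, ROI and valence
#'
#' Builds the grid of expected within-valence pattern correlations (`a`) that
#' the generator plants into simulated voxel patterns. `a` is directly
#' interpretable: two same-valence clip patterns from the same participant and
#' ROI have expected Pearson correlation `a`.
#'
#' The default grid encodes the qualitative structure of the study this
#' package emulates: children carry more within-valence similarity than
#' adults in every ROI, the child effect is largest in vmPFC, children show a
#' negative > positive > neutral ordering, and adults are flat across both
#' ROI and valence.
#'
#' @param a Optional single value in `[0, 1]`; if supplied, every cell of the
#'   grid is set to `a` (useful for null simulations). If `NULL`, the default
#'   structured grid is returned.
#' @return A data frame with columns `age_group`, `roi`, `valence`, `a`
#'   (18 rows: 2 groups x 3 ROIs x 3 valences).
#' @examples
#' similarity_grid()       # structured default
#' similarity_grid(a = 0)  # null: no planted representational structure
#' @export
similarity_grid <- function(a = NULL) {
  g <- expand.grid(
    valence = VALENCE_LEVELS,
    roi = ROI_LEVELS,
    age_group = c("child", "adult"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("age_group", "roi", "valence")]
  if (!is.null(a)) {
    stopifnot(is.numeric(a), length(a) == 1, a >= 0, a <= 1)
    g$a <- a
    return(g)
  }
  # rows: positive, negative, neutral; children structured, adults flat
  defaults <- cbind(
    child.AMY = c(0.10, 0.15, 0.07),
    child.NAcc = c(0.09, 0.14, 0.06),
    child.vmPFC = c(0.19, 0.24, 0.16),
    adult.AMY = c(0.07, 0.07, 0.07),
    adult.NAcc = c(0.06, 0.06, 0.06),
    adult.vmPFC = c(0.08, 0.08, 0.08)
  )
  g$a <- defaults[cbind(match(g$valence, VALENCE_LEVELS),
                        match(paste(g$age_group, g$roi, sep = "."),
                              colnames(defaults)))]
  g
}

#' Planted similarity grid for parameter-recovery experiments
#'
#' Same qualitative structure as the [similarity_grid()] default — children
#' above adults in every ROI, the child advantage largest in vmPFC, a
#' negative > positive > neutral ordering in children, flat adults — but
#' with every planted gap sized to at least 4-5 replicate-to-replicate
#' standard deviations of the corresponding contrast under the default
#' cohort (25 + 20 participants, `participant_sd = 0.1`, shared-template
#' cell noise at a few dozen voxels per ROI). Use this grid when the
#' question is whether the pipeline recovers a planted pattern reliably
#' across replicate studies; effects at detection threshold would conflate
#' recovery failures with power failures.
#'
#' @return A data frame like [similarity_grid()]'s.
#' @export
recovery_grid <- function() {
  g <- similarity_grid()
  child_vals <- cbind( # positive, negative, neutral
    AMY = c(0.22, 0.32, 0.16),
    NAcc = c(0.21, 0.31, 0.15),
    vmPFC = c(0.34, 0.44, 0.28)
  )
  child <- g$age_group == "child"
  g$a[child] <- child_vals[cbind(match(g$valence[child], VALENCE_LEVELS),
                                 match(g$roi[child], colnames(child_vals)))]
  g
}

#' Configuration of a simulated movie-viewing study
#'
#' Bundles the constants of the emulated design (sample sizes, 24-clip
#' stimulus structure, timing, scanner sampling) with the generator's planted
#' similarity levels and noise. Values default to the emulated study's
#' conditions: 25 children and 20 adults, 24 clips (8 per valence; 8 films
#' each contributing one positive and one negative clip; 8 distinct-source
#' neutral clips), clip durations 19-46 s, jittered 6-12 s ISI, three
#' counterbalanced orders, TR = 2 s and 510 volumes.
#'
#' @param n_children,n_adults Group sizes.
#' @param rois Named integer vector of voxels per ROI (all >= 2). Defaults to
#'   the sizes of the package's demonstration masks on a 4 mm grid.
#' @param similarity Data frame from [similarity_grid()].
#' @param noise_sd Standard deviation of additive scanner noise in the BOLD
#'   stage, in units of the (unit-variance) planted pattern betas.
#' @param participant_sd Between-participant sd of the planted similarity: a
#'   participant-level offset added to every cell's `a` (clamped into
#'   `[0, 1]`), inducing the clustering of similarity by participant that
#'   real cohorts show (an intraclass correlation near 0.1 at the default).
#' @param child_age_slope Planted change of `a` per month of age among
#'   children, centred on the child age midpoint (0 = no age trend).
#' @param tr_s Repetition time in seconds.
#' @param n_volumes Number of BOLD volumes per run.
#' @param initial_fixation_s Fixation lead-in before the first clip onset.
#' @param duration_range_s,isi_range_s Uniform sampling ranges for clip
#'   durations and interstimulus intervals, in seconds.
#' @param child_age_months,adult_age_months Ranges (months) from which
#'   participant ages are drawn uniformly.
#' @param highpass_cutoff_s GLM high-pass cutoff in seconds.
#' @param seed Default base seed for all generator stages.
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_children = 25, n_adults = 20,
                              rois = c(AMY = 40, NAcc = 14, vmPFC = 10),
                              similarity = similarity_grid(),
                              noise_sd = 1,
                              participant_sd = 0.1,
                              child_age_slope = 0,
                              tr_s = 2, n_volumes = 510,
                              initial_fixation_s = 6,
                              duration_range_s = c(19, 46),
                              isi_range_s = c(6, 12),
                              child_age_months = c(48, 131),
                              adult_age_months = c(240, 528),
                              highpass_cutoff_s = 100,
                              seed = 1L) {
  cfg <- list(
    n_children = as.integer(n_children), n_adults = as.integer(n_adults),
    rois = rois, similarity = similarity, noise_sd = noise_sd,
    participant_sd = participant_sd, child_age_slope = child_age_slope,
    tr_s = tr_s, n_volumes = as.integer(n_volumes),
    initial_fixation_s = initial_fixation_s,
    duration_range_s = duration_range_s, isi_range_s = isi_range_s,
    child_age_months = child_age_months, adult_age_months = adult_age_months,
    highpass_cutoff_s = highpass_cutoff_s,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$n_children >= 0, cfg$n_adults >= 0,
    length(cfg$rois) >= 1, !is.null(names(cfg$rois)), all(cfg$rois >= 2),
    is.data.frame(cfg$similarity),
    all(c("age_group", "roi", "valence", "a") %in% names(cfg$similarity)),
    all(cfg$similarity$a >= 0 & cfg$similarity$a <= 1),
    cfg$noise_sd >= 0, cfg$participant_sd >= 0,
    is.numeric(cfg$child_age_slope),
    cfg$tr_s > 0, cfg$n_volumes > 0,
    length(cfg$duration_range_s) == 2,
    cfg$duration_range_s[1] <= cfg$duration_range_s[2],
    length(cfg$isi_range_s) == 2, cfg$isi_range_s[1] <= cfg$isi_range_s[2]
  )
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulated study configuration\n")
  cat(sprintf("  participants: %d children + %d adults\n",
              x$n_children, x$n_adults))
  cat(sprintf("  ROIs: %s\n",
              paste(sprintf("%s (%d vox)", names(x$rois), x$rois),
                    collapse = ", ")))
  cat(sprintf("  run: %d volumes, TR %.1f s; clips %g-%g s, ISI %g-%g s\n",
              x$n_volumes, x$tr_s, x$duration_range_s[1], x$duration_range_s[2],
              x$isi_range_s[1], x$isi_range_s[2]))
  cat(sprintf("  planted similarity: %.2f-%.2f; noise sd %.2f; seed %d\n",
              min(x$similarity$a), max(x$similarity$a), x$noise_sd, x$seed))
  invisible(x)
}

# The fixed 24-clip stimulus set: 8 films each contributing one positive and
# one negative clip, plus 8 neutral clips from distinct documentary sources.
clip_roster <- function() {
  data.frame(
    clip_id = c(sprintf("pos_%02d", 1:8), sprintf("neg_%02d", 1:8),
                sprintf("neu_%02d", 1:8)),
    film_id = c(sprintf("film_%02d", 1:8), sprintf("film_%02d", 1:8),
                sprintf("doc_%02d", 1:8)),
    valence = rep(VALENCE_LEVELS, each = 8),
    stringsAsFactors = FALSE
  )
}

#' Generate counterbalanced clip schedules
#'
#' Draws one realisation of the 24-clip stimulus set and lays it out in three
#' counterbalanced presentation orders. Clip durations are sampled once per
#' study (they are stimulus properties, identical across orders) uniformly on
#' `duration_range_s`; each order gets its own permutation and its own
#' jittered ISIs drawn uniformly on `isi_range_s`. Draws are rejected and
#' retried until every order fits inside the run (`n_volumes * tr_s`), which
#' keeps the stated ranges while guaranteeing feasibility; sampling is
#' deterministic given `seed`.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A data frame of class `clip_schedule` with one row per clip per
#'   order and columns `order_id`, `clip_id`, `film_id`, `valence`,
#'   `onset_s`, `duration_s`.
#' @export
generate_schedule <- function(config, seed = config$seed) {
  validate_config(config)
  run_s <- config$n_volumes * config$tr_s
  min_total <- config$initial_fixation_s +
    24 * config$duration_range_s[1] + 23 * config$isi_range_s[1]
  if (min_total > run_s) {
    stop(sprintf(paste0(
      "infeasible timing: minimum schedule length %.1f s exceeds the run ",
      "length %.1f s (%d volumes x %.1f s) by %.1f s"),
      min_total, run_s, config$n_volumes, config$tr_s, min_total - run_s))
  }
  roster <- clip_roster()
  with_seed(seed, {
    for (try in 1:1000) {
      durations <- runif(24, config$duration_range_s[1],
                         config$duration_range_s[2])
      isis <- matrix(runif(3 * 23, config$isi_range_s[1],
                           config$isi_range_s[2]), nrow = 3)
      totals <- config$initial_fixation_s + sum(durations) + rowSums(isis)
      if (all(totals <= run_s)) break
      if (try == 1000) {
        stop("infeasible timing: could not fit 24 clips into the run after ",
             "1000 draws; lengthen the run or tighten the duration/ISI ranges")
      }
    }
    orders <- lapply(1:3, function(o) {
      perm <- sample.int(24)
      dur <- durations[perm]
      onset <- config$initial_fixation_s +
        cumsum(c(0, dur[-24] + isis[o, ]))
      data.frame(
        order_id = o,
        clip_id = roster$clip_id[perm],
        film_id = roster$film_id[perm],
        valence = roster$valence[perm],
        onset_s = onset,
        duration_s = dur,
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, orders)
    rownames(out) <- NULL
    class(out) <- c("clip_schedule", "data.frame")
    out
  })
}

#' Check the structural invariants of a clip schedule
#'
#' Verifies the stimulus-design contract: 24 clips per order, 8 per valence,
#' each film contributing exactly one positive and one negative clip, 8
#' distinct neutral sources, durations and ISIs inside the configured ranges,
#' and non-overlapping presentations within each order.
#'
#' @param schedule A `clip_schedule` data frame.
#' @param config The [simulation_config()] used to generate it.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_schedule <- function(schedule, config) {
  for (o in unique(schedule$order_id)) {
    s <- schedule[schedule$order_id == o, ]
    s <- s[order(s$onset_s), ]
    if (nrow(s) != 24) stop("order ", o, ": expected 24 clips, got ", nrow(s))
    if (!all(table(s$valence) == 8)) {
      stop("order ", o, ": valences are not 8/8/8")
    }
    for (v in c("positive", "negative")) {
      films <- s$film_id[s$valence == v]
      if (anyDuplicated(films)) {
        stop("order ", o, ": a film contributes two ", v, " clips")
      }
    }
    if (anyDuplicated(s$film_id[s$valence == "neutral"])) {
      stop("order ", o, ": neutral sources are not distinct")
    }
    if (any(s$duration_s < config$duration_range_s[1] - 1e-9) ||
        any(s$duration_s > config$duration_range_s[2] + 1e-9)) {
      stop("order ", o, ": clip duration outside the configured range")
    }
    gaps <- s$onset_s[-1] - (s$onset_s[-24] + s$duration_s[-24])
    if (any(gaps < config$isi_range_s[1] - 1e-9) ||
        any(gaps > config$isi_range_s[2] + 1e-9)) {
      stop("order ", o, ": ISI outside the configured range")
    }
    if (any(gaps < 0)) stop("order ", o, ": overlapping clips")
    if (max(s$onset_s + s$duration_s) > config$n_volumes * config$tr_s) {
      stop("order ", o, ": schedule overruns the scan")
    }
  }
  invisible(TRUE)
}

#' Simulate second-by-second affect codes for each clip
#'
#' Emulates the rater coding of clip content: one code per second of film,
#' +1 for seconds showing positive affect, -1 for negative affect, 0 for
#' unvalenced content. Code probabilities per valence are set so that the
#' expected mean code matches the coded affect of the emulated stimulus set
#' (about +0.89 for positive clips and -0.76 for negative clips).
#'
#' @param schedule A `clip_schedule` (only one order's rows are used, since
#'   codes are stimulus properties).
#' @param seed Integer seed.
#' @return A named list, one integer vector of codes in `{-1, 0, 1}` per
#'   clip, of length `floor(duration_s)`.
#' @export
generate_affect_codes <- function(schedule, seed = 1L) {
  s <- schedule[schedule$order_id == schedule$order_id[1], ]
  probs <- list( # P(-1), P(0), P(+1)
    positive = c(0.005, 0.100, 0.895),
    negative = c(0.875, 0.110, 0.015),
    neutral = c(0.050, 0.900, 0.050)
  )
  with_seed(seed, {
    codes <- lapply(seq_len(nrow(s)), function(i) {
      n <- floor(s$duration_s[i])
      sample(c(-1L, 0L, 1L), n, replace = TRUE, prob = probs[[s$valence[i]]])
    })
    names(codes) <- s$clip_id
    codes
  })
}

#' Mean affect score of a coded clip
#'
#' @param codes Integer vector of per-second codes in `{-1, 0, 1}`.
#' @return List with `mean` (arithmetic mean code) and `abs_mean` (mean of
#'   absolute codes, the fraction of seconds carrying any valenced content).
#' @examples
#' affect_score(c(1, 1, 0, -1)) # mean 0.25, abs_mean 0.75
#' @export
affect_score <- function(codes) {
  if (length(codes) == 0) stop("empty affect code series")
  if (!all(codes %in% c(-1, 0, 1))) {
    stop("affect codes must be in {-1, 0, 1}")
  }
  list(mean = mean(codes), abs_mean = mean(abs(codes)))
}
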