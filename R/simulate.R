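#' Simulate a complete study at the pattern level
#'
#' Convenience wrapper over the generator stages: draws the schedule, the
#' participant roster and the planted voxel patterns, and computes the
#' similarity table — everything downstream group statistics need. The BOLD
#' stage (timeseries, GLM) is bypassed; use [generate_bold()] and
#' [estimate_patterns()] to exercise it explicitly.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return List with `config`, `seed`, `schedule`, `patterns`
#'   (`roi_patterns`) and `similarity` (long-format table).
#' @export
simulate_study <- function(config = simulation_config(),
                           seed = config$seed) {
  schedule <- generate_schedule(config, seed)
  patterns <- generate_patterns(config, schedule, seed = seed)
  similarity <- build_similarity_table(patterns, schedule)
  list(config = config, seed = seed, schedule = schedule,
       patterns = patterns, similarity = similarity)
}

#' Simulate motion traces for a recruited cohort with high-motion members
#'
#' Emulates the recruitment-to-analysis funnel: every participant gets an
#' ordinary motion trace, and a designated number of children and adults get
#' traces with frequent injected spikes (18% of volumes) that trip the
#' 15%-outlier exclusion rule. With the emulated study's funnel (36 children
#' + 21 adults recruited, 11 children and 1 adult high-motion) QC retains
#' the effective sample of 45.
#'
#' @param n_children,n_adults Recruited group sizes.
#' @param high_motion_children,high_motion_adults How many of each group
#'   are simulated with excessive motion.
#' @param n_volumes Volumes per run.
#' @param seed Integer seed.
#' @return List with `motion` (named list of traces, suitable for
#'   [qc_cohort()]) and `truth` (data frame flagging the injected
#'   high-motion participants).
#' @export
simulate_motion_cohort <- function(n_children = 36, n_adults = 21,
                                   high_motion_children = 11,
                                   high_motion_adults = 1,
                                   n_volumes = 510, seed = 1L) {
  stopifnot(high_motion_children <= n_children,
            high_motion_adults <= n_adults)
  ids <- c(sprintf("child_%02d", seq_len(n_children)),
           sprintf("adult_%02d", seq_len(n_adults)))
  high <- c(sprintf("child_%02d", seq_len(high_motion_children)),
            sprintf("adult_%02d", seq_len(high_motion_adults)))
  n_spike <- ceiling(0.18 * n_volumes)
  motion <- lapply(seq_along(ids), function(i) {
    s <- derive_seed(seed, 300L + i)
    if (ids[i] %in% high) {
      spikes <- with_seed(derive_seed(s, 1L),
                          sample.int(n_volumes, n_spike))
      simulate_motion(n_volumes, seed = s, spike_volumes = spikes)
    } else {
      simulate_motion(n_volumes, seed = s)
    }
  })
  names(motion) <- ids
  list(motion = motion,
       truth = data.frame(participant_id = ids, high_motion = ids %in% high,
                          stringsAsFactors = FALSE))
}
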