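#' Run the full simulate-to-statistics pipeline into a directory
#'
#' Orchestrates the stages — simulate, motion QC, (optionally) BOLD + GLM,
#' similarity, group statistics — writing every stage's output as a plain
#' file so any stage can be inspected or re-run independently, plus a
#' manifest recording the configuration hash, seed, package version and row
#' counts. Reruns with the same config and seed are bit-identical.
#'
#' Outputs under `out_dir`: `config.yaml`, `schedule.tsv`,
#' `participants.csv`, `qc_report.csv`, `patterns.tsv`, `similarity.tsv`,
#' `anova.csv`, `contrasts.csv`, `multilevel.json`, `alpha.json`,
#' `manifest.json`.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Base seed; defaults to `config$seed`.
#' @param bold If `TRUE`, voxel patterns are re-estimated through the
#'   simulated BOLD + GLM stage (slower); if `FALSE` the planted patterns
#'   feed the similarity stage directly.
#' @param write_patterns If `FALSE`, the long-format pattern TSV (the
#'   largest output) is skipped.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = simulation_config(), out_dir,
                         seed = config$seed, bold = FALSE,
                         write_patterns = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  manifest <- list(seed = seed,
                   package_version = as.character(utils::packageVersion("affrsa")),
                   bold = bold, stages = list())

  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  manifest$config_hash <- unname(tools::md5sum(file.path(out_dir,
                                                         "config.yaml")))

  schedule <- stage("simulate", generate_schedule(config, seed))
  validate_schedule(schedule, config)
  write.table(schedule, file.path(out_dir, "schedule.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  participants <- stage("simulate", generate_participants(config, seed))
  write.csv(participants, file.path(out_dir, "participants.csv"),
            row.names = FALSE)
  patterns <- stage("simulate",
                    generate_patterns(config, schedule, participants, seed))
  manifest$stages$simulate <- list(
    schedule_rows = nrow(schedule), participants = nrow(participants))

  motion <- stage("qc", {
    m <- lapply(seq_len(nrow(participants)), function(i) {
      simulate_motion(config$n_volumes, seed = derive_seed(seed, 300L + i))
    })
    names(m) <- participants$participant_id
    m
  })
  qc <- stage("qc", qc_cohort(motion))
  write.csv(qc, file.path(out_dir, "qc_report.csv"), row.names = FALSE)
  kept <- qc$participant_id[qc$kept]
  manifest$stages$qc <- list(recruited = nrow(qc), kept = length(kept),
                             excluded = nrow(qc) - length(kept))
  patterns$participants <- patterns$participants[
    patterns$participants$participant_id %in% kept, ]
  patterns$patterns <- patterns$patterns[kept]

  if (bold) {
    patterns <- stage("glm", {
      est <- patterns
      for (pid in kept) {
        run <- generate_bold(patterns, pid, schedule, config, seed = seed)
        est$patterns[[pid]] <- estimate_patterns(run, schedule, config)
      }
      est
    })
  }
  if (write_patterns) {
    long <- do.call(rbind, lapply(kept, function(pid) {
      do.call(rbind, lapply(names(patterns$patterns[[pid]]), function(roi) {
        mat <- patterns$patterns[[pid]][[roi]]
        data.frame(participant_id = pid, roi = roi,
                   clip_id = rep(colnames(mat), each = nrow(mat)),
                   voxel = rep(seq_len(nrow(mat)), ncol(mat)),
                   beta = as.vector(mat), stringsAsFactors = FALSE)
      }))
    }))
    write.table(long, file.path(out_dir, "patterns.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  similarity <- stage("similarity", build_similarity_table(patterns, schedule))
  write_similarity_tsv(similarity, file.path(out_dir, "similarity.tsv"))
  manifest$stages$similarity <- list(
    rows = nrow(similarity), missing = sum(is.na(similarity$z)))

  anova_tab <- stage("stats", mixed_anova(similarity))
  write.csv(anova_tab, file.path(out_dir, "anova.csv"), row.names = FALSE)
  contrasts <- stage("stats", {
    fams <- default_contrast_families()
    do.call(rbind, lapply(names(fams), function(fn) {
      ct <- bonferroni_contrasts(similarity, fams[[fn]])
      cbind(family = fn, ct)
    }))
  })
  write.csv(contrasts, file.path(out_dir, "contrasts.csv"), row.names = FALSE)
  ml <- stage("stats", age_multilevel(similarity))
  jsonlite::write_json(ml, file.path(out_dir, "multilevel.json"),
                       auto_unbox = TRUE, digits = NA)
  ratings <- stage("stats",
                   generate_ratings(schedule, seed = derive_seed(seed, 41L)))
  alpha <- stage("stats", krippendorff_alpha(ratings))
  jsonlite::write_json(list(alpha = alpha, n_raters = ncol(ratings),
                            n_items = nrow(ratings)),
                       file.path(out_dir, "alpha.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$stages$stats <- list(
    anova_effects = nrow(anova_tab), contrasts = nrow(contrasts),
    multilevel_icc = ml$icc, krippendorff_alpha = alpha)

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
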