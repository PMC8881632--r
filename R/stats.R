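#' Two-stratum mixed ANOVA on Fisher-Z similarity values
#'
#' Fits the 3 (ROI) x 2 (age group) x 3 (valence) mixed-effects ANOVA with
#' age group as a between-participant factor and ROI and valence as
#' within-participant factors, using two error strata: the age-group effect
#' is tested against the participant-level residual, and all within-subject
#' effects against the within-participant residual. On the complete design
#' (45 participants x 3 x 3 x 28 pairs) the strata have 43 and 11,279
#' residual degrees of freedom.
#'
#' Effect sizes use the conventions: partial omega^2 =
#' `(SS_eff - df_eff * MS_err) / (SS_total + MS_participant_err)` (clamped at
#' 0), with `MS_err` from the effect's own stratum, and Cohen's f =
#' `sqrt(omega^2 / (1 - omega^2))`.
#'
#' @param table Similarity table from [build_similarity_table()]; rows with
#'   missing `z` are dropped with a message.
#' @param on_missing_cell What to do when a participant has an entire
#'   ROI x valence cell empty: `"error"` (default) or `"drop"` the
#'   participant.
#' @return Data frame of class `anova_table` with columns `stratum`,
#'   `effect`, `sum_sq`, `df`, `mean_sq`, `F`, `p`, `partial_omega_sq`,
#'   `cohens_f` (the residual rows carry `NA` test columns).
#' @export
mixed_anova <- function(table, on_missing_cell = c("error", "drop")) {
  on_missing_cell <- match.arg(on_missing_cell)
  d <- table[!is.na(table$z), ]
  n_dropped <- nrow(table) - nrow(d)
  if (n_dropped > 0) {
    message("dropping ", n_dropped, " records with missing similarity")
  }
  if (length(unique(d$age_group)) < 2) {
    stop("age_group must have both levels (children and adults) present")
  }
  cells <- table(d$participant_id, interaction(d$roi, d$valence))
  empty <- which(cells == 0, arr.ind = TRUE)
  if (nrow(empty) > 0) {
    what <- paste(rownames(cells)[empty[, 1]],
                  colnames(cells)[empty[, 2]], sep = ": ")
    if (on_missing_cell == "error") {
      stop("participants with empty design cells: ",
           paste(what, collapse = "; "))
    }
    bad <- unique(rownames(cells)[empty[, 1]])
    message("dropping participants with empty cells: ",
            paste(bad, collapse = ", "))
    d <- d[!(d$participant_id %in% bad), ]
  }
  d$participant_id <- factor(d$participant_id)
  d$age_group <- factor(d$age_group, levels = c("child", "adult"))
  d$roi <- factor(d$roi)
  d$valence <- factor(d$valence, levels = VALENCE_LEVELS)
  fit <- aov(z ~ age_group * roi * valence + Error(participant_id), data = d)
  strata <- summary(fit)
  tidy_stratum <- function(s, label) {
    tab <- s[[1]]
    eff <- trimws(rownames(tab))
    data.frame(stratum = label, effect = eff,
               sum_sq = tab[["Sum Sq"]], df = tab[["Df"]],
               mean_sq = tab[["Mean Sq"]],
               F = if ("F value" %in% names(tab)) tab[["F value"]] else NA,
               p = if ("Pr(>F)" %in% names(tab)) tab[["Pr(>F)"]] else NA,
               stringsAsFactors = FALSE)
  }
  between <- tidy_stratum(strata[["Error: participant_id"]], "participant")
  within <- tidy_stratum(strata[["Error: Within"]], "within")
  out <- rbind(between, within)
  ss_total <- sum(out$sum_sq)
  ms_participant_err <- between$mean_sq[between$effect == "Residuals"]
  ms_err <- ifelse(out$stratum == "participant", ms_participant_err,
                   within$mean_sq[within$effect == "Residuals"])
  omega <- pmax(0, (out$sum_sq - out$df * ms_err) /
                  (ss_total + ms_participant_err))
  omega[out$effect == "Residuals"] <- NA
  out$partial_omega_sq <- omega
  out$cohens_f <- sqrt(omega / (1 - omega))
  out$F[out$effect == "Residuals"] <- NA
  out$p[out$effect == "Residuals"] <- NA
  rownames(out) <- NULL
  class(out) <- c("anova_table", "data.frame")
  out
}

# Record selector for contrast cells. A cell set is a data frame whose
# columns are any of age_group / roi / valence / valence_class; a record
# matches a set if it matches any row.
select_records <- function(table, cells) {
  tab <- table
  tab$valence_class <- ifelse(tab$valence == "neutral", "neutral", "valenced")
  keep <- rep(FALSE, nrow(tab))
  for (r in seq_len(nrow(cells))) {
    m <- rep(TRUE, nrow(tab))
    for (col in names(cells)) {
      if (!is.na(cells[[col]][r])) m <- m & tab[[col]] == cells[[col]][r]
    }
    keep <- keep | m
  }
  which(keep)
}

cellset <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  df
}

#' Bonferroni-adjusted contrasts on similarity cell means
#'
#' Each contrast compares the mean Fisher-Z similarity of one set of design
#' cells against another (e.g. child vmPFC vs adult vmPFC, or the pooled
#' valenced cells of children vs adults). Interaction contrasts pool the
#' crossed cells of the two sides (e.g. {child AMY, adult vmPFC} vs
#' {adult AMY, child vmPFC}), i.e. a difference-of-differences up to a
#' factor of two. By default the test is an unpooled (Welch) two-sample
#' t-test over records with Satterthwaite degrees of freedom, which matches
#' the per-contrast df magnitudes such record-level post-hocs produce; a
#' pooled-variance test is available via `se_method`.
#'
#' @param table Similarity table (missing `z` rows are ignored).
#' @param family List of contrasts, each a list with `label`, `side_a`,
#'   `side_b` (cell-set data frames over `age_group` / `roi` / `valence` /
#'   `valence_class`); see [default_contrast_families()].
#' @param m Bonferroni family size; defaults to `length(family)`.
#' @param se_method `"welch"` (default) or `"pooled"`.
#' @return Data frame: `label`, `mean_difference` (Fisher-Z units, side A
#'   minus side B), `se`, `t`, `df`, `p`, `p_adjusted`
#'   (`min(1, m * p)`).
#' @export
bonferroni_contrasts <- function(table, family, m = length(family),
                                 se_method = c("welch", "pooled")) {
  se_method <- match.arg(se_method)
  stopifnot(m >= 1)
  d <- table[!is.na(table$z), ]
  rows <- lapply(family, function(ct) {
    ia <- select_records(d, ct$side_a)
    ib <- select_records(d, ct$side_b)
    if (length(ia) == 0 || length(ib) == 0) {
      stop("contrast '", ct$label, "' references cells with no records")
    }
    za <- d$z[ia]
    zb <- d$z[ib]
    na <- length(za)
    nb <- length(zb)
    diff <- mean(za) - mean(zb)
    if (se_method == "welch") {
      va <- var(za) / na
      vb <- var(zb) / nb
      se <- sqrt(va + vb)
      df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
    } else {
      sp2 <- ((na - 1) * var(za) + (nb - 1) * var(zb)) / (na + nb - 2)
      se <- sqrt(sp2 * (1 / na + 1 / nb))
      df <- na + nb - 2
    }
    tval <- diff / se
    p <- 2 * pt(-abs(tval), df)
    data.frame(label = ct$label, mean_difference = diff, se = se, t = tval,
               df = df, p = p, p_adjusted = min(1, m * p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default contrast families for the factorial design
#'
#' The post-hoc families following the mixed ANOVA, one per reported table
#' block: the nine age x ROI cell contrasts plus their three interaction
#' (difference-of-differences) contrasts; the nine age x valence cell
#' contrasts plus the positive/negative interaction contrast; and the
#' valenced-vs-neutral family. Family sizes (the Bonferroni `m`) are the
#' number of contrasts in each family and are a configuration knob of
#' [bonferroni_contrasts()].
#'
#' @return Named list of families, each a list of contrast specifications.
#' @export
default_contrast_families <- function() {
  grp_roi <- function(roi) list(
    label = sprintf("%s, child vs adult", roi),
    side_a = cellset(age_group = "child", roi = roi),
    side_b = cellset(age_group = "adult", roi = roi))
  roi_grp <- function(grp, r1, r2) list(
    label = sprintf("%s, %s vs %s", grp, r1, r2),
    side_a = cellset(age_group = grp, roi = r1),
    side_b = cellset(age_group = grp, roi = r2))
  roi_inter <- function(r1, r2) list(
    label = sprintf("%s, child and %s, adult vs %s, adult and %s, child",
                    r1, r2, r1, r2),
    side_a = cellset(age_group = c("child", "adult"), roi = c(r1, r2)),
    side_b = cellset(age_group = c("adult", "child"), roi = c(r1, r2)))
  grp_val <- function(v) list(
    label = sprintf("%s, child vs adult", v),
    side_a = cellset(age_group = "child", valence = v),
    side_b = cellset(age_group = "adult", valence = v))
  val_grp <- function(grp, v1, v2) list(
    label = sprintf("%s, %s vs %s", grp, v1, v2),
    side_a = cellset(age_group = grp, valence = v1),
    side_b = cellset(age_group = grp, valence = v2))
  list(
    roi_by_age = list(
      grp_roi("AMY"), grp_roi("NAcc"), grp_roi("vmPFC"),
      roi_grp("child", "AMY", "NAcc"), roi_grp("child", "AMY", "vmPFC"),
      roi_grp("child", "NAcc", "vmPFC"),
      roi_grp("adult", "AMY", "NAcc"), roi_grp("adult", "AMY", "vmPFC"),
      roi_grp("adult", "NAcc", "vmPFC")),
    roi_interaction = list(
      roi_inter("AMY", "NAcc"), roi_inter("AMY", "vmPFC"),
      roi_inter("NAcc", "vmPFC")),
    valence_by_age = list(
      grp_val("positive"), grp_val("negative"), grp_val("neutral"),
      val_grp("child", "positive", "negative"),
      val_grp("child", "positive", "neutral"),
      val_grp("child", "negative", "neutral"),
      val_grp("adult", "positive", "negative"),
      val_grp("adult", "positive", "neutral"),
      val_grp("adult", "negative", "neutral")),
    valence_interaction = list(list(
      label = "positive, child and negative, adult vs positive, adult and negative, child",
      side_a = cellset(age_group = c("child", "adult"),
                       valence = c("positive", "negative")),
      side_b = cellset(age_group = c("adult", "child"),
                       valence = c("positive", "negative")))),
    valenced_vs_neutral = list(
      list(label = "child, valenced vs neutral",
           side_a = cellset(age_group = "child", valence_class = "valenced"),
           side_b = cellset(age_group = "child", valence_class = "neutral")),
      list(label = "adult, valenced vs neutral",
           side_a = cellset(age_group = "adult", valence_class = "valenced"),
           side_b = cellset(age_group = "adult", valence_class = "neutral")),
      list(label = "valenced, child and neutral, adult vs valenced, adult and neutral, child",
           side_a = cellset(age_group = c("child", "adult"),
                            valence_class = c("valenced", "neutral")),
           side_b = cellset(age_group = c("adult", "child"),
                            valence_class = c("valenced", "neutral"))),
      list(label = "valenced, child vs valenced, adult",
           side_a = cellset(age_group = "child", valence_class = "valenced"),
           side_b = cellset(age_group = "adult", valence_class = "valenced")))
  )
}

#' Age-in-months multilevel model with ICC
#'
#' Restricted to the child sample: fits a random-intercept model of
#' Fisher-Z similarity on age in months (fixed slope), plus the null model
#' without fixed effects, whose intraclass correlation
#' (between-participant variance over total variance) summarises how much
#' similarity clusters by participant. Both the response and age are
#' standardised before fitting, so the slope is in standard-deviation
#' units.
#'
#' @param table Similarity table; only `age_group == "child"` rows are used.
#' @return List with `slope` (standardised), `se`, `p`, `icc`, `singular`
#'   (logical convergence flag), `n_participants`, `n_records`.
#' @export
age_multilevel <- function(table) {
  d <- table[table$age_group == "child" & !is.na(table$z), ]
  if (length(unique(d$participant_id)) < 3) {
    stop("need at least 3 child participants")
  }
  if (length(unique(d$age_months)) < 2) {
    stop("no age variation among children")
  }
  d$z_s <- as.numeric(scale(d$z))
  d$age_s <- as.numeric(scale(d$age_months))
  fit <- lmerTest::lmer(z_s ~ age_s + (1 | participant_id), data = d,
                        REML = TRUE)
  cf <- coef(summary(fit))["age_s", ]
  null <- lme4::lmer(z ~ 1 + (1 | participant_id), data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(null))
  var_b <- vc$vcov[vc$grp == "participant_id"]
  var_w <- vc$vcov[vc$grp == "Residual"]
  list(slope = unname(cf["Estimate"]), se = unname(cf["Std. Error"]),
       p = unname(cf["Pr(>|t|)"]), icc = var_b / (var_b + var_w),
       singular = lme4::isSingular(fit) || lme4::isSingular(null),
       n_participants = length(unique(d$participant_id)),
       n_records = nrow(d))
}

#' Krippendorff's alpha for nominal rater agreement
#'
#' Chance-corrected agreement `alpha = 1 - Do / De` from the coincidence
#' matrix over pairable values: for every item coded by at least two
#' raters, each ordered pair of codes from different raters contributes
#' `1 / (m_u - 1)` to the coincidence count of its code pair. Missing codes
#' are simply not paired.
#'
#' @param ratings Items x raters matrix (character or factor codes, `NA`
#'   allowed; at least 2 raters and 1 item with >= 2 codes).
#' @return Alpha in `[-1, 1]` (1 = perfect agreement, 0 = chance).
#' @export
krippendorff_alpha <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (ncol(ratings) < 2) stop("need at least 2 raters")
  codes <- sort(unique(as.vector(ratings[!is.na(ratings)])))
  if (length(codes) == 0) stop("no codes present")
  k <- length(codes)
  o <- matrix(0, k, k, dimnames = list(codes, codes))
  for (u in seq_len(nrow(ratings))) {
    vals <- ratings[u, !is.na(ratings[u, ])]
    m_u <- length(vals)
    if (m_u < 2) next
    idx <- match(vals, codes)
    for (i in seq_len(m_u)) {
      for (j in seq_len(m_u)) {
        if (i != j) o[idx[i], idx[j]] <- o[idx[i], idx[j]] + 1 / (m_u - 1)
      }
    }
  }
  n <- sum(o)
  if (n == 0) stop("no pairable values (no item has two or more codes)")
  n_c <- rowSums(o)
  d_o <- (n - sum(diag(o))) / n
  d_e <- (n^2 - sum(n_c^2)) / (n * (n - 1))
  if (d_e == 0) return(1) # a single observed code: define as full agreement
  1 - d_o / d_e
}

#' Simulate rater codings of the clip set
#'
#' Three (by default) independent raters code each clip's valence; each
#' code matches the clip's true category with probability `1 - miscode`,
#' otherwise one of the other two categories at random. The default miscode
#' rate is set so the expected chance-corrected agreement matches the
#' inter-rater reliability reported for the emulated stimulus set
#' (alpha around 0.91).
#'
#' @param clips Data frame with `clip_id` and `valence` (one row per clip).
#' @param n_raters Number of raters.
#' @param miscode Per-code error probability.
#' @param seed Integer seed.
#' @return Items x raters character matrix with clip ids as row names.
#' @export
generate_ratings <- function(clips, n_raters = 3, miscode = 0.03,
                             seed = 1L) {
  clips <- unique(clips[, c("clip_id", "valence")])
  with_seed(seed, {
    out <- vapply(seq_len(n_raters), function(r) {
      vapply(clips$valence, function(v) {
        if (runif(1) < miscode) sample(setdiff(VALENCE_LEVELS, v), 1) else v
      }, character(1))
    }, character(nrow(clips)))
    out <- matrix(out, nrow = nrow(clips),
                  dimnames = list(clips$clip_id,
                                  sprintf("rater_%d", seq_len(n_raters))))
    out
  })
}
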