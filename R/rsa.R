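#' Enumerate valid within-valence inter-movie clip pairs
#'
#' The pairing rule of the similarity analysis: all unordered pairs of clips
#' that share a valence but come from different source films. Same-film
#' pairs are excluded because two clips from one film can resemble each
#' other for superficial, non-affective reasons (shared characters, audio,
#' style). On the full design (8 films each giving one positive and one
#' negative clip, 8 distinct-source neutral clips) this yields 28 pairs per
#' valence category.
#'
#' @param clips Data frame with columns `clip_id`, `film_id`, `valence`
#'   (duplicated rows, e.g. from multi-order schedules, are collapsed).
#' @return Data frame with columns `valence`, `clip_a`, `clip_b`
#'   (`clip_a < clip_b`), one row per unordered pair; zero rows if none.
#' @export
valid_pairs <- function(clips) {
  clips <- unique(clips[, c("clip_id", "film_id", "valence")])
  clips <- clips[order(clips$clip_id), ]
  out <- lapply(split(clips, clips$valence), function(s) {
    n <- nrow(s)
    if (n < 2) return(NULL)
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- s$film_id[idx[, 1]] != s$film_id[idx[, 2]]
    if (!any(keep)) return(NULL)
    data.frame(valence = s$valence[1],
               clip_a = s$clip_id[idx[keep, 1]],
               clip_b = s$clip_id[idx[keep, 2]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(valence = character(), clip_a = character(),
                      clip_b = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation with midranks and pairwise-complete voxels
#'
#' The package's similarity statistic: the Pearson correlation of average
#' (mid)ranks, computed over the voxel positions that are non-missing in
#' both patterns of the pair. Positions missing in either vector are
#' dropped for that pair only.
#'
#' @param x,y Numeric pattern vectors of equal length; `NA`/non-finite
#'   entries are treated as missing.
#' @return List with `rho` (in `[-1, 1]`, or `NA` when fewer than 3 shared
#'   positions remain or either rank vector is constant — a warning is
#'   raised) and `n_used` (shared non-missing positions).
#' @export
spearman_similarity <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  n_used <- sum(ok)
  if (n_used < 3) {
    warning("fewer than 3 shared non-missing voxels; similarity undefined")
    return(list(rho = NA_real_, n_used = n_used))
  }
  rx <- rank(x[ok], ties.method = "average")
  ry <- rank(y[ok], ties.method = "average")
  rx <- rx - mean(rx)
  ry <- ry - mean(ry)
  sxx <- sum(rx^2)
  syy <- sum(ry^2)
  if (sxx == 0 || syy == 0) {
    warning("zero rank variance; similarity undefined")
    return(list(rho = NA_real_, n_used = n_used))
  }
  rho <- sum(rx * ry) / sqrt(sxx * syy)
  list(rho = max(-1, min(1, rho)), n_used = n_used)
}

#' Fisher Z transformation of a correlation coefficient
#'
#' `z = atanh(rho)` after clamping `rho` into `[-1 + eps, 1 - eps]` so that
#' degenerate correlations of exactly +/-1 stay finite.
#'
#' @param rho Correlation in `[-1, 1]` (`NA` passes through).
#' @param eps Clamping margin.
#' @return Fisher Z value(s); strictly increasing in `rho`.
#' @export
fisher_z <- function(rho, eps = 1e-7) {
  bad <- !is.na(rho) & abs(rho) > 1
  if (any(bad)) stop("correlations outside [-1, 1]: ",
                     paste(signif(rho[bad], 4), collapse = ", "))
  atanh(pmax(-1 + eps, pmin(1 - eps, rho)))
}

# Fast path: columnwise midrank correlation matrix for a complete (no NA)
# voxels x clips matrix. Identical to spearman_similarity() pair by pair.
rank_correlation_matrix <- function(mat) {
  R <- apply(mat, 2, rank, ties.method = "average")
  R <- scale(R, center = TRUE, scale = FALSE)
  ss <- sqrt(colSums(R^2))
  C <- crossprod(R) / tcrossprod(ss)
  C[C > 1] <- 1
  C[C < -1] <- -1
  C
}

#' Build the long-format similarity table for a simulated study
#'
#' Runs the pairing engine and similarity statistic over every participant
#' and ROI: for each valid within-valence inter-movie pair, the Spearman
#' correlation of the two aligned voxel patterns is computed
#' (pairwise-complete over voxels), Fisher Z transformed, and emitted as one
#' row with all grouping labels. On the full design this produces 28 rows
#' per participant x ROI x valence (84 per participant x ROI).
#'
#' Clips with no stored pattern, and degenerate correlations, yield rows
#' with `NA` similarity rather than being dropped.
#'
#' @param patterns `roi_patterns` from [generate_patterns()], or a
#'   compatible list (`participants`, `patterns[[pid]][[roi]]`).
#' @param schedule `clip_schedule` (supplies film and valence labels).
#' @return Data frame with columns `participant_id`, `age_group`,
#'   `age_months`, `roi`, `valence`, `clip_a`, `clip_b`, `rho`, `z`,
#'   `n_voxels_used`.
#' @export
build_similarity_table <- function(patterns, schedule) {
  pairs <- valid_pairs(schedule)
  participants <- patterns$participants
  rois <- names(patterns$patterns[[1]])
  n_pairs <- nrow(pairs)
  blocks <- vector("list", nrow(participants) * length(rois))
  b <- 0L
  for (p in seq_len(nrow(participants))) {
    pid <- participants$participant_id[p]
    for (roi in rois) {
      mat <- patterns$patterns[[pid]][[roi]]
      rho <- rep(NA_real_, n_pairs)
      n_used <- rep(0L, n_pairs)
      have <- pairs$clip_a %in% colnames(mat) &
        pairs$clip_b %in% colnames(mat)
      if (any(have)) {
        sub <- mat[, unique(c(pairs$clip_a[have], pairs$clip_b[have])),
                   drop = FALSE]
        if (all(is.finite(sub))) {
          C <- rank_correlation_matrix(sub)
          rho[have] <- C[cbind(match(pairs$clip_a[have], colnames(sub)),
                               match(pairs$clip_b[have], colnames(sub)))]
          n_used[have] <- nrow(sub)
        } else {
          for (i in which(have)) {
            s <- spearman_similarity(mat[, pairs$clip_a[i]],
                                     mat[, pairs$clip_b[i]])
            rho[i] <- s$rho
            n_used[i] <- s$n_used
          }
        }
      }
      b <- b + 1L
      blocks[[b]] <- data.frame(
        participant_id = pid,
        age_group = participants$age_group[p],
        age_months = participants$age_months[p],
        roi = roi,
        valence = pairs$valence,
        clip_a = pairs$clip_a,
        clip_b = pairs$clip_b,
        rho = rho,
        z = fisher_z(rho),
        n_voxels_used = n_used,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Write / read a similarity table as TSV
#'
#' @param table Similarity data frame from [build_similarity_table()].
#' @param path File path.
#' @return `write_similarity_tsv` returns `path` invisibly;
#'   `read_similarity_tsv` returns the data frame.
#' @export
write_similarity_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity_tsv
#' @export
read_similarity_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
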