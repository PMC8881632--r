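#' Volume geometry: grid shape, voxel size and index-to-mm affine
#'
#' All mask and alignment operations work in a single common (MNI-like)
#' space described by a `volume_geometry`: a 3D grid shape, voxel sizes and
#' an invertible 4x4 affine mapping 0-based voxel indices to mm coordinates.
#'
#' @param shape Integer length-3 grid dimensions.
#' @param voxel_size_mm Numeric length-3 voxel edge lengths (> 0).
#' @param origin_mm mm coordinate of voxel `(0, 0, 0)`; ignored when a full
#'   `affine` is given.
#' @param affine Optional 4x4 affine; defaults to a diagonal scaling by
#'   `voxel_size_mm` plus `origin_mm`.
#' @return An object of class `volume_geometry`.
#' @export
volume_geometry <- function(shape, voxel_size_mm,
                            origin_mm = c(0, 0, 0), affine = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape > 0),
            length(voxel_size_mm) == 3, all(voxel_size_mm > 0))
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- voxel_size_mm
    affine[1:3, 4] <- origin_mm
  }
  stopifnot(all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  structure(list(shape = shape, voxel_size_mm = voxel_size_mm,
                 affine = affine), class = "volume_geometry")
}

# 0-based voxel indices (n x 3) -> mm coordinates (n x 3)
vox_to_mm <- function(geometry, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  h <- cbind(ijk, 1) %*% t(geometry$affine)
  h[, 1:3, drop = FALSE]
}

# mm coordinates -> continuous 0-based voxel indices
mm_to_vox <- function(geometry, mm) {
  mm <- matrix(as.numeric(mm), ncol = 3)
  h <- cbind(mm, 1) %*% t(solve(geometry$affine))
  h[, 1:3, drop = FALSE]
}

# all voxel centers of a geometry, as an (prod(shape) x 3) 0-based index grid
all_voxels <- function(geometry) {
  as.matrix(expand.grid(i = 0:(geometry$shape[1] - 1),
                        j = 0:(geometry$shape[2] - 1),
                        k = 0:(geometry$shape[3] - 1),
                        KEEP.OUT.ATTRS = FALSE))
}

new_roi_mask <- function(name, geometry, voxels) {
  voxels <- matrix(as.integer(voxels), ncol = 3)
  ord <- order(voxels[, 1], voxels[, 2], voxels[, 3])
  voxels <- voxels[ord, , drop = FALSE]
  colnames(voxels) <- c("i", "j", "k")
  structure(list(name = name, geometry = geometry, voxels = voxels),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("ROI mask '%s': %d voxels on a %s grid (%s mm)\n",
              x$name, nrow(x$voxels), paste(x$geometry$shape, collapse = "x"),
              paste(x$geometry$voxel_size_mm, collapse = "x")))
  invisible(x)
}

#' Spherical ROI mask around an MNI coordinate
#'
#' Includes every voxel whose center lies within `diameter_mm / 2` of the mm
#' center (ties at exactly the radius are included), plus always the voxel
#' containing the center itself, so a zero diameter yields exactly that voxel.
#'
#' @param center_mni_mm mm coordinate of the sphere center (e.g.
#'   `c(2, 46, -8)` for a ventromedial prefrontal seed).
#' @param diameter_mm Sphere diameter in mm (>= 0).
#' @param geometry A [volume_geometry()].
#' @param name Mask name.
#' @return An `roi_mask`.
#' @export
sphere_mask <- function(center_mni_mm, diameter_mm, geometry,
                        name = "sphere") {
  stopifnot(diameter_mm >= 0)
  center_vox <- round(mm_to_vox(geometry, center_mni_mm))
  if (any(center_vox < 0) || any(center_vox >= geometry$shape)) {
    stop(sprintf("sphere center [%s] mm falls outside the volume",
                 paste(center_mni_mm, collapse = ", ")))
  }
  grid <- all_voxels(geometry)
  mm <- vox_to_mm(geometry, grid)
  d2 <- (mm[, 1] - center_mni_mm[1])^2 + (mm[, 2] - center_mni_mm[2])^2 +
    (mm[, 3] - center_mni_mm[3])^2
  keep <- d2 <= (diameter_mm / 2)^2 + 1e-9
  voxels <- grid[keep, , drop = FALSE]
  voxels <- unique(rbind(voxels, matrix(center_vox, ncol = 3)))
  new_roi_mask(name, geometry, voxels)
}

#' Threshold a probabilistic atlas volume into an ROI mask
#'
#' @param prob_volume 3D array of per-voxel probabilities on a 0-100 scale.
#' @param threshold_pct Inclusive threshold: voxels with probability >=
#'   `threshold_pct` become members.
#' @param geometry A [volume_geometry()] matching `dim(prob_volume)`.
#' @param name Mask name.
#' @return An `roi_mask`.
#' @export
threshold_prob_mask <- function(prob_volume, threshold_pct, geometry,
                                name = "atlas") {
  stopifnot(all(dim(prob_volume) == geometry$shape))
  if (any(prob_volume < 0, na.rm = TRUE) ||
      any(prob_volume > 100, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 100]")
  }
  keep <- which(prob_volume >= threshold_pct, arr.ind = TRUE)
  if (nrow(keep) == 0) {
    stop(sprintf(paste0("thresholding at %.1f%% leaves no voxels in '%s'; ",
                        "use a lower threshold"), threshold_pct, name))
  }
  new_roi_mask(name, geometry, keep - 1L) # arr.ind is 1-based
}

#' Extract aligned ROI voxel vectors from per-clip beta volumes
#'
#' Pulls the mask's member voxels out of each clip's beta volume in a fixed
#' order (lexicographically sorted index triples), so the same anatomical
#' position occupies the same vector position for every clip. Non-finite
#' voxels are recorded as missing for that clip only, never dropped from the
#' shared coordinate index.
#'
#' @param beta_volumes Named list of 3D arrays (one per clip), all on the
#'   mask's geometry.
#' @param mask An `roi_mask`.
#' @return A voxels x clips matrix with `NA` at missing positions; row
#'   attribute `voxels` carries the index triples.
#' @export
align_patterns <- function(beta_volumes, mask) {
  stopifnot(is.list(beta_volumes), length(beta_volumes) >= 1,
            !is.null(names(beta_volumes)))
  for (nm in names(beta_volumes)) {
    d <- dim(beta_volumes[[nm]])
    for (ax in 1:3) {
      if (d[ax] != mask$geometry$shape[ax]) {
        stop(sprintf(
          "volume '%s' does not match the mask geometry on axis %d (%d vs %d)",
          nm, ax, d[ax], mask$geometry$shape[ax]))
      }
    }
  }
  lin <- 1L + mask$voxels[, 1] +
    mask$geometry$shape[1] * (mask$voxels[, 2] +
                                mask$geometry$shape[2] * mask$voxels[, 3])
  out <- vapply(beta_volumes, function(vol) {
    v <- vol[lin]
    v[!is.finite(v)] <- NA_real_
    v
  }, numeric(nrow(mask$voxels)))
  out <- matrix(out, nrow = nrow(mask$voxels),
                dimnames = list(NULL, names(beta_volumes)))
  attr(out, "voxels") <- mask$voxels
  out
}

#' Synthetic probabilistic atlas volume
#'
#' Builds a smooth probability field (0-100) with Gaussian falloff around one
#' or more mm centers — a stand-in, clearly synthetic, for a population atlas
#' such as the Harvard-Oxford subcortical maps, used so that the thresholding
#' path can be exercised without shipping third-party atlas data.
#'
#' @param geometry A [volume_geometry()].
#' @param centers_mm Matrix (n x 3) of blob centers in mm.
#' @param sigma_mm Gaussian falloff scale; the 50% contour sits at
#'   `sigma_mm * sqrt(2 log 2)` from a center.
#' @return 3D array of probabilities in `[0, 100]`.
#' @export
synthetic_prob_atlas <- function(geometry, centers_mm, sigma_mm = 6) {
  centers_mm <- matrix(as.numeric(centers_mm), ncol = 3)
  mm <- vox_to_mm(geometry, all_voxels(geometry))
  p <- rep(0, nrow(mm))
  for (c_i in seq_len(nrow(centers_mm))) {
    d2 <- (mm[, 1] - centers_mm[c_i, 1])^2 +
      (mm[, 2] - centers_mm[c_i, 2])^2 + (mm[, 3] - centers_mm[c_i, 3])^2
    p <- pmax(p, 100 * exp(-d2 / (2 * sigma_mm^2)))
  }
  array(p, dim = geometry$shape)
}

#' Demonstration study geometry and ROI masks
#'
#' A compact MNI-like 4 mm grid covering the medial prefrontal and
#' subcortical territory, with the three study masks: a 10 mm diameter
#' sphere at MNI `[2, 46, -8]` for vmPFC, and bilateral synthetic
#' probabilistic blobs thresholded at 50% for amygdala and nucleus
#' accumbens.
#'
#' @param voxel_mm Isotropic voxel size in mm.
#' @return List with `geometry` and `masks` (named list of `roi_mask`).
#' @export
study_geometry <- function(voxel_mm = 4) {
  geometry <- volume_geometry(
    shape = ceiling(c(92, 110, 80) / voxel_mm),
    voxel_size_mm = rep(voxel_mm, 3),
    origin_mm = c(-46, -60, -40)
  )
  amy_prob <- synthetic_prob_atlas(
    geometry, rbind(c(-24, -4, -18), c(24, -4, -18)), sigma_mm = 6)
  nacc_prob <- synthetic_prob_atlas(
    geometry, rbind(c(-10, 12, -8), c(10, 12, -8)), sigma_mm = 4.5)
  masks <- list(
    AMY = threshold_prob_mask(amy_prob, 50, geometry, name = "AMY"),
    NAcc = threshold_prob_mask(nacc_prob, 50, geometry, name = "NAcc"),
    vmPFC = sphere_mask(c(2, 46, -8), 10, geometry, name = "vmPFC")
  )
  list(geometry = geometry, masks = masks)
}

#' Write / read an ROI mask as a NIfTI-1 binary volume
#'
#' @param mask An `roi_mask`.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `write_mask_nifti` returns `path` invisibly; `read_mask_nifti`
#'   returns an `roi_mask` reconstructed from the on-disk volume.
#' @export
write_mask_nifti <- function(mask, path) {
  vol <- array(0L, dim = mask$geometry$shape)
  lin <- 1L + mask$voxels[, 1] +
    mask$geometry$shape[1] * (mask$voxels[, 2] +
                                mask$geometry$shape[2] * mask$voxels[, 3])
  vol[lin] <- 1L
  img <- RNifti::asNifti(vol)
  img <- RNifti::`sform<-`(img, structure(mask$geometry$affine, code = 4L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask_nifti
#' @param name Mask name to attach on read.
#' @export
read_mask_nifti <- function(path, name = "mask") {
  img <- RNifti::readNifti(path)
  affine <- structure(RNifti::xform(img), class = NULL)
  geometry <- volume_geometry(dim(img)[1:3],
                              voxel_size_mm = RNifti::pixdim(img)[1:3],
                              affine = matrix(affine, 4, 4))
  keep <- which(as.array(img) > 0.5, arr.ind = TRUE)
  new_roi_mask(name, geometry, keep - 1L)
}
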