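#' Intensity windowing of an attenuation volume
#'
#' Clips HU values to a window. The default window (-1024, 3071) spans the
#' physical 12-bit CT range, so it is the identity on real-world volumes;
#' normalization deliberately preserves HU calibration because the downstream
#' density descriptors (mean attenuation and attenuation heterogeneity) are
#' only meaningful on the native HU scale.
#'
#' @param volume an [attenuation_volume()].
#' @param clip_lo,clip_hi window bounds in HU, `clip_lo < clip_hi`.
#' @return an [attenuation_volume()] on the same grid.
#' @export
normalize_intensity <- function(volume, clip_lo = -1024, clip_hi = 3071) {
  stopifnot(inherits(volume, "attenuation_volume"))
  if (!(clip_lo < clip_hi)) stop("clip_lo must be < clip_hi")
  v <- volume$values
  v[v < clip_lo] <- clip_lo
  v[v > clip_hi] <- clip_hi
  attenuation_volume(v, volume$spacing, volume$origin)
}

#' Calcium segmentation by HU thresholding with an optional ROI constraint
#'
#' A voxel is calcified iff its attenuation is at or above the threshold
#' (inclusive; 130 HU is the conventional calcium cutoff on contrast CT) and,
#' when a region-of-interest mask is supplied, lies inside the ROI. The ROI
#' is the machine-readable stand-in for anatomical constraints such as
#' excluding adjacent bone.
#'
#' @param volume an [attenuation_volume()].
#' @param threshold HU cutoff, inclusive. Default 130.
#' @param roi optional [binary_mask()] on the same grid.
#' @return a [binary_mask()].
#' @export
threshold_calcium <- function(volume, threshold = 130, roi = NULL) {
  stopifnot(inherits(volume, "attenuation_volume"))
  m <- volume$values >= threshold
  if (!is.null(roi)) {
    stopifnot(inherits(roi, "binary_mask"))
    stopifnot_same_grid(volume, roi, "volume and roi")
    m <- m & roi$values
  }
  binary_mask(m, volume$spacing, volume$origin)
}

#' Morphological cleaning of a calcium mask
#'
#' Binary opening with a discrete ball (radius in voxels; radius 0 is a
#' no-op) followed by removal of connected components whose physical volume
#' is below a floor. Opening suppresses speckle from image noise at the
#' threshold boundary; the size floor removes sub-voxel debris. The result is
#' always a subset of the input mask.
#'
#' @param mask a [binary_mask()].
#' @param min_volume_mm3 minimum component volume retained, in mm^3.
#' @param opening_radius_voxels radius of the opening ball, in voxels.
#' @param connectivity adjacency used for the size filter.
#' @return a cleaned [binary_mask()].
#' @export
morphological_clean <- function(mask, min_volume_mm3 = 1.0,
                                opening_radius_voxels = 1,
                                connectivity = 26) {
  stopifnot(inherits(mask, "binary_mask"))
  if (min_volume_mm3 < 0) stop("min_volume_mm3 must be >= 0")
  if (opening_radius_voxels < 0) stop("opening_radius_voxels must be >= 0")
  connectivity <- check_connectivity(connectivity)
  d <- grid_dim(mask)
  m <- mask$values
  r <- as.integer(opening_radius_voxels)
  if (r > 0 && any(m)) {
    er <- morph_ball_cpp(as.logical(m), d, r, TRUE)
    op <- morph_ball_cpp(er, d, r, FALSE)
    # opening is contained in the original for a symmetric element, but the
    # subset contract is enforced explicitly to be safe at grid borders
    m <- array(op & m, d)
  }
  if (min_volume_mm3 > 0 && any(m)) {
    lab <- cc_label_cpp(as.logical(m), d, connectivity)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes * voxel_volume(mask) >= min_volume_mm3)
    m <- array(lab %in% keep, d)
  }
  binary_mask(m, mask$spacing, mask$origin)
}

#' 3D connected-component labeling of a binary mask
#'
#' Partitions the foreground into maximal connected sets under 6-, 18- or
#' 26-adjacency. Labels are assigned in decreasing component-volume order,
#' with ties broken by the smallest linear (column-major) voxel index, so the
#' labeling is deterministic across runs and platforms.
#'
#' @param mask a [binary_mask()].
#' @param connectivity 6, 18 or 26 (default). 26 merges corner-touching
#'   fragments into one cluster, matching the reading of a cluster as a
#'   single discrete calcification.
#' @return a [cluster_label_map()].
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "binary_mask"))
  connectivity <- check_connectivity(connectivity)
  lab <- cc_label_cpp(as.logical(mask$values), grid_dim(mask), connectivity)
  cluster_label_map(array(lab, grid_dim(mask)), connectivity,
                    mask$spacing, mask$origin)
}

#' One-call segmentation stage
#'
#' Windowing, thresholding, cleaning and labeling in pipeline order.
#'
#' @inheritParams threshold_calcium
#' @inheritParams morphological_clean
#' @param clip_lo,clip_hi HU window passed to [normalize_intensity()].
#' @return a [cluster_label_map()].
#' @export
segment_volume <- function(volume, threshold = 130, roi = NULL,
                           clip_lo = -1024, clip_hi = 3071,
                           min_volume_mm3 = 1.0, opening_radius_voxels = 1,
                           connectivity = 26) {
  v <- normalize_intensity(volume, clip_lo, clip_hi)
  m <- threshold_calcium(v, threshold, roi)
  m <- morphological_clean(m, min_volume_mm3, opening_radius_voxels, connectivity)
  label_components(m, connectivity)
}
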