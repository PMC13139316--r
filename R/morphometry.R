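#' Minimum oriented bounding box dimensions of a voxel point set
#'
#' Searches orientations built from the principal axes of the point cloud:
#' the raw principal-component frame, plus, for each principal axis taken as
#' the box axis, the in-plane rotation minimizing the area of the 2D
#' footprint (rotating calipers over the convex hull of the projected
#' points). The candidate box with minimal raw volume wins. Each extent is
#' the span of the projected voxel centres plus one mean voxel spacing, so a
#' single voxel has positive dimensions and a degenerate (collinear, planar)
#' cluster keeps a defined aspect ratio.
#'
#' The search is deterministic and rotation-equivariant (the candidate
#' frames rotate with the data), near-minimal rather than provably minimal.
#'
#' @param voxel_centers n x 3 matrix of world coordinates (mm).
#' @param spacing voxel spacing (mm), used only for the extent padding.
#' @return named numeric: `dim_max_mm`, `dim_mid_mm`, `dim_min_mm` (sorted
#'   descending).
#' @export
oriented_bounding_box <- function(voxel_centers, spacing = c(1, 1, 1)) {
  pts <- as.matrix(voxel_centers)
  if (nrow(pts) < 1) stop("value error: empty point set")
  pad <- mean(spacing)
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  if (nrow(pts) == 1) {
    dims <- rep(pad, 3)
  } else {
    ev <- eigen(crossprod(x) / nrow(x), symmetric = TRUE)$vectors
    frames <- list(ev)
    for (axis in 1:3) {
      w <- ev[, axis]
      uv <- ev[, setdiff(1:3, axis), drop = FALSE]
      p2 <- x %*% uv
      theta <- min_area_rect_angle(p2)
      rot2 <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
      frames[[axis + 1]] <- cbind(uv %*% rot2, w)
    }
    best <- NULL; best_vol <- Inf
    for (f in frames) {
      pr <- x %*% f
      ext <- unname(apply(pr, 2, function(v) diff(range(v))))
      vol <- prod(ext)
      if (vol < best_vol - 1e-12) { best_vol <- vol; best <- ext }
    }
    dims <- best + pad
  }
  dims <- sort(dims, decreasing = TRUE)
  c(dim_max_mm = dims[1], dim_mid_mm = dims[2], dim_min_mm = dims[3])
}

# Angle (radians) of the minimum-area enclosing rectangle of 2D points,
# via rotating calipers over hull edge directions. Degenerate sets (< 3
# distinct points, collinear) fall back to angle 0.
min_area_rect_angle <- function(p2) {
  up <- unique(round(p2, 12))
  if (nrow(up) < 3) return(0)
  h <- tryCatch(chull(up[, 1], up[, 2]), error = function(e) NULL)
  if (is.null(h) || length(h) < 3) return(0)
  hp <- up[h, , drop = FALSE]
  edges <- diff(rbind(hp, hp[1, , drop = FALSE]))
  angs <- unique(atan2(edges[, 2], edges[, 1]) %% (pi / 2))
  best_a <- 0; best_area <- Inf
  for (a in angs) {
    r <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    q <- hp %*% r
    area <- diff(range(q[, 1])) * diff(range(q[, 2]))
    if (area < best_area - 1e-12) { best_area <- area; best_a <- a }
  }
  -best_a
}

#' Eccentricity (elongation index) of a voxel point set
#'
#' The central second-moment (inertia) tensor of the voxel centres is
#' computed, regularized by the voxel self-moment (`spacing^2 / 12` per
#' axis, the second moment of a uniform box) so single-voxel and planar
#' clusters stay finite. With eigenvalues `l1 >= l2 >= l3`,
#' eccentricity `= sqrt(l1 / l3) - 1`: 0 for a sphere, about `r - 1` for an
#' `r:1:1` ellipsoid, and larger for lobed or asymmetric shapes because all
#' voxels (not just the bounding box) enter the moments.
#'
#' @inheritParams oriented_bounding_box
#' @return non-negative scalar.
#' @export
cluster_eccentricity <- function(voxel_centers, spacing = c(1, 1, 1)) {
  pts <- as.matrix(voxel_centers)
  if (nrow(pts) < 1) stop("value error: empty point set")
  x <- sweep(pts, 2, colMeans(pts))
  m <- crossprod(x) / nrow(pts) + diag(as.numeric(spacing)^2 / 12)
  lam <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  sqrt(lam[1] / lam[3]) - 1
}

#' Compactness (sphere-normalized surface index) of a component
#'
#' `compactness = A^(3/2) / (6 sqrt(pi) V)` with `V` the voxel-count volume
#' and `A` the area of the 0.5-level isosurface of the component's indicator
#' field. The indicator is pre-smoothed with a Gaussian (sigma 0.8 voxels)
#' before meshing by marching tetrahedra, which removes the staircase bias
#' of a binary isosurface (a raw binary mesh overestimates a sphere's area
#' by ~28%; the smoothed mesh is within 1%). The index is 1 for a continuum
#' sphere and grows with surface irregularity. Components thinner than two
#' voxels along some axis cannot be meshed reliably and fall back to the
#' voxel-face area with a warning.
#'
#' @param component_mask logical 3D array holding a single component.
#' @param spacing voxel spacing (mm).
#' @return scalar >= ~1.
#' @export
cluster_compactness <- function(component_mask, spacing = c(1, 1, 1)) {
  m <- component_mask
  if (!any(m)) stop("value error: empty component")
  vvol <- prod(spacing)
  v <- sum(m) * vvol
  idx <- which(m, arr.ind = TRUE)
  span <- apply(idx, 2, function(i) diff(range(i))) + 1
  if (any(span < 2)) {
    warning("component thinner than 2 voxels along an axis; ",
            "using voxel-face surface area")
    a <- face_area_cpp(as.logical(m), dim(m), as.numeric(spacing))
  } else {
    # crop to the bounding box plus margin to keep meshing local
    lo <- pmax(apply(idx, 2, min) - 2L, 1L)
    hi <- pmin(apply(idx, 2, max) + 2L, dim(m))
    sub <- m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    f <- gauss_smooth_cpp(as.numeric(sub), dim(sub), 0.8)
    a <- mt_area_iso(f, dim(sub), as.numeric(spacing))
  }
  a^1.5 / (6 * sqrt(pi) * v)
}

mt_area_iso <- function(field, dims, spacing) {
  mt_area_cpp(field, as.integer(dims), spacing, 0.5)
}

#' Mean attenuation and attenuation heterogeneity of a component
#'
#' `mu` is the arithmetic mean of the in-component HU values; `sigma` the
#' sample standard deviation (n - 1 denominator), 0 for a single voxel.
#'
#' @param component_mask logical 3D array.
#' @param volume an [attenuation_volume()] on the same grid.
#' @return named numeric `c(mu_hu, sigma_hu)`.
#' @export
attenuation_stats <- function(component_mask, volume) {
  stopifnot(inherits(volume, "attenuation_volume"))
  if (!identical(dim(component_mask), grid_dim(volume)))
    stop("shape error: component mask and volume grids differ")
  hu <- volume$values[component_mask]
  if (length(hu) < 1) stop("value error: empty component")
  c(mu_hu = mean(hu), sigma_hu = if (length(hu) > 1) sd(hu) else 0)
}

#' Per-cluster feature table
#'
#' Combines volume, oriented-bounding-box dimensions, aspect ratio,
#' eccentricity, compactness, attenuation statistics and world centroid for
#' every label of a cluster label map, one row per cluster ordered by label.
#'
#' @param labels a [cluster_label_map()].
#' @param volume the [attenuation_volume()] the labels were derived from.
#' @param plaque_id identifier copied into every row.
#' @param validate re-derive the component partition to check the label-map
#'   invariants before measuring (integrity error on violation).
#' @return data.frame with columns `plaque_id, cluster_id, volume_mm3,
#'   dim_max_mm, dim_min_mm, aspect_ratio, eccentricity, compactness, mu_hu,
#'   sigma_hu, centroid_x_mm, centroid_y_mm, centroid_z_mm, n_voxels`.
#' @export
compute_cluster_features <- function(labels, volume, plaque_id = "P001",
                                     validate = FALSE) {
  stopifnot(inherits(labels, "cluster_label_map"))
  stopifnot(inherits(volume, "attenuation_volume"))
  stopifnot_same_grid(labels, volume, "labels and volume")
  if (validate) validate_label_map(labels)
  k <- max(labels$labels)
  vvol <- voxel_volume(labels)
  rows <- vector("list", k)
  for (c in seq_len(k)) {
    sel <- labels$labels == c
    idx <- which(sel, arr.ind = TRUE)
    pts <- voxel_centers(labels, idx)
    obb <- oriented_bounding_box(pts, labels$spacing)
    att <- attenuation_stats(sel, volume)
    ctr <- colMeans(pts)
    rows[[c]] <- data.frame(
      plaque_id = plaque_id,
      cluster_id = c,
      volume_mm3 = nrow(idx) * vvol,
      dim_max_mm = unname(obb["dim_max_mm"]),
      dim_min_mm = unname(obb["dim_min_mm"]),
      aspect_ratio = unname(obb["dim_max_mm"] / obb["dim_min_mm"]),
      eccentricity = cluster_eccentricity(pts, labels$spacing),
      compactness = cluster_compactness(sel, labels$spacing),
      mu_hu = unname(att["mu_hu"]),
      sigma_hu = unname(att["sigma_hu"]),
      centroid_x_mm = ctr[1], centroid_y_mm = ctr[2], centroid_z_mm = ctr[3],
      n_voxels = nrow(idx),
      stringsAsFactors = FALSE)
  }
  if (k == 0)
    return(data.frame(plaque_id = character(), cluster_id = integer(),
                      volume_mm3 = numeric(), dim_max_mm = numeric(),
                      dim_min_mm = numeric(), aspect_ratio = numeric(),
                      eccentricity = numeric(), compactness = numeric(),
                      mu_hu = numeric(), sigma_hu = numeric(),
                      centroid_x_mm = numeric(), centroid_y_mm = numeric(),
                      centroid_z_mm = numeric(), n_voxels = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Per-plaque aggregation of cluster features
#'
#' Groups the cluster feature table by plaque and records the cluster count,
#' total and mean cluster volume, feature means, and the single-versus-multi
#' fragmentation flag (`is_multi` iff at least two clusters).
#'
#' @param features a data.frame from [compute_cluster_features()] (possibly
#'   row-bound over plaques).
#' @return data.frame with one row per plaque.
#' @export
aggregate_plaques <- function(features) {
  if (nrow(features) == 0)
    return(data.frame(plaque_id = character(), n_clusters = integer(),
                      total_volume_mm3 = numeric(),
                      mean_cluster_volume_mm3 = numeric(),
                      mean_eccentricity = numeric(),
                      mean_compactness = numeric(),
                      mean_mu_hu = numeric(), mean_sigma_hu = numeric(),
                      is_multi = logical(), stringsAsFactors = FALSE))
  sp <- split(features, features$plaque_id)
  out <- lapply(sp, function(g) data.frame(
    plaque_id = g$plaque_id[1],
    n_clusters = nrow(g),
    total_volume_mm3 = sum(g$volume_mm3),
    mean_cluster_volume_mm3 = mean(g$volume_mm3),
    mean_eccentricity = mean(g$eccentricity),
    mean_compactness = mean(g$compactness),
    mean_mu_hu = mean(g$mu_hu),
    mean_sigma_hu = mean(g$sigma_hu),
    is_multi = nrow(g) >= 2,
    stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$plaque_id), , drop = FALSE]
}
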