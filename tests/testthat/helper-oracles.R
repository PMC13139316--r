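# Independent oracles and phantom builders shared across the suite.
# These deliberately avoid the package's C++ kernels: labeling is checked
# against a breadth-first flood fill, morphology against an explicit
# neighbourhood scan, influence diagnostics against literal refits.

# Solid ball of radius r_vox (voxel units) inside a cubic grid.
ball_mask <- function(r_vox, pad = 4L) {
  n <- as.integer(2 * ceiling(r_vox) + 2 * pad)
  ctr <- (n + 1) / 2
  idx <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  m <- array(FALSE, c(n, n, n))
  m[idx[colSums((t(idx) - ctr)^2) <= r_vox^2, , drop = FALSE]] <- TRUE
  m
}

# Axis-aligned solid ellipsoid with semi-axes (voxel units), optional
# rotation applied to the body frame before voxelization.
ellipsoid_mask <- function(semi, pad = 4L, rotation = NULL) {
  half <- if (is.null(rotation)) semi else
    sapply(1:3, function(i) sqrt(sum((rotation[i, ] * semi)^2)))
  n <- as.integer(2 * ceiling(half) + 2 * pad)
  ctr <- (n + 1) / 2
  idx <- as.matrix(expand.grid(1:n[1], 1:n[2], 1:n[3]))
  q <- sweep(idx, 2, ctr)
  if (!is.null(rotation)) q <- q %*% rotation
  keep <- (q[, 1] / semi[1])^2 + (q[, 2] / semi[2])^2 + (q[, 3] / semi[3])^2 <= 1
  m <- array(FALSE, n)
  m[idx[keep, , drop = FALSE]] <- TRUE
  m
}

rotation_from_angles <- function(a, b, g) {
  rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  rz <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

conn_offsets_oracle <- function(connectivity) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  manh <- rowSums(abs(offs))
  if (connectivity == 6) offs <- offs[manh == 1, , drop = FALSE]
  if (connectivity == 18) offs <- offs[manh <= 2, , drop = FALSE]
  offs
}

# Breadth-first flood-fill labeling, frontier-vectorized.
bfs_label_oracle <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- conn_offsets_oracle(connectivity)
  lab <- array(0L, d)
  nextlab <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    nextlab <- nextlab + 1L
    lab[s] <- nextlab
    frontier <- s
    while (length(frontier) > 0) {
      cc <- arrayInd(frontier, d)
      nb <- integer(0)
      for (o in seq_len(nrow(offs))) {
        cand <- sweep(cc, 2, offs[o, ], "+")
        ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
          cand[, 2] >= 1 & cand[, 2] <= d[2] &
          cand[, 3] >= 1 & cand[, 3] <= d[3]
        if (any(ok)) {
          cnd <- cand[ok, , drop = FALSE]
          nb <- c(nb, cnd[, 1] + d[1] * (cnd[, 2] - 1) +
                    d[1] * d[2] * (cnd[, 3] - 1))
        }
      }
      nb <- unique(nb)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- nextlab
      frontier <- nb
    }
  }
  lab
}

# TRUE iff two labelings induce the same partition of the foreground.
same_partition <- function(lab_a, lab_b, mask) {
  a <- lab_a[mask]; b <- lab_b[mask]
  if (any(a == 0) || any(b == 0)) return(FALSE)
  pairs <- unique(cbind(a, b))
  nrow(pairs) == length(unique(a)) && nrow(pairs) == length(unique(b))
}

# Erosion/dilation by explicit neighbourhood scan (ball of given radius).
brute_morph_oracle <- function(mask, radius, erode) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-radius:radius, -radius:radius,
                                -radius:radius))
  offs <- offs[rowSums(offs^2) <= radius^2, , drop = FALSE]
  out <- array(FALSE, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    cand <- sweep(offs, 2, c(i, j, k), "+")
    ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
      cand[, 2] >= 1 & cand[, 2] <= d[2] &
      cand[, 3] >= 1 & cand[, 3] <= d[3]
    vals <- rep(FALSE, nrow(offs))
    vals[ok] <- mask[cand[ok, , drop = FALSE]]
    out[i, j, k] <- if (erode) all(vals) else any(vals)
  }
  out
}

# Downscaled cohort configuration for fast pipeline tests: smaller grid and
# volume range, same statistical structure as the default.
small_cohort_config <- function(n_plaques = 6, seed = 1L, ...) {
  cohort_config(n_plaques = n_plaques,
                grid_shape = c(64, 64, 64),
                volume_range_mm3 = c(15, 150),
                seed = seed, ...)
}

# Match extracted clusters to ground-truth records by centroid proximity;
# returns the merged table (one row per ground-truth cluster) or NULL if
# the matching is not 1:1.
match_clusters <- function(features, ground_truth) {
  out <- NULL
  for (p in unique(ground_truth$plaque_id)) {
    g <- ground_truth[ground_truth$plaque_id == p, , drop = FALSE]
    f <- features[features$plaque_id == p, , drop = FALSE]
    if (nrow(g) != nrow(f)) return(NULL)
    dmat <- outer(seq_len(nrow(f)), seq_len(nrow(g)), Vectorize(function(i, j)
      sqrt((f$centroid_x_mm[i] - g$true_center_x_mm[j])^2 +
           (f$centroid_y_mm[i] - g$true_center_y_mm[j])^2 +
           (f$centroid_z_mm[i] - g$true_center_z_mm[j])^2)))
    assign_ <- apply(dmat, 2, which.min)
    if (length(unique(assign_)) != nrow(g)) return(NULL)
    out <- rbind(out, cbind(f[assign_, , drop = FALSE],
                            g[, setdiff(names(g), "plaque_id"), drop = FALSE]))
  }
  out
}
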