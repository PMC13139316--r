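sp1 <- c(1, 1, 1)

test_that("OBB padding conventions: single voxel and collinear runs", {
  one <- matrix(c(1.0, 2.0, 3.0), 1, 3)
  d1 <- oriented_bounding_box(one, c(0.5, 0.5, 0.5))
  expect_equal(unname(d1), c(0.5, 0.5, 0.5))

  run <- cbind(c(0, 0.5, 1.0, 1.5), 0, 0)   # 4 collinear voxels, 0.5 mm apart
  d2 <- oriented_bounding_box(run, c(0.5, 0.5, 0.5))
  expect_equal(unname(d2), c(2.0, 0.5, 0.5), tolerance = 1e-12)
  expect_equal(unname(d2["dim_max_mm"] / d2["dim_min_mm"]), 4)
})

test_that("OBB dimensions are invariant under point-set rotation", {
  m <- ellipsoid_mask(c(10, 5, 3))
  pts <- which(m, arr.ind = TRUE) * 1.0
  base <- oriented_bounding_box(pts, sp1)
  set.seed(3)
  for (i in 1:5) {
    rot <- rotation_from_angles(runif(1, 0, pi), runif(1, 0, pi),
                                runif(1, 0, pi))
    got <- oriented_bounding_box(pts %*% t(rot), sp1)
    expect_lt(max(abs(got - base)), 1e-6)
  }
})

test_that("eccentricity follows the inertia-tensor closed forms", {
  ball <- which(ball_mask(8), arr.ind = TRUE) * 1.0
  expect_lte(cluster_eccentricity(ball, sp1), 0.05)

  # 2c:c:c ellipsoid: continuum moments give sqrt(l1/l3) = 2, eccentricity 1
  ell <- which(ellipsoid_mask(c(16, 8, 8)), arr.ind = TRUE) * 1.0
  expect_lt(abs(cluster_eccentricity(ell, sp1) - 1), 0.1)

  one <- matrix(c(2, 2, 2), 1, 3)
  expect_equal(cluster_eccentricity(one, sp1), 0)   # self-moment regularized
})

test_that("a lobed shape is more eccentric than its smooth envelope", {
  grid <- list(shape = c(72, 72, 72), spacing = c(0.5, 0.5, 0.5))
  single <- build_cluster_mask(c(6, 3, 3), rep(17.75, 3), grid = grid)
  lobed <- build_cluster_mask(c(6, 3, 3), rep(17.75, 3), n_lobes = 2,
                              lobe_offset_frac = 0.6, grid = grid, seed = 8)
  e_single <- cluster_eccentricity(which(single$values, arr.ind = TRUE) * 0.5,
                                   grid$spacing)
  e_lobed <- cluster_eccentricity(which(lobed$values, arr.ind = TRUE) * 0.5,
                                  grid$spacing)
  expect_gt(e_lobed, e_single)
})

test_that("compactness matches closed forms for cube and ball and grows with elongation", {
  cube <- array(FALSE, c(38, 38, 38)); cube[4:35, 4:35, 4:35] <- TRUE
  expect_lt(abs(cluster_compactness(cube, sp1) - sqrt(6 / pi)) / sqrt(6 / pi),
            0.08)

  ball <- ball_mask(16)
  cb <- cluster_compactness(ball, sp1)
  expect_gte(cb, 1.0); expect_lte(cb, 1.15)

  fam <- sapply(c(1, 1.5, 2, 3), function(e) {
    semi <- c(e, 1, 1) * (500 / e)^(1/3)   # constant-volume family
    cluster_compactness(ellipsoid_mask(semi), sp1)
  })
  expect_true(all(diff(fam) > 0))
})

test_that("thin components fall back to voxel-face area with a warning", {
  slab <- array(FALSE, c(10, 10, 3)); slab[2:9, 2:9, 2] <- TRUE
  expect_warning(c1 <- cluster_compactness(slab, sp1), "thinner")
  expect_gt(c1, 1)
})

test_that("attenuation statistics use the sample sd with the single-voxel convention", {
  arr <- array(0, c(3, 1, 1)); arr[] <- c(200, 300, 400)
  v <- attenuation_volume(arr, sp1)
  m <- array(TRUE, c(3, 1, 1))
  s <- attenuation_stats(m, v)
  expect_equal(unname(s["mu_hu"]), 300)
  expect_equal(unname(s["sigma_hu"]), 100)

  m1 <- array(FALSE, c(3, 1, 1)); m1[2, 1, 1] <- TRUE
  expect_equal(unname(attenuation_stats(m1, v)["sigma_hu"]), 0)

  vconst <- attenuation_volume(array(400, c(3, 1, 1)), sp1)
  expect_equal(unname(attenuation_stats(m, vconst)["sigma_hu"]), 0)

  bad <- attenuation_volume(array(0, c(2, 2, 2)), sp1)
  expect_error(attenuation_stats(m, bad), "shape error")
})

test_that("feature extraction handles empty maps and satisfies exact volume conservation", {
  sp05 <- c(0.5, 0.5, 0.5)
  lm0 <- cluster_label_map(array(0L, c(4, 4, 4)), 26, sp05)
  v0 <- attenuation_volume(array(100, c(4, 4, 4)), sp05)
  expect_equal(nrow(compute_cluster_features(lm0, v0)), 0)

  arr <- array(FALSE, c(8, 8, 8)); arr[3:4, 3:4, 3:4] <- TRUE
  arr[7, 7, 7] <- TRUE
  bm <- binary_mask(arr, sp05)
  lm <- label_components(bm)
  v <- attenuation_volume(array(300, c(8, 8, 8)), sp05)
  # the single-voxel cluster legitimately warns about the voxel-face fallback
  f <- suppressWarnings(compute_cluster_features(lm, v, validate = TRUE))
  expect_equal(nrow(f), 2)
  expect_equal(f$volume_mm3[1], 8 * 0.125)     # 2x2x2 cube -> 1 mm^3
  expect_equal(f$volume_mm3, f$n_voxels * 0.125)
  expect_equal(sum(f$volume_mm3), sum(arr) * 0.125)
  # centroid of the cube at indices 3:4: centres at 1.0 and 1.5 mm
  expect_equal(unname(unlist(f[1, c("centroid_x_mm", "centroid_y_mm",
                                    "centroid_z_mm")])),
               rep(1.25, 3))
})

test_that("shape descriptors are exactly invariant under grid-axis permutation", {
  m <- ellipsoid_mask(c(9, 5, 4))
  # pad to a cube so permutation keeps the array valid
  n <- max(dim(m))
  cube <- array(FALSE, c(n, n, n))
  cube[seq_len(dim(m)[1]), seq_len(dim(m)[2]), seq_len(dim(m)[3])] <- m
  f1 <- local({
    pts <- which(cube, arr.ind = TRUE) * 1.0
    c(cluster_eccentricity(pts, sp1),
      unname(oriented_bounding_box(pts, sp1)),
      cluster_compactness(cube, sp1))
  })
  perm <- aperm(cube, c(3, 1, 2))
  f2 <- local({
    pts <- which(perm, arr.ind = TRUE) * 1.0
    c(cluster_eccentricity(pts, sp1),
      unname(oriented_bounding_box(pts, sp1)),
      cluster_compactness(perm, sp1))
  })
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("isotropic scaling leaves shape descriptors stable while volume scales cubically", {
  small <- ellipsoid_mask(c(8, 4, 4))
  big <- ellipsoid_mask(c(16, 8, 8))
  psmall <- which(small, arr.ind = TRUE) * 1.0
  pbig <- which(big, arr.ind = TRUE) * 1.0
  vs <- sum(small); vb <- sum(big)
  expect_lt(abs(vb / vs - 8) / 8, 0.05)
  es <- cluster_eccentricity(psmall, sp1); eb <- cluster_eccentricity(pbig, sp1)
  expect_lt(abs(es - eb), 0.1)
  os <- oriented_bounding_box(psmall, sp1); ob <- oriented_bounding_box(pbig, sp1)
  expect_lt(abs(os[1] / os[3] - ob[1] / ob[3]), 0.15)
  cs <- cluster_compactness(small, sp1); cb <- cluster_compactness(big, sp1)
  expect_lt(abs(cs - cb), 0.1)
})

test_that("plaque aggregation records totals, means and the fragmentation flag", {
  f1 <- data.frame(plaque_id = "A", cluster_id = 1, volume_mm3 = 100,
                   eccentricity = 1, compactness = 2, mu_hu = 400,
                   sigma_hu = 100)
  a1 <- aggregate_plaques(f1)
  expect_equal(a1$total_volume_mm3, 100)
  expect_equal(a1$mean_cluster_volume_mm3, 100)
  expect_false(a1$is_multi)

  f2 <- data.frame(plaque_id = "B", cluster_id = 1:2, volume_mm3 = c(60, 40),
                   eccentricity = c(1, 2), compactness = c(2, 3),
                   mu_hu = c(400, 500), sigma_hu = c(100, 150))
  a2 <- aggregate_plaques(f2)
  expect_equal(a2$total_volume_mm3, 100)
  expect_equal(a2$mean_cluster_volume_mm3, 50)
  expect_true(a2$is_multi)
  expect_equal(a2$n_clusters, 2)
})

test_that("coalescing two equal clusters conserves total volume and doubles the mean", {
  sp05 <- c(0.5, 0.5, 0.5)
  grid <- list(shape = c(72, 72, 72), spacing = sp05)
  # two separated spheres
  m1 <- build_cluster_mask(c(3, 3, 3), c(8, 17.75, 17.75), grid = grid)
  m2 <- build_cluster_mask(c(3, 3, 3), c(26, 17.75, 17.75), grid = grid)
  apart <- binary_mask(m1$values | m2$values, sp05)
  v <- fill_attenuation(apart, 400, 400, noise_sd = 0, background = 60)
  f_apart <- compute_cluster_features(label_components(apart), v, "A")
  a_apart <- aggregate_plaques(f_apart)
  expect_equal(a_apart$n_clusters, 2)

  # same two spheres brought to (near-)tangency: they coalesce into one
  # cluster whose volume is the sum up to the tiny contact lens
  m3 <- build_cluster_mask(c(3, 3, 3), c(14.85, 17.75, 17.75), grid = grid)
  m4 <- build_cluster_mask(c(3, 3, 3), c(20.65, 17.75, 17.75), grid = grid)
  merged <- binary_mask(m3$values | m4$values, sp05)
  vm <- fill_attenuation(merged, 400, 400, noise_sd = 0, background = 60)
  f_merged <- compute_cluster_features(label_components(merged), vm, "A")
  a_merged <- aggregate_plaques(f_merged)
  expect_equal(a_merged$n_clusters, 1)
  # within voxelization error (~2-3% for radius-6-voxel spheres) plus the
  # tiny contact lens
  expect_lt(abs(a_merged$total_volume_mm3 - a_apart$total_volume_mm3) /
              a_apart$total_volume_mm3, 0.05)
  expect_gt(a_merged$mean_cluster_volume_mm3 /
              a_apart$mean_cluster_volume_mm3, 1.9)
})
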