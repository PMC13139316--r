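sp05 <- c(0.5, 0.5, 0.5)

test_that("intensity windowing clips, is the identity inside the window, and is idempotent", {
  v <- attenuation_volume(array(c(5000, -2000, 100, 300, 0, 130, 129, 60),
                                c(2, 2, 2)), sp05)
  w <- normalize_intensity(v)
  expect_equal(max(w$values), 3071)
  expect_equal(min(w$values), -1024)
  inside <- attenuation_volume(array(runif(27, -500, 1500), c(3, 3, 3)), sp05)
  expect_identical(normalize_intensity(inside)$values, inside$values)
  expect_identical(normalize_intensity(w)$values, w$values)
  expect_error(normalize_intensity(v, 100, 100), "clip_lo")
})

test_that("calcium threshold is inclusive at 130 HU and conjoins with the ROI", {
  arr <- array(60, c(4, 4, 4))
  arr[2, 2, 2] <- 130
  arr[3, 3, 3] <- 129
  arr[1, 1, 1] <- 500
  v <- attenuation_volume(arr, sp05)
  m <- threshold_calcium(v)
  expect_true(m$values[2, 2, 2])
  expect_false(m$values[3, 3, 3])
  expect_true(m$values[1, 1, 1])

  uniform129 <- attenuation_volume(array(129, c(3, 3, 3)), sp05)
  expect_equal(sum(threshold_calcium(uniform129)$values), 0)

  roi <- binary_mask(array(TRUE, c(4, 4, 4)), sp05)
  roi$values[1, 1, 1] <- FALSE
  mr <- threshold_calcium(v, roi = roi)
  expect_false(mr$values[1, 1, 1])   # 500 HU but outside ROI
  expect_true(mr$values[2, 2, 2])

  bad_roi <- binary_mask(array(TRUE, c(3, 3, 3)), sp05)
  expect_error(threshold_calcium(v, roi = bad_roi), "grid")
})

test_that("raising the threshold never grows the mask (voxelwise subset)", {
  set.seed(4)
  v <- attenuation_volume(array(runif(16^3, 0, 600), c(16, 16, 16)), sp05)
  lo <- threshold_calcium(v, 130)$values
  hi <- threshold_calcium(v, 200)$values
  expect_true(all(lo | !hi))
})

test_that("cleaning removes sub-floor components and is idempotent on solid shapes", {
  m <- array(FALSE, c(12, 12, 12))
  m[6, 6, 6] <- TRUE   # 0.125 mm^3 at 0.5 mm spacing
  bm <- binary_mask(m, sp05)
  expect_equal(sum(morphological_clean(bm, min_volume_mm3 = 1.0,
                                       opening_radius_voxels = 0)$values), 0)

  cube <- array(FALSE, c(14, 14, 14)); cube[3:12, 3:12, 3:12] <- TRUE
  bc <- binary_mask(cube, sp05)
  cleaned <- morphological_clean(bc, 1.0, 1)
  expect_true(all(!cleaned$values | cube))          # subset of input
  again <- morphological_clean(cleaned, 1.0, 1)
  expect_identical(again$values, cleaned$values)    # opening idempotence
})

test_that("opening matches a brute-force neighbourhood-scan oracle on speckle", {
  for (seed in 1:3) {
    set.seed(seed)
    m <- array(runif(16^3) < 0.25, c(16, 16, 16))
    bm <- binary_mask(m, sp05)
    got <- morphological_clean(bm, min_volume_mm3 = 0,
                               opening_radius_voxels = 1)$values
    er <- brute_morph_oracle(m, 1, erode = TRUE)
    want <- brute_morph_oracle(er, 1, erode = FALSE)
    expect_identical(got, array(want & m, dim(m)))
  }
})

test_that("cleaning never increases the component count", {
  set.seed(9)
  m <- array(runif(20^3) < 0.15, c(20, 20, 20))
  bm <- binary_mask(m, sp05)
  before <- max(label_components(bm)$labels)
  after_ <- max(label_components(morphological_clean(bm, 1.0, 1))$labels)
  expect_lte(after_, before)
})

test_that("face and corner adjacency follow the connectivity definition", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE; m[2, 1, 1] <- TRUE    # share a face
  bm <- binary_mask(m, sp05)
  expect_equal(max(label_components(bm, 6)$labels), 1)
  expect_equal(max(label_components(bm, 26)$labels), 1)

  m2 <- array(FALSE, c(4, 4, 4))
  m2[1, 1, 1] <- TRUE; m2[2, 2, 2] <- TRUE  # share only a corner
  bm2 <- binary_mask(m2, sp05)
  expect_equal(max(label_components(bm2, 26)$labels), 1)
  expect_equal(max(label_components(bm2, 6)$labels), 2)
})

test_that("labels are ordered by size with deterministic tie-breaking", {
  m <- array(FALSE, c(10, 10, 10))
  m[8:9, 8:9, 8:9] <- TRUE          # 8 voxels, late in scan order
  m[1, 1, 1] <- TRUE                # 1 voxel, first in scan order
  m[5, 5, 5] <- TRUE                # 1 voxel, later
  lm <- label_components(binary_mask(m, sp05))
  expect_equal(lm$labels[8, 8, 8], 1L)      # biggest first
  expect_equal(lm$labels[1, 1, 1], 2L)      # tie broken by linear index
  expect_equal(lm$labels[5, 5, 5], 3L)
  expect_silent(validate_label_map(lm))
})

test_that("random masks partition identically to the BFS oracle at 6 and 26 connectivity", {
  for (seed in 1:12) {
    set.seed(seed)
    m <- array(runif(16^3) < 0.2, c(16, 16, 16))
    bm <- binary_mask(m, sp05)
    for (conn in c(6, 26)) {
      got <- label_components(bm, conn)$labels
      want <- bfs_label_oracle(m, conn)
      expect_true(same_partition(got, want, m),
                  info = sprintf("seed %d conn %d", seed, conn))
    }
  }
})
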