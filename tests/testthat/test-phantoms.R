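test_that("copula sampler hits target Spearman couplings at large n", {
  marg <- list(a = function(p) qlnorm(p, 5, 1),
               b = function(p) qunif(p, 1, 4),
               c = function(p) qlnorm(p, 7, 0.3))
  idm <- diag(3); dimnames(idm) <- list(names(marg), names(marg))
  # average the pairwise rank correlations over 5 independent draws of
  # n = 2000: the sampling error of the mean is ~ sqrt(1/10000), so 0.05
  # is a 5-sigma bound on the population coupling being zero
  cms <- lapply(1:5, function(s) {
    x <- sample_coupled_parameters(2000, idm, marg, seed = s)
    cor(apply(x, 2, rank))
  })
  cm <- Reduce(`+`, cms) / length(cms)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.05)

  tg <- idm; tg[1, 2] <- tg[2, 1] <- 0.8
  y <- sample_coupled_parameters(2000, tg, marg, seed = 2)
  r12 <- cor(rank(y$a), rank(y$b))
  expect_gte(r12, 0.75); expect_lte(r12, 0.85)
})

test_that("Spearman couplings are invariant under strictly monotone marginals", {
  tg <- diag(3); tg[1, 2] <- tg[2, 1] <- 0.6
  m1 <- list(a = function(p) p, b = function(p) p, c = function(p) p)
  m2 <- list(a = function(p) exp(5 * p), b = function(p) log(p + 0.1),
             c = function(p) p^3)
  x1 <- sample_coupled_parameters(500, tg, m1, seed = 3)
  x2 <- sample_coupled_parameters(500, tg, m2, seed = 3)
  expect_equal(cor(rank(x1$a), rank(x1$b)), cor(rank(x2$a), rank(x2$b)))
})

test_that("non-positive-definite targets raise a configuration error naming a pair", {
  tg <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3,
               dimnames = list(c("u", "v", "w"), c("u", "v", "w")))
  expect_error(sample_coupled_parameters(10, tg, list(u = identity,
                                                      v = identity,
                                                      w = identity), 1),
               "not positive definite")
})

test_that("voxelized sphere volume matches the analytic ball within 5%", {
  grid <- list(shape = c(48, 48, 48), spacing = c(0.5, 0.5, 0.5))
  m <- build_cluster_mask(c(4, 4, 4), center_mm = c(11.75, 11.75, 11.75),
                          grid = grid)
  v_analytic <- 4 / 3 * pi * 4^3
  v_voxel <- sum(m$values) * prod(grid$spacing)
  expect_lt(abs(v_voxel - v_analytic) / v_analytic, 0.05)
})

test_that("a spherical single-lobe mask is symmetric under grid axis permutation", {
  grid <- list(shape = c(32, 32, 32), spacing = c(0.5, 0.5, 0.5))
  m <- build_cluster_mask(c(3, 3, 3), center_mm = rep(7.75, 3), grid = grid)$values
  expect_identical(m, aperm(m, c(2, 3, 1)))
  expect_identical(m, aperm(m, c(3, 1, 2)))
})

test_that("multi-lobe masks stay a single connected component", {
  grid <- list(shape = c(64, 64, 64), spacing = c(0.5, 0.5, 0.5))
  m <- build_cluster_mask(c(6, 4, 3), center_mm = rep(15.75, 3), n_lobes = 3,
                          lobe_offset_frac = 0.5, grid = grid, seed = 5)
  lab <- label_components(m)
  expect_equal(max(lab$labels), 1)
})

test_that("geometry and value errors are raised for impossible masks", {
  grid <- list(shape = c(20, 20, 20), spacing = c(0.5, 0.5, 0.5))
  expect_error(build_cluster_mask(c(8, 8, 8), center_mm = c(5, 5, 5),
                                  grid = grid), "geometry error")
  expect_error(build_cluster_mask(c(2, 1, 0), center_mm = c(5, 5, 5),
                                  grid = grid), "value error")
})

test_that("attenuation fill respects the core-periphery ramp contract", {
  m <- ball_mask(8)
  bm <- binary_mask(m, c(1, 1, 1))
  flat <- fill_attenuation(bm, 400, 400, noise_sd = 0, background = 60)
  expect_equal(sd(flat$values[m]), 0)
  expect_equal(unique(flat$values[m]), 400)

  ramp <- fill_attenuation(bm, 1000, 200, noise_sd = 0, background = 60)
  mu <- mean(ramp$values[m])
  expect_gt(mu, 200); expect_lt(mu, 1000)
  expect_gt(min(ramp$values[m]), 199.999)   # periphery at the edge value

  noisy <- fill_attenuation(bm, 400, 400, noise_sd = 30, background = 60,
                            seed = 2)
  expect_lt(abs(sd(noisy$values[m]) - 30) / 30, 0.1)

  empty <- binary_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 1))
  expect_error(fill_attenuation(empty, 400, 200), "empty mask")
})

test_that("interior depth increases attenuation toward the core", {
  m <- ball_mask(10)
  bm <- binary_mask(m, c(1, 1, 1))
  ramp <- fill_attenuation(bm, 1000, 200, noise_sd = 0, background = 60)
  d <- dim(m); ctr <- (d[1] + 1) / 2
  centre_val <- ramp$values[ctr, ctr, ctr]
  edge_idx <- which(m & !brute_morph_oracle(m, 1, erode = TRUE))
  expect_gt(centre_val, 990)                      # deepest voxel near core HU
  expect_lt(max(ramp$values[edge_idx]), centre_val)
})

test_that("degenerate cluster-count distribution yields exactly one cluster per plaque", {
  cfg <- small_cohort_config(n_plaques = 4, seed = 2,
                             cluster_count_probs = 1)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh$ground_truth), 4)
  expect_true(all(table(coh$ground_truth$plaque_id) == 1))
})

test_that("cohort generation is byte-identical under a fixed seed", {
  cfg <- small_cohort_config(n_plaques = 3, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$volumes, b$volumes)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("total cluster count stays within binomial sampling error of its expectation", {
  probs <- c(0.81, 0.12, 0.05, 0.02)
  n <- 60
  cfg <- small_cohort_config(n_plaques = n, seed = 21)
  coh <- generate_cohort(cfg)
  counts <- table(coh$ground_truth$plaque_id)
  expect_equal(sum(counts), nrow(coh$ground_truth))
  e_count <- sum(seq_along(probs) * probs)
  sd_count <- sqrt(sum((seq_along(probs) - e_count)^2 * probs))
  expect_lt(abs(mean(counts) - e_count), 3.5 * sd_count / sqrt(n))
  # cluster ids unique within plaque
  expect_false(any(duplicated(coh$ground_truth[, c("plaque_id", "cluster_id")])))
  # recorded axes honour a >= b >= c > 0
  gt <- coh$ground_truth
  expect_true(all(gt$true_axis_a_mm >= gt$true_axis_b_mm &
                  gt$true_axis_b_mm >= gt$true_axis_c_mm &
                  gt$true_axis_c_mm > 0))
})
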