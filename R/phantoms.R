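#' Configuration of a synthetic calcification cohort
#'
#' Describes the study conditions a generated cohort emulates: how many
#' plaques, how many clusters per plaque, the marginal distributions of
#' cluster volume, elongation and core attenuation, the rank couplings among
#' them, and the voxel grid each plaque volume is rendered on.
#'
#' Defaults reproduce the cohort structure the analysis is designed for:
#' 107 plaques with 1-4 clusters each (81% single-cluster), lognormal cluster
#' volumes with median about 172 mm^3, elongation with median about 2.2, a
#' dense core / less-dense periphery attenuation ramp, and Spearman couplings
#' of 0.8 (volume-elongation), 0.5 (volume-core attenuation) and 0.4
#' (elongation-core attenuation). Clusters in multi-cluster plaques draw
#' volumes scaled by `multi_volume_factor` (default 1/4), reflecting the
#' fragmentation phenotype in which multi-cluster plaques carry smaller
#' individual deposits.
#'
#' @param n_plaques number of plaques (one volume each).
#' @param cluster_count_probs probability vector over cluster counts 1..K;
#'   must be non-negative and sum to 1.
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_spacing_mm numeric length-3, mm per voxel.
#' @param target_spearman symmetric 3x3 matrix of target Spearman
#'   correlations over the generator parameters (volume, elongation,
#'   core_hu), unit diagonal, entries in \[-1, 1\]. The implied Gaussian
#'   copula correlation matrix must be positive definite.
#' @param volume_lognormal_params named numeric `c(meanlog, sdlog)` of cluster
#'   volume in mm^3.
#' @param volume_range_mm3 truncation bounds of the volume marginal.
#' @param elongation_lognormal_params `c(meanlog, sdlog)` of the major/minor
#'   axis ratio.
#' @param elongation_range truncation bounds (min/max axis ratio, >= 1).
#' @param attenuation_params list with `core_hu` (median core HU),
#'   `core_sdlog`, `core_range_hu` (truncation bounds of the core marginal),
#'   `edge_hu`, `noise_sd_hu`, `background_hu`.
#' @param multi_volume_factor multiplier on volumes drawn for clusters in
#'   multi-cluster plaques.
#' @param lobe_count_probs probability vector over lobes per cluster 1..L.
#' @param lobe_offset_frac lobe offset as a fraction of the major semi-axis.
#' @param threshold_hu segmentation threshold the cohort must be separable
#'   at: background strictly below, core strictly above.
#' @param seed integer master seed; every stochastic step derives from it.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_plaques = 107,
                          cluster_count_probs = c(0.81, 0.12, 0.05, 0.02),
                          grid_shape = c(88, 88, 88),
                          voxel_spacing_mm = c(0.5, 0.5, 0.5),
                          target_spearman = default_target_spearman(),
                          volume_lognormal_params = c(meanlog = log(172), sdlog = 1.4),
                          volume_range_mm3 = c(15, 800),
                          elongation_lognormal_params = c(meanlog = log(2.23), sdlog = 0.57),
                          elongation_range = c(1.05, 4.5),
                          attenuation_params = list(core_hu = 1000,
                                                    core_sdlog = 0.3,
                                                    core_range_hu = c(400, 2400),
                                                    edge_hu = 200,
                                                    noise_sd_hu = 25,
                                                    background_hu = 60),
                          multi_volume_factor = 0.25,
                          lobe_count_probs = 1,
                          lobe_offset_frac = 0.35,
                          threshold_hu = 130,
                          seed = 1L) {
  cfg <- list(n_plaques = as.integer(n_plaques),
              cluster_count_probs = as.numeric(cluster_count_probs),
              grid_shape = as.integer(grid_shape),
              voxel_spacing_mm = as.numeric(voxel_spacing_mm),
              target_spearman = as.matrix(target_spearman),
              volume_lognormal_params = volume_lognormal_params,
              volume_range_mm3 = as.numeric(volume_range_mm3),
              elongation_lognormal_params = elongation_lognormal_params,
              elongation_range = as.numeric(elongation_range),
              attenuation_params = attenuation_params,
              multi_volume_factor = as.numeric(multi_volume_factor),
              lobe_count_probs = as.numeric(lobe_count_probs),
              lobe_offset_frac = as.numeric(lobe_offset_frac),
              threshold_hu = as.numeric(threshold_hu),
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @export
default_target_spearman <- function() {
  m <- matrix(c(1.0, 0.8, 0.5,
                0.8, 1.0, 0.4,
                0.5, 0.4, 1.0), 3, 3,
              dimnames = list(c("volume", "elongation", "core_hu"),
                              c("volume", "elongation", "core_hu")))
  m
}

validate_cohort_config <- function(cfg) {
  p <- cfg$cluster_count_probs
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("cluster_count_probs must be non-negative and sum to 1")
  if (any(cfg$lobe_count_probs < 0) || abs(sum(cfg$lobe_count_probs) - 1) > 1e-9)
    stop("lobe_count_probs must be non-negative and sum to 1")
  check_spearman_target(cfg$target_spearman)
  ap <- cfg$attenuation_params
  if (!(ap$background_hu < cfg$threshold_hu))
    stop("background HU (", ap$background_hu,
         ") must be strictly below the segmentation threshold (",
         cfg$threshold_hu, ")")
  if (!(min(ap$core_range_hu) > cfg$threshold_hu))
    stop("core HU range must lie strictly above the segmentation threshold")
  if (!(ap$edge_hu <= min(ap$core_range_hu)))
    stop("edge HU must not exceed the minimum core HU")
  if (cfg$n_plaques < 1) stop("n_plaques must be >= 1")
  if (any(cfg$grid_shape < 8)) stop("grid_shape too small")
  if (cfg$volume_range_mm3[1] <= 0 || diff(cfg$volume_range_mm3) <= 0)
    stop("volume_range_mm3 must be positive and increasing")
  if (cfg$elongation_range[1] < 1 || diff(cfg$elongation_range) <= 0)
    stop("elongation_range must start at >= 1 and be increasing")
  invisible(cfg)
}

check_spearman_target <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("target_spearman must be a square matrix")
  if (max(abs(m - t(m))) > 1e-12) stop("target_spearman must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-12) stop("target_spearman must have unit diagonal")
  if (any(abs(m) > 1)) stop("target_spearman entries must lie in [-1, 1]")
  r <- spearman_to_pearson(m)
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    off <- abs(r); diag(off) <- 0
    ij <- which(off == max(off), arr.ind = TRUE)[1, ]
    nm <- if (!is.null(rownames(m))) rownames(m) else as.character(seq_len(nrow(m)))
    stop("configuration error: implied Gaussian-copula correlation matrix is ",
         "not positive definite; strongest constraint is the pair (",
         nm[ij[1]], ", ", nm[ij[2]], ")")
  }
  invisible(r)
}

# Exact Spearman -> Pearson conversion for a Gaussian copula.
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Sample parameters with prescribed Spearman couplings
#'
#' Draws `n` rows whose population Spearman correlation between any pair of
#' columns equals the target entry, via a Gaussian copula: target Spearman
#' values are converted to Pearson correlations (r = 2 sin(pi rho / 6), exact
#' for bivariate normals), a multivariate normal sample is drawn, and each
#' column is pushed through its marginal quantile function. Because the
#' marginals are applied as strictly monotone transforms, ranks (and hence
#' Spearman correlations) are untouched by the choice of marginal.
#'
#' @param n number of rows.
#' @param target_spearman symmetric target matrix (see [cohort_config()]).
#' @param marginals named list of quantile functions, one per column,
#'   each strictly increasing on (0, 1).
#' @param seed integer seed; the draw is deterministic given it.
#' @return data.frame with `n` rows and one column per marginal.
#' @export
sample_coupled_parameters <- function(n, target_spearman, marginals, seed) {
  k <- length(marginals)
  if (nrow(target_spearman) != k)
    stop("target_spearman must be ", k, " x ", k, " to match the marginals")
  r <- check_spearman_target(target_spearman)
  ch <- chol(r)
  z <- with_seed(seed, matrix(rnorm(n * k), n, k)) %*% ch
  u <- pnorm(z)
  out <- as.data.frame(lapply(seq_len(k), function(j) marginals[[j]](u[, j])))
  names(out) <- if (!is.null(names(marginals))) names(marginals)
                else paste0("param", seq_len(k))
  out
}

# Normalized interior depth of the true voxels of one component.
# The raw EDT measures distance to the nearest background voxel centre, but
# the component surface lies half a voxel closer (midway between the
# boundary voxel centre and the adjacent background centre). Subtracting
# that half-voxel offset makes the mean normalized depth nearly scale-free
# (a ball of any radius averages ~0.25), so mean attenuation does not pick
# up a spurious size dependence from the discretization.
ramp_fraction <- function(sel, depth, spacing) {
  d <- pmax(depth[sel] - min(spacing) / 2, 0)
  dmax <- max(d)
  if (dmax > 0) d / dmax else rep(0.5, length(d))
}

# The fragmentation condition (multi-cluster plaques draw volumes scaled by
# multi_volume_factor) mixes two volume scales in one cohort, which
# attenuates the pooled rank correlation between volume and the other
# parameters below the copula target. To plant the configured couplings in
# the *cohort*, the copula targets for the volume pairs are compensated
# upward by a deterministic fixed-point calibration on a large parameter
# draw (no voxel rendering involved). Errors if the required pre-scaling
# coupling is infeasible (implied copula matrix not positive definite).
calibrate_targets <- function(cfg, n_cal = 30000, iters = 6, cal_seed = 987654L) {
  f <- cfg$multi_volume_factor
  p_multi_cluster <- {
    k <- seq_along(cfg$cluster_count_probs)
    sum(k[k > 1] * cfg$cluster_count_probs[k > 1]) /
      sum(k * cfg$cluster_count_probs)
  }
  if (f == 1 || p_multi_cluster == 0) return(cfg$target_spearman)
  pre <- cfg$target_spearman
  lo <- cfg$volume_range_mm3[1]
  marg <- cohort_marginals(cfg)
  multi <- with_seed(cal_seed, runif(n_cal) < p_multi_cluster)
  feasible <- function(m) tryCatch({ check_spearman_target(m); TRUE },
                                   error = function(e) FALSE)
  for (it in seq_len(iters)) {
    pars <- sample_coupled_parameters(n_cal, pre, marg, seed = cal_seed + it)
    pars$volume[multi] <- pmax(pars$volume[multi] * f, lo)
    meas <- cor(apply(pars, 2, rank))
    adj <- cfg$target_spearman - meas
    # only the volume pairs are attenuated by the scaling
    adj[-1, -1] <- 0
    # damped update, projected back to the positive-definite region
    step <- 0.8
    repeat {
      cand <- pre + step * adj
      clip <- abs(cand) > 0.98 & row(cand) != col(cand)
      cand[clip] <- sign(cand[clip]) * 0.98
      if (feasible(cand)) break
      step <- step / 2
      if (step < 0.01) { cand <- pre; break }
    }
    pre <- cand
  }
  check_spearman_target(pre)
  pre
}

# Quantile function of a lognormal truncated to [lo, hi].
qlnorm_trunc <- function(meanlog, sdlog, lo, hi) {
  plo <- plnorm(lo, meanlog, sdlog)
  phi <- plnorm(hi, meanlog, sdlog)
  function(p) qlnorm(plo + p * (phi - plo), meanlog, sdlog)
}

cohort_marginals <- function(cfg, multi = FALSE) {
  vp <- cfg$volume_lognormal_params
  ep <- cfg$elongation_lognormal_params
  ap <- cfg$attenuation_params
  qvol <- qlnorm_trunc(vp[["meanlog"]], vp[["sdlog"]],
                       cfg$volume_range_mm3[1], cfg$volume_range_mm3[2])
  fvol <- if (multi) {
    f <- cfg$multi_volume_factor
    lo <- cfg$volume_range_mm3[1]
    function(p) pmax(qvol(p) * f, lo)
  } else qvol
  list(volume = fvol,
       elongation = qlnorm_trunc(ep[["meanlog"]], ep[["sdlog"]],
                                 cfg$elongation_range[1], cfg$elongation_range[2]),
       core_hu = qlnorm_trunc(log(ap$core_hu), ap$core_sdlog,
                              ap$core_range_hu[1], ap$core_range_hu[2]))
}

# Uniformly random rotation matrix (det +1) from the current RNG stream.
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Support radius of an ellipsoid (semi-axes s, rotation R) along unit d.
ellipsoid_support <- function(axes, rotation, d) {
  sqrt(sum((axes * drop(crossprod(rotation, d)))^2))
}

# Voxelize one ellipsoid into a logical array: voxel centre inside the
# (optionally rotated) ellipsoid. Only the bounding sub-grid is scanned.
voxelize_ellipsoid <- function(arr, spacing, origin, center, axes, rotation) {
  d <- dim(arr)
  half <- vapply(1:3, function(i)
    sqrt(sum((rotation[i, ] * axes)^2)), numeric(1))
  lo <- pmax(1L, floor((center - half - origin) / spacing) + 1L)
  hi <- pmin(d, ceiling((center + half - origin) / spacing) + 1L)
  if (any(lo > hi)) return(arr)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  idx <- as.matrix(expand.grid(ii, jj, kk))
  pts <- voxel_centers(list(spacing = spacing, origin = origin), idx)
  q <- sweep(pts, 2, center) %*% rotation   # body coordinates
  inside <- (q[, 1] / axes[1])^2 + (q[, 2] / axes[2])^2 + (q[, 3] / axes[3])^2 <= 1
  if (any(inside)) {
    sel <- idx[inside, , drop = FALSE]
    arr[sel] <- TRUE
  }
  arr
}

#' Build a (possibly lobed) ellipsoidal cluster mask
#'
#' The mask is the union of `n_lobes` ellipsoids: the first centred at
#' `center_mm` with semi-axes `axis_lengths_mm` (a >= b >= c), each further
#' lobe scaled by 0.6 and offset by `lobe_offset_frac * a` along a random
#' direction (seeded). Offsets are clamped so lobes always overlap the main
#' body, and the result is verified to be a single connected component.
#' Lobes model the local surface asymmetry of real deposits, which raises
#' eccentricity without changing the bounding box much.
#'
#' @param axis_lengths_mm semi-axes (a, b, c) in mm, a >= b >= c > 0.
#' @param center_mm world coordinates of the main ellipsoid centre.
#' @param n_lobes number of lobes (>= 1).
#' @param lobe_offset_frac lobe offset as a fraction of a.
#' @param grid list with `shape`, `spacing`, and optionally `origin`.
#' @param seed integer seed for the lobe directions.
#' @param rotation optional 3x3 rotation applied to the whole cluster.
#' @return a [binary_mask()].
#' @export
build_cluster_mask <- function(axis_lengths_mm, center_mm, n_lobes = 1,
                               lobe_offset_frac = 0.35,
                               grid = list(shape = c(64, 64, 64),
                                           spacing = c(0.5, 0.5, 0.5)),
                               seed = 1L, rotation = NULL) {
  axes <- as.numeric(axis_lengths_mm)
  if (any(axes <= 0)) stop("value error: axis lengths must be > 0")
  if (is.unsorted(rev(axes))) stop("axis lengths must satisfy a >= b >= c")
  if (n_lobes < 1) stop("n_lobes must be >= 1")
  shape <- as.integer(grid$shape)
  spacing <- as.numeric(grid$spacing)
  origin <- if (!is.null(grid$origin)) as.numeric(grid$origin) else c(0, 0, 0)
  if (is.null(rotation)) rotation <- diag(3)

  gmin <- origin - spacing   # one-voxel margin outside the first voxel centre
  gmax <- origin + (shape - 1) * spacing + spacing
  fits <- function(ctr, ax, rot) {
    half <- vapply(1:3, function(i) sqrt(sum((rot[i, ] * ax)^2)), numeric(1))
    all(ctr - half >= gmin + spacing) && all(ctr + half <= gmax - spacing)
  }
  if (!fits(center_mm, axes, rotation))
    stop("geometry error: ellipsoid exceeds grid bounds (needs >= 1 voxel margin)")

  arr <- array(FALSE, shape)
  arr <- voxelize_ellipsoid(arr, spacing, origin, center_mm, axes, rotation)
  lobe_geom <- list(list(center = center_mm, axes = axes, rotation = rotation))

  if (n_lobes > 1) {
    with_seed(seed, {
      for (l in seq_len(n_lobes - 1)) {
        lobe_axes <- 0.6 * axes
        placed <- FALSE
        for (try in 1:50) {
          d <- rnorm(3); d <- d / sqrt(sum(d^2))
          off_req <- lobe_offset_frac * axes[1]
          off_max <- 0.85 * (ellipsoid_support(axes, rotation, d) +
                             ellipsoid_support(lobe_axes, rotation, d))
          off <- min(off_req, off_max)
          ctr <- center_mm + off * d
          if (!fits(ctr, lobe_axes, rotation)) next
          arr <- voxelize_ellipsoid(arr, spacing, origin, ctr, lobe_axes, rotation)
          lobe_geom[[length(lobe_geom) + 1]] <-
            list(center = ctr, axes = lobe_axes, rotation = rotation)
          placed <- TRUE
          break
        }
        if (!placed)
          stop("geometry error: could not place lobe inside the grid; ",
               "use a larger grid")
      }
    })
  }
  if (!any(arr)) stop("geometry error: ellipsoid voxelizes to an empty mask")
  lab <- cc_label_cpp(as.logical(arr), shape, 26L)
  if (max(lab) != 1L)
    stop("geometry error: cluster mask is not a single connected component")
  out <- binary_mask(arr, spacing, origin)
  attr(out, "lobes") <- lobe_geom
  out
}

# Analytic core-periphery ramp for a lobed ellipsoidal cluster: for each
# voxel the normalized radial coordinate rho of the nearest-covering lobe is
# computed from the exact geometry, and the ramp fraction is max(1 - rho)
# over lobes, clipped to [0, 1]. E[1 - rho] over a solid ellipsoid is 1/4
# for any axes, so the mean ramp is scale- and shape-free by construction.
analytic_ramp <- function(mask, lobes) {
  sel <- which(mask$values)
  idx <- which(mask$values, arr.ind = TRUE)
  pts <- voxel_centers(mask, idx)
  frac <- rep(0, length(sel))
  for (lb in lobes) {
    q <- sweep(pts, 2, lb$center) %*% lb$rotation
    rho <- sqrt((q[, 1] / lb$axes[1])^2 + (q[, 2] / lb$axes[2])^2 +
                  (q[, 3] / lb$axes[3])^2)
    frac <- pmax(frac, pmin(pmax(1 - rho, 0), 1))
  }
  list(sel = sel, frac = frac)
}

#' Fill a cluster mask with a core-periphery attenuation ramp plus noise
#'
#' Inside the mask, attenuation ramps linearly with normalized interior
#' depth: `HU = mu_edge + (mu_core - mu_edge) * d / dmax`, where `d` is the
#' Euclidean distance from the voxel centre to the component surface and
#' `dmax` the component's maximum interior depth (computed per connected
#' component). The deepest voxels therefore reach `mu_core` while the
#' periphery sits near `mu_edge`, emulating deposits whose cores are more
#' mineralized than their recently deposited rims. Outside the mask the
#' field is `background`. Independent Gaussian noise (sd `noise_sd`) is
#' added everywhere.
#'
#' @param mask a non-empty [binary_mask()].
#' @param mu_core,mu_edge core and edge HU, `mu_core >= mu_edge`
#'   (recycled over components in label order if vectors).
#' @param noise_sd Gaussian noise sd in HU.
#' @param background background HU, strictly below `mu_edge`.
#' @param seed integer seed for the noise.
#' @return an [attenuation_volume()] on the mask's grid.
#' @export
fill_attenuation <- function(mask, mu_core, mu_edge, noise_sd = 0,
                             background = 60, seed = 1L) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$values)) stop("value error: empty mask")
  if (any(mu_core < mu_edge)) stop("mu_core must be >= mu_edge")
  if (any(mu_edge <= background)) stop("mu_edge must be > background")
  d <- grid_dim(mask)
  lab <- cc_label_cpp(as.logical(mask$values), d, 26L)
  k <- max(lab)
  mu_core <- rep_len(mu_core, k)
  mu_edge <- rep_len(mu_edge, k)
  depth <- edt_cpp(as.logical(mask$values), d, mask$spacing)
  vals <- array(background, d)
  for (c in seq_len(k)) {
    sel <- which(lab == c)
    frac <- ramp_fraction(sel, depth, mask$spacing)
    vals[sel] <- mu_edge[c] + (mu_core[c] - mu_edge[c]) * frac
  }
  if (noise_sd > 0)
    vals <- vals + with_seed(seed, array(rnorm(length(vals), 0, noise_sd), d))
  attenuation_volume(vals, mask$spacing, mask$origin)
}

#' Generate a synthetic cohort of plaque volumes with ground truth
#'
#' Draws per-plaque cluster counts, per-cluster parameters with the
#' configured rank couplings, renders each plaque as an attenuation volume
#' (clusters are randomly rotated prolate ellipsoids with a core-periphery
#' ramp, embedded in soft-tissue background with Gaussian noise), and
#' returns the volumes together with a ground-truth table. Clusters within
#' one plaque are placed with at least a two-voxel gap so the labeler can
#' resolve them. Fully reproducible from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return list with `volumes` (named list of [attenuation_volume()]),
#'   `ground_truth` (data.frame: plaque_id, cluster_id, true_volume_mm3,
#'   true_axis_a_mm/b/c, true_center_x/y/z_mm, true_core_hu, true_edge_hu,
#'   n_lobes; `true_volume_mm3` is the voxelized mask volume, the digital
#'   ground truth recovery is measured against), and `config`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  cfg <- config
  seeds <- derive_seeds(cfg$seed, 4 + cfg$n_plaques)
  counts <- with_seed(seeds[1], sample.int(length(cfg$cluster_count_probs),
                                           cfg$n_plaques, replace = TRUE,
                                           prob = cfg$cluster_count_probs))
  n_total <- sum(counts)
  is_multi_cluster <- rep(counts > 1L, counts)

  # one copula draw for the whole cohort, with targets compensated so the
  # post-scaling cohort carries the configured couplings; the multi-cluster
  # volume scaling is a monotone per-row transform applied afterwards
  pre_targets <- calibrate_targets(cfg)
  pars <- sample_coupled_parameters(n_total, pre_targets,
                                    cohort_marginals(cfg), seeds[2])
  if (any(is_multi_cluster)) {
    lo <- cfg$volume_range_mm3[1]
    pars$volume[is_multi_cluster] <-
      pmax(pars$volume[is_multi_cluster] * cfg$multi_volume_factor, lo)
  }
  lobes <- with_seed(seeds[3], sample.int(length(cfg$lobe_count_probs),
                                          n_total, replace = TRUE,
                                          prob = cfg$lobe_count_probs))

  spacing <- cfg$voxel_spacing_mm
  shape <- cfg$grid_shape
  origin <- c(0, 0, 0)
  extent <- (shape - 1) * spacing
  ap <- cfg$attenuation_params

  volumes <- vector("list", cfg$n_plaques)
  gt <- vector("list", cfg$n_plaques)
  row0 <- 0L
  for (p in seq_len(cfg$n_plaques)) {
    k <- counts[p]
    rows <- row0 + seq_len(k)
    row0 <- row0 + k
    pl <- render_plaque(pars[rows, , drop = FALSE], lobes[rows], cfg,
                        spacing, shape, origin, extent, seeds[4 + p])
    pid <- sprintf("P%03d", p)
    names(pl$records)[1] <- "cluster_id"
    gt[[p]] <- data.frame(plaque_id = pid, pl$records,
                          stringsAsFactors = FALSE)
    volumes[[p]] <- pl$volume
    names(volumes)[p] <- pid
  }
  names(volumes) <- sprintf("P%03d", seq_len(cfg$n_plaques))
  list(volumes = volumes,
       ground_truth = do.call(rbind, gt),
       config = cfg)
}

# Render one plaque: place k clusters, fill attenuation, return volume +
# ground-truth rows.
render_plaque <- function(pars, lobes, cfg, spacing, shape, origin, extent,
                          seed) {
  k <- nrow(pars)
  ap <- cfg$attenuation_params
  sub_seeds <- derive_seeds(seed, 3)
  gap <- 2.5 * mean(spacing)

  geom <- with_seed(sub_seeds[1], {
    axes_list <- vector("list", k)
    rot_list <- vector("list", k)
    centers <- matrix(NA_real_, k, 3)
    for (attempt in 1:200) {
      ok <- TRUE
      for (i in seq_len(k)) {
        v <- pars$volume[i]; e <- pars$elongation[i]
        cax <- (3 * v / (4 * pi * e))^(1/3)
        axes_list[[i]] <- c(e * cax, cax, cax)
        rot_list[[i]] <- random_rotation()
        half <- vapply(1:3, function(j)
          sqrt(sum((rot_list[[i]][j, ] * axes_list[[i]])^2)), numeric(1))
        margin <- half + 2 * spacing
        if (any(margin * 2 > extent)) { ok <- FALSE; break }
        centers[i, ] <- origin + margin +
          runif(3) * (extent - 2 * margin)
      }
      if (!ok) next
      if (k > 1) {
        for (i in seq_len(k - 1)) for (j in (i + 1):k) {
          d <- centers[j, ] - centers[i, ]
          dist <- sqrt(sum(d^2)); du <- d / dist
          need <- ellipsoid_support(axes_list[[i]], rot_list[[i]], du) +
                  ellipsoid_support(axes_list[[j]], rot_list[[j]], du) + gap
          if (dist < need) { ok <- FALSE; break }
        }
      }
      if (ok) break
    }
    if (!ok) stop("geometry error: could not place ", k,
                  " clusters after bounded retries; use a larger grid")
    list(axes = axes_list, rot = rot_list, centers = centers)
  })

  grid <- list(shape = shape, spacing = spacing, origin = origin)
  masks <- vector("list", k)
  mask_seeds <- derive_seeds(sub_seeds[2], k)
  for (i in seq_len(k)) {
    masks[[i]] <- build_cluster_mask(geom$axes[[i]], geom$centers[i, ],
                                     n_lobes = lobes[i],
                                     lobe_offset_frac = cfg$lobe_offset_frac,
                                     grid = grid, seed = mask_seeds[i],
                                     rotation = geom$rot[[i]])
  }
  # enforce >= 2-voxel separation at the voxel level
  if (k > 1) {
    dil <- lapply(masks, function(m)
      morph_ball_cpp(as.logical(m$values), shape, 1L, FALSE))
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      if (any(dil[[i]] & dil[[j]]))
        stop("geometry error: clusters too close after voxelization; ",
             "use a larger grid")
  }

  combined <- Reduce(`|`, lapply(masks, `[[`, "values"))
  lab_check <- cc_label_cpp(as.logical(combined), shape, 26L)
  if (max(lab_check) != k)
    stop("geometry error: placed clusters merged during voxelization")

  vals <- array(ap$background_hu, shape)
  for (i in seq_len(k)) {
    rmp <- analytic_ramp(masks[[i]], attr(masks[[i]], "lobes"))
    vals[rmp$sel] <- ap$edge_hu + (pars$core_hu[i] - ap$edge_hu) * rmp$frac
  }
  if (ap$noise_sd_hu > 0)
    vals <- vals + with_seed(sub_seeds[3],
                             array(rnorm(length(vals), 0, ap$noise_sd_hu), shape))

  vol <- attenuation_volume(vals, spacing, origin)
  vvol <- prod(spacing)
  records <- data.frame(
    cluster_id = seq_len(k),
    true_volume_mm3 = vapply(masks, function(m) sum(m$values) * vvol, numeric(1)),
    true_axis_a_mm = vapply(geom$axes, `[`, numeric(1), 1),
    true_axis_b_mm = vapply(geom$axes, `[`, numeric(1), 2),
    true_axis_c_mm = vapply(geom$axes, `[`, numeric(1), 3),
    true_center_x_mm = geom$centers[, 1],
    true_center_y_mm = geom$centers[, 2],
    true_center_z_mm = geom$centers[, 3],
    true_core_hu = pars$core_hu,
    true_edge_hu = ap$edge_hu,
    n_lobes = lobes)
  list(volume = vol, records = records)
}

#' Read or write a cohort configuration as JSON or YAML
#'
#' The document mirrors the [cohort_config()] field names; the target
#' Spearman matrix is stored as a list of rows. Format is chosen by file
#' extension (`.json`, `.yaml`/`.yml`).
#'
#' @param path file path.
#' @export
read_cohort_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else stop("unsupported config format: .", ext)
  m <- raw$target_spearman
  if (is.list(m)) m <- do.call(rbind, lapply(m, as.numeric))
  m <- unname(as.matrix(m))
  dimnames(m) <- list(c("volume", "elongation", "core_hu"),
                      c("volume", "elongation", "core_hu"))
  raw$target_spearman <- m
  vl <- unlist(raw$volume_lognormal_params)
  el <- unlist(raw$elongation_lognormal_params)
  do.call(cohort_config, c(raw[setdiff(names(raw),
            c("volume_lognormal_params", "elongation_lognormal_params"))],
          list(volume_lognormal_params = vl, elongation_lognormal_params = el)))
}

#' @rdname read_cohort_config
#' @param config a [cohort_config()].
#' @export
write_cohort_config <- function(config, path) {
  x <- unclass(config)
  x$target_spearman <- lapply(seq_len(nrow(config$target_spearman)),
                              function(i) unname(config$target_spearman[i, ]))
  x$volume_lognormal_params <- as.list(config$volume_lognormal_params)
  x$elongation_lognormal_params <- as.list(config$elongation_lognormal_params)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json")
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  else if (ext %in% c("yaml", "yml"))
    yaml::write_yaml(x, path)
  else stop("unsupported config format: .", ext)
  invisible(path)
}
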