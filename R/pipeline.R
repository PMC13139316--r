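#' Coupling and regression analysis of a cluster feature table
#'
#' The statistical stage of the pipeline: unadjusted and partial Spearman
#' correlation matrices over the six per-cluster features (volume, aspect
#' ratio, eccentricity, compactness, mean attenuation, attenuation
#' heterogeneity) with bootstrap confidence intervals and BH q-values;
#' restricted-cubic-spline fits with influence screening and Wald
#' nonlinearity tests for every feature pair that is significant (q < 0.05)
#' in the partial analysis; and the fragmentation comparisons.
#'
#' @param features per-cluster feature table ([compute_cluster_features()]).
#' @param plaques per-plaque summary table ([aggregate_plaques()]); derived
#'   from `features` when NULL.
#' @param n_boot bootstrap resamples for all confidence intervals.
#' @param seed integer seed for every stochastic step.
#' @param feature_cols analyzed feature columns.
#' @return list with `correlations` (unadjusted), `partial_correlations`,
#'   `rcs_fits` (list of `rcs_fit`), `rcs_table` (flat summary),
#'   `spline_predictions` (stacked prediction tables),
#'   `fragmentation` (see [compare_fragmentation()]), and
#'   `feature_summary` (median/IQR per feature).
#' @export
analyze_cohort <- function(features, plaques = NULL, n_boot = 1000,
                           seed = 1L,
                           feature_cols = c("volume_mm3", "aspect_ratio",
                                            "eccentricity", "compactness",
                                            "mu_hu", "sigma_hu")) {
  stopifnot(all(feature_cols %in% names(features)))
  if (is.null(plaques)) plaques <- aggregate_plaques(features)
  seeds <- derive_seeds(seed, 3)

  correlations <- coupling_matrix(features, feature_cols, partial = FALSE,
                                  n_boot = n_boot, seed = seeds[1])
  partial_correlations <- coupling_matrix(features, feature_cols,
                                          partial = TRUE, n_boot = n_boot,
                                          seed = seeds[2])

  sig <- partial_correlations[partial_correlations$q_value < 0.05, ,
                              drop = FALSE]
  rcs_fits <- list()
  preds <- list()
  for (i in seq_len(nrow(sig))) {
    fx <- sig$feature_x[i]; fy <- sig$feature_y[i]
    covs <- features[, setdiff(feature_cols, c(fx, fy)), drop = FALSE]
    fit <- tryCatch(
      fit_rcs_model(features[[fy]], features[[fx]], covariates = covs,
                    outcome = fy, exposure = fx),
      error = function(e) NULL)
    if (is.null(fit)) next
    nm <- paste(fy, "vs", fx)
    rcs_fits[[nm]] <- fit
    pr <- predict_rcs(fit, covariate_means = colMeans(covs))
    pr <- data.frame(model = nm, pr, stringsAsFactors = FALSE)
    preds[[nm]] <- pr
  }
  rcs_table <- if (length(rcs_fits) > 0) do.call(rbind, lapply(
    names(rcs_fits), function(nm) {
      f <- rcs_fits[[nm]]
      data.frame(model = nm, outcome = f$outcome, exposure = f$exposure,
                 knot1 = f$knots[1], knot2 = f$knots[2], knot3 = f$knots[3],
                 beta_linear = f$coefficients[["linear"]],
                 se_linear = f$se[["linear"]],
                 beta_nonlinear = f$coefficients[["nonlinear"]],
                 se_nonlinear = f$se[["nonlinear"]],
                 wald_chi2 = f$wald_chi2, p_nonlinear = f$p_nonlinear,
                 n_used = f$n_used,
                 n_excluded = length(f$excluded_indices),
                 stringsAsFactors = FALSE)
    })) else NULL

  fragmentation <- tryCatch(compare_fragmentation(plaques),
                            error = function(e) {
                              warning(conditionMessage(e))
                              NULL
                            })

  feature_summary <- do.call(rbind, lapply(feature_cols, function(f) {
    s <- summarize_median_iqr(features[[f]])
    data.frame(feature = f, median = s[["median"]], q1 = s[["q1"]],
               q3 = s[["q3"]], n = nrow(features), stringsAsFactors = FALSE)
  }))

  list(correlations = correlations,
       partial_correlations = partial_correlations,
       rcs_fits = rcs_fits, rcs_table = rcs_table,
       spline_predictions = if (length(preds)) do.call(rbind, c(preds,
         list(make.row.names = FALSE))) else NULL,
       fragmentation = fragmentation,
       feature_summary = feature_summary)
}

#' Run the synthetic-cohort pipeline end to end
#'
#' Orchestrates the stages `simulate` (phantom cohort + ground truth),
#' `segment` (threshold, clean, label each volume), `features` (per-cluster
#' morphometry and per-plaque aggregation) and `analyze` (coupling and
#' fragmentation statistics), writing each stage's artifacts under `outdir`
#' and a JSON run manifest echoing every parameter and seed. `all` runs the
#' four stages in order; on a synthetic configuration it needs no external
#' input. Later stages read the artifacts of earlier stages from `outdir`
#' and refuse with a dependency error when they are missing.
#'
#' @param config a [cohort_config()].
#' @param mode one of `"simulate"`, `"segment"`, `"features"`, `"analyze"`,
#'   `"all"`.
#' @param outdir output directory (created if needed).
#' @param n_boot bootstrap resamples in the analyze stage.
#' @param write_volumes write per-plaque NIfTI volumes and label maps
#'   (disable to save space; the CSV artifacts are always written).
#' @param threshold,min_volume_mm3,opening_radius_voxels,connectivity
#'   segmentation parameters (echoed to the manifest).
#' @return the run manifest, invisibly.
#' @export
run_pipeline <- function(config, mode = c("all", "simulate", "segment",
                                          "features", "analyze"),
                         outdir, n_boot = 1000, write_volumes = TRUE,
                         threshold = config$threshold_hu,
                         min_volume_mm3 = 1.0, opening_radius_voxels = 1,
                         connectivity = 26) {
  mode <- match.arg(mode)
  validate_cohort_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  vol_dir <- file.path(outdir, "volumes")
  lab_dir <- file.path(outdir, "labels")
  seg_params <- list(threshold = threshold, min_volume_mm3 = min_volume_mm3,
                     opening_radius_voxels = opening_radius_voxels,
                     connectivity = connectivity)
  manifest <- list(tool = "calcmorph",
                   version = as.character(packageVersion("calcmorph")),
                   mode = mode,
                   config = manifest_config(config),
                   seeds = list(master = config$seed,
                                analyze = derive_seeds(config$seed, 5)[5]),
                   parameters = seg_params,
                   n_boot = n_boot,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  stages <- if (mode == "all") c("simulate", "segment", "features", "analyze")
            else mode
  cohort <- NULL
  labels <- NULL

  if ("simulate" %in% stages) {
    cohort <- generate_cohort(config)
    write.csv(cohort$ground_truth, file.path(outdir, "ground_truth.csv"),
              row.names = FALSE)
    if (write_volumes) {
      dir.create(vol_dir, showWarnings = FALSE)
      for (nm in names(cohort$volumes))
        write_volume(cohort$volumes[[nm]],
                     file.path(vol_dir, paste0(nm, ".nii.gz")))
    }
  }

  if ("segment" %in% stages) {
    if (is.null(cohort)) {
      if (!dir.exists(vol_dir))
        stop("dependency error: no volumes found under ", vol_dir,
             "; run the simulate stage first")
      paths <- sort(list.files(vol_dir, pattern = "\\.nii(\\.gz)?$",
                               full.names = TRUE))
      cohort <- list(volumes = setNames(lapply(paths, read_volume),
                                        sub("\\.nii(\\.gz)?$", "",
                                            basename(paths))))
    }
    labels <- lapply(cohort$volumes, function(v)
      segment_volume(v, threshold = threshold,
                     min_volume_mm3 = min_volume_mm3,
                     opening_radius_voxels = opening_radius_voxels,
                     connectivity = connectivity))
    if (write_volumes) {
      dir.create(lab_dir, showWarnings = FALSE)
      for (nm in names(labels))
        write_volume(labels[[nm]],
                     file.path(lab_dir, paste0(nm, "_labels.nii.gz")))
    }
  }

  if ("features" %in% stages) {
    if (is.null(labels)) {
      if (!dir.exists(lab_dir) || !dir.exists(vol_dir))
        stop("dependency error: no label maps found under ", lab_dir,
             "; run the segment stage first")
      lpaths <- sort(list.files(lab_dir, pattern = "_labels\\.nii(\\.gz)?$",
                                full.names = TRUE))
      nms <- sub("_labels\\.nii(\\.gz)?$", "", basename(lpaths))
      labels <- setNames(lapply(lpaths, read_label_map, connectivity), nms)
      cohort <- list(volumes = setNames(lapply(
        file.path(vol_dir, paste0(nms, ".nii.gz")), read_volume), nms))
    }
    features <- do.call(rbind, lapply(names(labels), function(nm)
      compute_cluster_features(labels[[nm]], cohort$volumes[[nm]],
                               plaque_id = nm)))
    plaques <- aggregate_plaques(features)
    write.csv(features, file.path(outdir, "features.csv"), row.names = FALSE)
    write.csv(plaques, file.path(outdir, "plaques.csv"), row.names = FALSE)
  }

  if ("analyze" %in% stages) {
    fpath <- file.path(outdir, "features.csv")
    ppath <- file.path(outdir, "plaques.csv")
    if (!file.exists(fpath))
      stop("dependency error: ", fpath,
           " not found; run the features stage first")
    features <- read.csv(fpath, stringsAsFactors = FALSE)
    plaques <- if (file.exists(ppath))
      read.csv(ppath, stringsAsFactors = FALSE) else NULL
    res <- analyze_cohort(features, plaques, n_boot = n_boot,
                          seed = manifest$seeds$analyze)
    write.csv(res$correlations, file.path(outdir, "correlations.csv"),
              row.names = FALSE)
    write.csv(res$partial_correlations,
              file.path(outdir, "partial_correlations.csv"),
              row.names = FALSE)
    if (!is.null(res$rcs_table))
      write.csv(res$rcs_table, file.path(outdir, "rcs_fits.csv"),
                row.names = FALSE)
    if (!is.null(res$spline_predictions))
      write.csv(res$spline_predictions,
                file.path(outdir, "spline_predictions.csv"),
                row.names = FALSE)
    if (!is.null(res$fragmentation)) {
      write.csv(res$fragmentation$dichotomy,
                file.path(outdir, "group_comparisons.csv"),
                row.names = FALSE)
      if (!is.null(res$fragmentation$by_count))
        write.csv(res$fragmentation$by_count,
                  file.path(outdir, "group_comparisons_by_count.csv"),
                  row.names = FALSE)
      if (!is.null(res$fragmentation$pairwise))
        write.csv(res$fragmentation$pairwise,
                  file.path(outdir, "group_comparisons_pairwise.csv"),
                  row.names = FALSE)
    }
    write.csv(res$feature_summary, file.path(outdir, "feature_summary.csv"),
              row.names = FALSE)
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  csvs <- list.files(outdir, pattern = "\\.csv$", full.names = TRUE)
  manifest$artifact_digests <- as.list(tools::md5sum(csvs))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

manifest_config <- function(config) {
  x <- unclass(config)
  x$target_spearman <- lapply(seq_len(nrow(config$target_spearman)),
                              function(i) unname(config$target_spearman[i, ]))
  x$volume_lognormal_params <- as.list(config$volume_lognormal_params)
  x$elongation_lognormal_params <- as.list(config$elongation_lognormal_params)
  x
}
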