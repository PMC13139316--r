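#' Fragmentation phenotype comparisons
#'
#' Compares plaque-level features between single- and multi-cluster plaques
#' (the fragmentation dichotomy) with Mann-Whitney U tests, and, as a
#' sensitivity analysis, across exact cluster counts with Kruskal-Wallis
#' tests followed by Benjamini-Hochberg-adjusted pairwise Mann-Whitney
#' tests for the features whose Kruskal-Wallis p is below 0.05. Per-group
#' medians with interquartile ranges are reported for every feature.
#'
#' Count strata with fewer than `min_group` plaques are dropped from the
#' sensitivity analysis with a warning naming the stratum; the primary
#' dichotomy refuses with a group-size error when either side has fewer
#' than `min_group` plaques.
#'
#' @param plaques plaque summary table from [aggregate_plaques()].
#' @param features which plaque-level columns to compare (defaults to mean
#'   cluster volume, total volume, and the mean shape/density features).
#' @param min_group minimum plaques per compared group (default 2).
#' @return list with `dichotomy` (one row per feature: U, p, q across the
#'   feature family, group medians/IQRs), `by_count` (Kruskal-Wallis H and
#'   p per feature), and `pairwise` (BH-adjusted pairwise Mann-Whitney
#'   rows, only for features with Kruskal-Wallis p < 0.05).
#' @export
compare_fragmentation <- function(plaques,
                                  features = c("mean_cluster_volume_mm3",
                                               "total_volume_mm3",
                                               "mean_eccentricity",
                                               "mean_compactness",
                                               "mean_mu_hu",
                                               "mean_sigma_hu"),
                                  min_group = 2) {
  stopifnot(all(features %in% names(plaques)))
  single <- plaques[!plaques$is_multi, , drop = FALSE]
  multi <- plaques[plaques$is_multi, , drop = FALSE]
  if (nrow(single) < min_group || nrow(multi) < min_group)
    stop("group-size error: single-vs-multi comparison needs >= ", min_group,
         " plaques per group (single: ", nrow(single), ", multi: ",
         nrow(multi), ")")

  dich <- lapply(features, function(f) {
    mw <- mann_whitney_u(single[[f]], multi[[f]])
    ms <- summarize_median_iqr(single[[f]])
    mm <- summarize_median_iqr(multi[[f]])
    data.frame(feature = f, U = mw$U, p_value = mw$p_value,
               median_single = ms[["median"]], q1_single = ms[["q1"]],
               q3_single = ms[["q3"]], median_multi = mm[["median"]],
               q1_multi = mm[["q1"]], q3_multi = mm[["q3"]],
               n_single = nrow(single), n_multi = nrow(multi),
               stringsAsFactors = FALSE)
  })
  dich <- do.call(rbind, dich)
  dich$q_value <- bh_fdr(dich$p_value)

  counts <- sort(unique(plaques$n_clusters))
  sizes <- vapply(counts, function(k) sum(plaques$n_clusters == k), 1L)
  drop <- counts[sizes < min_group]
  if (length(drop) > 0)
    warning("dropping cluster-count strat", if (length(drop) > 1) "a" else "um",
            " with < ", min_group, " plaques: count ",
            paste(drop, collapse = ", "))
  counts <- counts[sizes >= min_group]

  by_count <- NULL
  pairwise <- NULL
  if (length(counts) >= 2) {
    kw_rows <- lapply(features, function(f) {
      gr <- lapply(counts, function(k) plaques[[f]][plaques$n_clusters == k])
      kw <- kruskal_wallis(gr)
      data.frame(feature = f, H = kw$H, p_value = kw$p_value,
                 n_strata = length(counts), stringsAsFactors = FALSE)
    })
    by_count <- do.call(rbind, kw_rows)
    sig <- by_count$feature[by_count$p_value < 0.05]
    if (length(sig) > 0) {
      prs <- combn(counts, 2)
      pw <- lapply(sig, function(f) {
        do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
          k1 <- prs[1, i]; k2 <- prs[2, i]
          a <- plaques[[f]][plaques$n_clusters == k1]
          b <- plaques[[f]][plaques$n_clusters == k2]
          mw <- mann_whitney_u(a, b)
          data.frame(feature = f, count_a = k1, count_b = k2, U = mw$U,
                     p_value = mw$p_value, stringsAsFactors = FALSE)
        }))
      })
      pairwise <- do.call(rbind, pw)
      # BH within each feature's family of pairwise tests
      pairwise$q_value <- unlist(lapply(split(pairwise$p_value,
                                              pairwise$feature)[unique(pairwise$feature)],
                                        bh_fdr), use.names = FALSE)
    }
  }
  list(dichotomy = dich, by_count = by_count, pairwise = pairwise)
}
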