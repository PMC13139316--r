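#!/usr/bin/env Rscript
# Stage 5: fragmentation phenotype.
#
# Compares single- versus multi-cluster plaques (Mann-Whitney U) on the
# plaque-level features and, as a sensitivity analysis, stratifies by exact
# cluster count (Kruskal-Wallis, BH-adjusted pairwise tests). The analyze
# stage already wrote the tables; this script reads and narrates them.

suppressPackageStartupMessages(library(calcmorph))

outdir <- "results/cohort"
gc_path <- file.path(outdir, "group_comparisons.csv")
if (!file.exists(gc_path))
  stop("run analysis/04_coupling_analysis.R first (missing ", gc_path, ")")

gc <- read.csv(gc_path)
cat(sprintf("Single- vs multi-cluster plaques (n = %d vs %d):\n",
            gc$n_single[1], gc$n_multi[1]))
for (i in seq_len(nrow(gc)))
  cat(sprintf("  %-26s single %.2f [%.2f-%.2f] vs multi %.2f [%.2f-%.2f], U = %.0f, p = %.2g\n",
              gc$feature[i], gc$median_single[i], gc$q1_single[i],
              gc$q3_single[i], gc$median_multi[i], gc$q1_multi[i],
              gc$q3_multi[i], gc$U[i], gc$p_value[i]))

kw_path <- file.path(outdir, "group_comparisons_by_count.csv")
if (file.exists(kw_path)) {
  kw <- read.csv(kw_path)
  cat("\nStratified by exact cluster count (Kruskal-Wallis):\n")
  for (i in seq_len(nrow(kw)))
    cat(sprintf("  %-26s H = %.2f, p = %.2g\n",
                kw$feature[i], kw$H[i], kw$p_value[i]))
}
pw_path <- file.path(outdir, "group_comparisons_pairwise.csv")
if (file.exists(pw_path)) {
  pw <- read.csv(pw_path)
  cat("\nPairwise (BH-adjusted) tests for significant features:\n")
  for (i in seq_len(nrow(pw)))
    cat(sprintf("  %s, %d vs %d clusters: q = %.2g\n",
                pw$feature[i], pw$count_a[i], pw$count_b[i], pw$q_value[i]))
}
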