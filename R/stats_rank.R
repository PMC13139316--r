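#' Spearman rank correlation with t-approximation p-value
#'
#' `rho` is the Pearson correlation of average-tie ranks; the two-sided
#' p-value uses `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom, with `|rho| = 1` returning the p = 0 limit.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, neither constant.
#' @return list with `rho` and `p_value`.
#' @export
spearman <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("undefined correlation: constant input")
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1 - 1e-15) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: q of the i-th smallest p is
#' `min over j >= i of p_(j) * m / j`, capped at 1 and mapped back to the
#' input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("value error: p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Bootstrap percentile confidence interval
#'
#' Resamples the rows of `rows` with replacement `n_boot` times, evaluates
#' `statistic` on each resample, and returns the empirical
#' `(1 - level) / 2` and `1 - (1 - level) / 2` percentiles. Resamples on
#' which the statistic is undefined (error or non-finite) are redrawn, up to
#' a bounded number of extra draws; if more than half of all draws fail the
#' data are declared degenerate.
#'
#' @param statistic function of a data.frame (or matrix) returning a scalar.
#' @param rows the data to resample (data.frame or matrix, >= 3 rows).
#' @param n_boot number of bootstrap resamples.
#' @param level confidence level.
#' @param seed integer seed; bounds are deterministic given it.
#' @return named numeric `c(lo, hi)`.
#' @export
bootstrap_percentile_ci <- function(statistic, rows, n_boot = 1000,
                                    level = 0.95, seed = 1L) {
  n <- nrow(rows)
  if (is.null(n) || n < 3) stop("need at least 3 rows")
  with_seed(seed, {
    vals <- numeric(n_boot)
    got <- 0L
    draws <- 0L
    max_draws <- 2L * n_boot
    while (got < n_boot && draws < max_draws) {
      draws <- draws + 1L
      idx <- sample.int(n, n, replace = TRUE)
      v <- tryCatch(statistic(rows[idx, , drop = FALSE]),
                    error = function(e) NA_real_)
      if (length(v) == 1 && is.finite(v)) {
        got <- got + 1L
        vals[got] <- v
      }
    }
    if (got < n_boot && got < draws / 2)
      stop("degenerate data: statistic undefined on more than half of the ",
           "bootstrap resamples")
    vals <- vals[seq_len(got)]
    alpha <- (1 - level) / 2
    ci <- quantile(vals, c(alpha, 1 - alpha), names = FALSE, type = 7)
    c(lo = ci[1], hi = ci[2])
  })
}

#' Partial Spearman correlation
#'
#' All variables are rank-transformed (average ties); the x- and y-ranks are
#' each residualized against the covariate ranks plus an intercept by least
#' squares, and the partial correlation is the Pearson correlation of the
#' residuals. The p-value uses a t-statistic on `n - k - 2` degrees of
#' freedom (`k` covariates); the confidence interval bootstraps complete
#' rows. With no covariates this reduces exactly to plain Spearman.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame (or NULL) of adjustment variables.
#' @param n_boot,level,seed bootstrap settings (see
#'   [bootstrap_percentile_ci()]); `n_boot = 0` skips the interval.
#' @return a one-row data.frame in the coupling-result layout: `feature_x`,
#'   `feature_y`, `rho`, `ci_lo`, `ci_hi`, `p_value`, `partial`,
#'   `adjusted_for`.
#' @export
partial_spearman <- function(x, y, covariates = NULL, n_boot = 1000,
                             level = 0.95, seed = 1L,
                             feature_x = "x", feature_y = "y") {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  if (k > 0 && nrow(covariates) != n)
    stop("covariates must have the same number of rows as x")
  if (n <= k + 2) stop("need n > number of covariates + 2")

  est <- function(xx, yy, cc) {
    rx <- rank(xx); ry <- rank(yy)
    if (k == 0) return(cor(rx, ry))
    rc <- vapply(cc, rank, numeric(length(xx)))
    qrc <- qr(cbind(1, rc))
    if (qrc$rank < ncol(rc) + 1) {
      bad <- qrc$pivot[(qrc$rank + 1):(ncol(rc) + 1)]
      badn <- c("(intercept)", colnames(rc))[bad]
      stop("collinearity error: covariate ranks are linearly dependent (",
           paste(badn, collapse = ", "), ")")
    }
    cor(qr.resid(qrc, rx), qr.resid(qrc, ry))
  }
  rho <- est(x, y, covariates)
  p <- if (abs(rho) >= 1 - 1e-15) 0 else {
    tstat <- rho * sqrt((n - k - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - k - 2)
  }
  ci <- c(lo = NA_real_, hi = NA_real_)
  if (n_boot > 0) {
    tab <- if (k == 0) data.frame(.x = x, .y = y)
           else cbind(data.frame(.x = x, .y = y), covariates)
    ci <- bootstrap_percentile_ci(function(d)
      est(d$.x, d$.y, if (k == 0) NULL else d[, -(1:2), drop = FALSE]),
      tab, n_boot = n_boot, level = level, seed = seed)
  }
  data.frame(feature_x = feature_x, feature_y = feature_y, rho = rho,
             ci_lo = unname(ci[1]), ci_hi = unname(ci[2]), p_value = p,
             partial = k > 0,
             adjusted_for = if (k == 0) "" else
               paste(colnames(covariates), collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Pairwise (partial) Spearman correlation matrix with FDR control
#'
#' Computes the Spearman correlation for every unordered pair of the listed
#' features, with bootstrap percentile confidence intervals, and adjusts the
#' family of p-values (all pairs in the matrix) by Benjamini-Hochberg. With
#' `partial = TRUE` each pair is adjusted for all remaining listed features.
#'
#' @param data data.frame holding the features.
#' @param features character vector of column names.
#' @param partial adjust each pair for the remaining features?
#' @param n_boot,level,seed bootstrap settings.
#' @return data.frame, one row per pair: `feature_x`, `feature_y`, `rho`,
#'   `ci_lo`, `ci_hi`, `p_value`, `q_value`, `partial`, `adjusted_for`.
#' @export
coupling_matrix <- function(data, features, partial = FALSE, n_boot = 1000,
                            level = 0.95, seed = 1L) {
  stopifnot(all(features %in% names(data)))
  prs <- combn(features, 2)
  seeds <- derive_seeds(seed, ncol(prs))
  rows <- lapply(seq_len(ncol(prs)), function(i) {
    fx <- prs[1, i]; fy <- prs[2, i]
    cov <- if (partial) data[, setdiff(features, c(fx, fy)), drop = FALSE]
           else NULL
    partial_spearman(data[[fx]], data[[fy]], cov, n_boot = n_boot,
                     level = level, seed = seeds[i],
                     feature_x = fx, feature_y = fy)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out[, c("feature_x", "feature_y", "rho", "ci_lo", "ci_hi", "p_value",
          "q_value", "partial", "adjusted_for")]
}

#' Mann-Whitney U test
#'
#' `U` counts the pairs `(a, b)` with `a > b` plus half the tied pairs.
#' The two-sided p-value is exact (full enumeration of group assignments)
#' for small samples, and otherwise uses the normal approximation with the
#' tie correction. The exact branch is taken when the smaller group has at
#' most 8 observations and the total number of assignments is enumerable
#' (`choose(n1 + n2, n1) <= 2e5`).
#'
#' @param a,b numeric vectors, both non-empty.
#' @return list with `U` and `p_value`.
#' @export
mann_whitney_u <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  u_stat <- function(aa, bb) {
    r <- rank(c(aa, bb))
    sum(r[seq_along(aa)]) - length(aa) * (length(aa) + 1) / 2
  }
  u <- u_stat(a, b)
  comb <- c(a, b)
  n <- n1 + n2
  exact_ok <- min(n1, n2) <= 8 && choose(n, min(n1, n2)) <= 2e5
  if (exact_ok) {
    ctr <- n1 * n2 / 2
    dev <- abs(u - ctr)
    sel <- combn(n, n1)
    us <- apply(sel, 2, function(ix) u_stat(comb[ix], comb[-ix]))
    p <- mean(abs(us - ctr) >= dev - 1e-9)
  } else {
    ties <- table(comb)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sig2 <= 0) stop("degenerate data: all values tied")
    z <- (u - n1 * n2 / 2) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
  }
  list(U = u, p_value = min(p, 1))
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-squared reference on `g - 1` degrees
#' of freedom (delegated to [stats::kruskal.test()]).
#'
#' @param groups list of at least two non-empty numeric vectors.
#' @return list with `H` and `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2 || any(vapply(groups, length, 1L) < 1))
    stop("need >= 2 non-empty groups")
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) < 2)
    stop("degenerate data: all values identical")
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  kt <- kruskal.test(vals, g)
  list(H = unname(kt$statistic), p_value = kt$p.value)
}

#' Median and interquartile range
#'
#' Linear-interpolation quantile convention (positions `(n - 1) p`,
#' R type 7).
#'
#' @param values numeric vector, length >= 1.
#' @return named numeric `c(median, q1, q3)`.
#' @export
summarize_median_iqr <- function(values) {
  if (length(values) < 1) stop("need at least one value")
  q <- quantile(values, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}
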