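#' Restricted cubic spline basis with 3 knots
#'
#' Harrell-normalized basis: column 1 is `x` itself; column 2 is
#' `[(x - t1)+^3 - (x - t2)+^3 (t3 - t1)/(t3 - t2)
#'   + (x - t3)+^3 (t2 - t1)/(t3 - t2)] / (t3 - t1)^2`.
#' The resulting spline is continuous with continuous first and second
#' derivatives and is linear outside `[t1, t3]`.
#'
#' @param x numeric vector.
#' @param knots strictly increasing numeric length-3 `(t1, t2, t3)`.
#' @return n x 2 matrix with columns `linear`, `nonlinear`.
#' @export
rcs_basis <- function(x, knots) {
  if (length(knots) != 3 || is.unsorted(knots, strictly = TRUE))
    stop("value error: knots must be 3 strictly increasing values")
  t1 <- knots[1]; t2 <- knots[2]; t3 <- knots[3]
  pp3 <- function(u) pmax(u, 0)^3
  nl <- (pp3(x - t1) - pp3(x - t2) * (t3 - t1) / (t3 - t2) +
           pp3(x - t3) * (t2 - t1) / (t3 - t2)) / (t3 - t1)^2
  cbind(linear = x, nonlinear = nl)
}

#' Regression influence diagnostics with union flagging
#'
#' Cook's distance, hat-diagonal leverage and standardized DFBETAS are
#' computed from a single OLS fit using the closed-form leave-one-out
#' identities. A row is flagged if any criterion exceeds its conventional
#' threshold: Cook's D > 4/n, leverage > 2p/n, max |DFBETAS| > 2/sqrt(n).
#'
#' @param design numeric model matrix including the intercept column.
#' @param y response vector.
#' @param cooks_threshold,leverage_threshold,dfbetas_threshold overrides of
#'   the default cutoffs.
#' @return object of class `influence_report`: per-row `cooks_d`,
#'   `leverage`, `max_abs_dfbetas`, the thresholds, per-criterion flag sets
#'   and their union `flagged`.
#' @export
influence_filter <- function(design, y, cooks_threshold = NULL,
                             leverage_threshold = NULL,
                             dfbetas_threshold = NULL) {
  design <- as.matrix(design)
  n <- nrow(design); p <- ncol(design)
  if (n <= p) stop("need more rows than design columns")
  if (qr(design)$rank < p)
    stop("collinearity error: design matrix is rank deficient")
  fit <- lm(y ~ design - 1)
  h <- unname(hatvalues(fit))
  s2 <- sum(residuals(fit)^2) / (n - p)
  if (s2 <= 1e-16 * max(var(y), .Machine$double.eps)) {
    # numerically perfect fit: residual-based diagnostics are exactly zero
    cd <- rep(0, n)
    dfb <- rep(0, n)
  } else {
    cd <- unname(cooks.distance(fit))
    dfb <- apply(abs(dfbetas(fit)), 1, max)
  }
  thr_c <- if (is.null(cooks_threshold)) 4 / n else cooks_threshold
  thr_h <- if (is.null(leverage_threshold)) 2 * p / n else leverage_threshold
  thr_d <- if (is.null(dfbetas_threshold)) 2 / sqrt(n) else dfbetas_threshold
  f_c <- which(cd > thr_c)
  f_h <- which(h > thr_h)
  f_d <- which(dfb > thr_d)
  structure(list(cooks_d = cd, leverage = h, max_abs_dfbetas = unname(dfb),
                 thresholds = c(cooks_d = thr_c, leverage = thr_h,
                                dfbetas = thr_d),
                 flagged_cooks = f_c, flagged_leverage = f_h,
                 flagged_dfbetas = f_d,
                 flagged = sort(union(union(f_c, f_h), f_d))),
            class = "influence_report")
}

#' @export
print.influence_report <- function(x, ...) {
  cat(sprintf("<influence_report> %d rows, %d flagged (Cook %d, leverage %d, DFBETAS %d)\n",
              length(x$cooks_d), length(x$flagged), length(x$flagged_cooks),
              length(x$flagged_leverage), length(x$flagged_dfbetas)))
  invisible(x)
}

#' Restricted-cubic-spline regression with Wald nonlinearity test
#'
#' Fits `y` by OLS on `[rcs_basis(x), covariates, intercept]` with the three
#' knots at empirical quantiles of `x` (default 0.10 / 0.50 / 0.90). When
#' influence screening is on, rows flagged by [influence_filter()] on the
#' initial fit are excluded and the model is refit exactly once on the
#' remainder. Nonlinearity is tested by the Wald statistic
#' `chi^2 = (beta_nonlinear / SE)^2` against a chi-squared distribution
#' with 1 degree of freedom.
#'
#' @param y outcome vector.
#' @param x exposure vector (needs >= 10 distinct values for knot
#'   placement).
#' @param covariates optional data.frame of additional linear terms.
#' @param knot_quantiles quantiles of `x` at which the knots sit.
#' @param influence_screen run the influence exclusion pass?
#' @param outcome,exposure labels carried into the result.
#' @return object of class `rcs_fit`: coefficients with standard errors,
#'   knots, `wald_chi2`, `p_nonlinear`, `n_used`, `excluded_indices` (empty
#'   when screening is off).
#' @export
fit_rcs_model <- function(y, x, covariates = NULL,
                          knot_quantiles = c(0.10, 0.50, 0.90),
                          influence_screen = TRUE,
                          outcome = "y", exposure = "x") {
  n <- length(y)
  if (length(x) != n) stop("x and y must have equal length")
  if (length(unique(x)) < 10)
    stop("knot-placement error: need at least 10 distinct exposure values")
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n <= (2 + k + 1) + 5) stop("too few observations for the model size")
  knots <- unname(quantile(x, knot_quantiles, type = 7))
  if (is.unsorted(knots, strictly = TRUE))
    stop("knot-placement error: knot quantiles are not distinct for this x")
  basis <- rcs_basis(x, knots)
  design <- cbind(`(Intercept)` = 1, basis,
                  if (k > 0) as.matrix(covariates))
  excluded <- integer(0)
  if (influence_screen) {
    rep_ <- influence_filter(design, y)
    excluded <- rep_$flagged
    if (length(excluded) > 0 && (n - length(excluded)) > ncol(design) + 2) {
      keep <- setdiff(seq_len(n), excluded)
      design <- design[keep, , drop = FALSE]
      y <- y[keep]
    } else excluded <- integer(0)
  }
  fit <- lm(y ~ design - 1)
  cf <- coef(fit)
  vc <- vcov(fit)
  se <- sqrt(diag(vc))
  names(cf) <- names(se) <- colnames(design)
  dimnames(vc) <- list(colnames(design), colnames(design))
  sig <- summary(fit)$sigma
  wald <- if (sig^2 <= 1e-16 * max(var(y), .Machine$double.eps)) 0
          else (cf[["nonlinear"]] / se[["nonlinear"]])^2
  structure(list(outcome = outcome, exposure = exposure,
                 covariates = if (k > 0) colnames(covariates) else character(0),
                 knots = knots, coefficients = cf, se = se, vcov = vc,
                 wald_chi2 = unname(wald),
                 p_nonlinear = pchisq(wald, df = 1, lower.tail = FALSE),
                 n_used = length(y), excluded_indices = excluded,
                 sigma = sig),
            class = "rcs_fit")
}

#' @export
print.rcs_fit <- function(x, ...) {
  cat(sprintf("<rcs_fit> %s ~ rcs(%s, knots %.3g/%.3g/%.3g)%s\n",
              x$outcome, x$exposure, x$knots[1], x$knots[2], x$knots[3],
              if (length(x$covariates)) paste0(" + ",
                paste(x$covariates, collapse = " + ")) else ""))
  cat(sprintf("  n_used %d (excluded %d), Wald chi2(nonlinear) = %.3f, p = %.4g\n",
              x$n_used, length(x$excluded_indices), x$wald_chi2,
              x$p_nonlinear))
  invisible(x)
}

#' Spline prediction table for plotting
#'
#' Fitted outcome over a grid of the exposure at the mean of each covariate,
#' with pointwise 95% confidence bounds from the coefficient covariance.
#'
#' @param fit an `rcs_fit`.
#' @param x_grid exposure values to predict at (default: 100 points across
#'   the knot span extended by 10%).
#' @param covariate_means named covariate values to hold fixed (defaults to
#'   0 for each; callers pass the training means).
#' @return data.frame `x`, `fitted`, `ci_lo`, `ci_hi`.
#' @export
predict_rcs <- function(fit, x_grid = NULL, covariate_means = NULL) {
  stopifnot(inherits(fit, "rcs_fit"))
  if (is.null(x_grid)) {
    span <- fit$knots[3] - fit$knots[1]
    x_grid <- seq(fit$knots[1] - 0.1 * span, fit$knots[3] + 0.1 * span,
                  length.out = 100)
  }
  basis <- rcs_basis(x_grid, fit$knots)
  xk <- matrix(0, length(x_grid), length(fit$covariates),
               dimnames = list(NULL, fit$covariates))
  if (!is.null(covariate_means))
    for (nm in intersect(names(covariate_means), fit$covariates))
      xk[, nm] <- covariate_means[[nm]]
  m <- cbind(1, basis, xk)
  est <- drop(m %*% fit$coefficients)
  v <- rowSums((m %*% fit$vcov) * m)   # pointwise prediction variance
  hw <- qnorm(0.975) * sqrt(v)
  data.frame(x = x_grid, fitted = est, ci_lo = est - hw, ci_hi = est + hw)
}
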