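test_that("Spearman is monotone-invariant and matches rank-Pearson with ties", {
  x <- sort(rnorm(20))
  expect_equal(spearman(x, exp(x))$rho, 1)
  expect_equal(spearman(x, -x)$rho, -1)
  expect_equal(spearman(x, exp(x))$p_value, 0)

  xt <- c(1, 2, 2, 3); yt <- c(10, 20, 20, 40)
  # hand-average ranks: x -> 1, 2.5, 2.5, 4; y -> 1, 2.5, 2.5, 4
  expect_equal(spearman(xt, yt)$rho, cor(c(1, 2.5, 2.5, 4), c(1, 2.5, 2.5, 4)))

  set.seed(5)
  for (i in 1:10) {
    a <- sample(1:6, 30, replace = TRUE)
    b <- a + sample(1:4, 30, replace = TRUE)
    s <- spearman(a, b)
    # oracle: t test of the Pearson correlation of the average ranks
    ct <- cor.test(rank(a), rank(b), method = "pearson")
    expect_equal(s$rho, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(s$p_value, ct$p.value, tolerance = 1e-10)
  }
  expect_error(spearman(rep(1, 5), 1:5), "constant")
})

test_that("BH adjustment reproduces the hand step-up and keeps its ordering property", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.03), 0.03)
  # independent step-up oracle
  bh_oracle <- function(p) {
    m <- length(p); o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  set.seed(8)
  for (i in 1:10) {
    p <- runif(sample(3:20, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p))
    expect_true(!is.unsorted(q[order(p)]))
  }
  expect_error(bh_fdr(c(0.2, 1.4)), "value error")
})

test_that("Mann-Whitney U follows the tie conventions and exact enumeration", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 1 / 3)

  a <- c(2, 5, 9)
  r2 <- mann_whitney_u(a, a)
  expect_equal(r2$U, length(a)^2 / 2)

  # direct pair-counting oracle for U, any data
  u_oracle <- function(a, b)
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  set.seed(3)
  for (i in 1:10) {
    a <- sample(1:5, sample(2:7, 1), replace = TRUE)
    b <- sample(1:5, sample(2:7, 1), replace = TRUE)
    expect_equal(mann_whitney_u(a, b)$U, u_oracle(a, b))
  }

  # tie-free exact p agrees with the exact Wilcoxon distribution
  for (i in 1:10) {
    set.seed(100 + i)
    a <- rnorm(sample(2:7, 1)); b <- rnorm(sample(2:7, 1))
    expect_equal(mann_whitney_u(a, b)$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  }

  # large samples use the tie-corrected normal approximation
  set.seed(4)
  a <- sample(1:10, 40, replace = TRUE); b <- sample(2:11, 35, replace = TRUE)
  got <- mann_whitney_u(a, b)
  ref <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("Kruskal-Wallis is label-invariant and consistent with Mann-Whitney at two groups", {
  set.seed(6)
  g1 <- rnorm(25); g2 <- rnorm(25, 0.5)
  kw <- kruskal_wallis(list(g1, g2))
  mw <- mann_whitney_u(g1, g2)
  expect_lt(abs(kw$p_value - mw$p_value), 0.02)
  expect_gte(kw$H, 0)
  expect_equal(kruskal_wallis(list(g2, g1))$H, kw$H)

  g3 <- rnorm(10); g4 <- rnorm(12); g5 <- rnorm(9)
  expect_equal(kruskal_wallis(list(g3, g4, g5))$H,
               kruskal_wallis(list(g5, g3, g4))$H)
  expect_error(kruskal_wallis(list(rep(1, 5), rep(1, 4))), "degenerate")
})

test_that("median/IQR summaries use the linear-interpolation convention", {
  s <- summarize_median_iqr(c(1, 2, 3, 4, 5))
  expect_equal(unname(s), c(3, 2, 4))
  expect_equal(unname(summarize_median_iqr(7)), c(7, 7, 7))
  set.seed(2)
  v <- rnorm(31)
  expect_equal(summarize_median_iqr(v + 5), summarize_median_iqr(v) + 5)
})

test_that("bootstrap percentile CI is deterministic and degenerates correctly", {
  d <- data.frame(x = rnorm(20))
  ci_const <- bootstrap_percentile_ci(function(dd) 3.5, d, n_boot = 50,
                                      seed = 1)
  expect_equal(unname(ci_const), c(3.5, 3.5))

  set.seed(9)
  d2 <- data.frame(x = rnorm(50), y = rnorm(50))
  f <- function(dd) cor(rank(dd$x), rank(dd$y))
  ci_a <- bootstrap_percentile_ci(f, d2, n_boot = 200, seed = 7)
  ci_b <- bootstrap_percentile_ci(f, d2, n_boot = 200, seed = 7)
  expect_identical(ci_a, ci_b)
  expect_lte(ci_a[1], ci_a[2])
})

test_that("partial Spearman reduces to plain Spearman and matches the precision-matrix oracle", {
  set.seed(11)
  x <- rnorm(60); y <- 0.5 * x + rnorm(60)
  expect_lt(abs(partial_spearman(x, y, NULL, n_boot = 0)$rho -
                spearman(x, y)$rho), 1e-12)

  z <- data.frame(c1 = 0.3 * x + rnorm(60), c2 = rnorm(60))
  got <- partial_spearman(x, y, z, n_boot = 0)$rho
  rmat <- cor(cbind(rank(x), rank(y), rank(z$c1), rank(z$c2)))
  pmat <- solve(rmat)
  expect_lt(abs(got - (-pmat[1, 2] / sqrt(pmat[1, 1] * pmat[2, 2]))), 1e-10)

  dup <- data.frame(c1 = x, c2 = 2 * x)   # rank-identical covariates
  expect_error(partial_spearman(rnorm(60), y, dup, n_boot = 0),
               "collinearity")
})

test_that("coupling matrix covers all pairs with a single BH family", {
  set.seed(13)
  d <- data.frame(a = rnorm(80), b = rnorm(80), c = rnorm(80), e = rnorm(80))
  d$b <- d$b + 1.2 * d$a
  cm <- coupling_matrix(d, c("a", "b", "c", "e"), n_boot = 100, seed = 3)
  expect_equal(nrow(cm), choose(4, 2))
  expect_equal(cm$q_value, bh_fdr(cm$p_value))
  ab <- cm[cm$feature_x == "a" & cm$feature_y == "b", ]
  expect_lt(ab$q_value, 0.05)
  expect_true(ab$ci_lo <= ab$rho && ab$rho <= ab$ci_hi)

  pm <- coupling_matrix(d, c("a", "b", "c"), partial = TRUE, n_boot = 0,
                        seed = 3)
  expect_true(all(pm$partial))
  expect_equal(pm$adjusted_for[pm$feature_x == "a" & pm$feature_y == "b"], "c")
})
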