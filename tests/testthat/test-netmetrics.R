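test_that("group_correlation matches hand-computed Pearson values", {
  x <- cbind(g1 = c(1, 2, 3, 4), g2 = c(1, 3, 2, 4), g3 = c(1, 2, 3, 4))
  net <- group_correlation(x, rep(TRUE, 4))
  # cov(x, y) = 4/3, sd = sqrt(5/3) each -> r = 4/5
  expect_equal(net[1, 2], 0.8)
  expect_equal(net[1, 3], 1.0)  # identical columns
  expect_equal(diag(unclass(net)), c(g1 = 0, g2 = 0, g3 = 0))
  expect_equal(unclass(net), t(unclass(net)))

  # independent columns stay near zero at large n
  xn <- rand_expr(5000, 2, seed = 20)
  netn <- group_correlation(xn, rep(TRUE, 5000))
  expect_lt(abs(netn[1, 2]), 0.05)

  xc <- cbind(g1 = c(1, 1, 1, 1), g2 = 1:4)
  expect_error(group_correlation(xc, rep(TRUE, 4)), "g1")
})

test_that("part_residuals implements full-sample OLS with orthogonal residuals", {
  x <- orthogonal_expr(50, 4, seed = 2)
  pr <- part_residuals(x)
  # zero sample correlation -> slope 0, residual is the centered column
  expect_lt(abs(pr$slopes[1, 2]), 1e-12)
  expect_equal(pr$residual(1, 2), x[, 1] - mean(x[, 1]), tolerance = 1e-12,
               ignore_attr = TRUE)

  # identical columns -> zero residual
  xd <- standardize_expression(cbind(g1 = rnorm(30), g2 = 1:30, g3 = (1:30)^2))
  xd <- cbind(xd, g4 = xd[, "g2"])
  pr2 <- suppressWarnings(part_residuals(xd))  # flag lost by cbind
  expect_lt(max(abs(pr2$residual(4, 2))), 1e-12)

  # OLS orthogonality for every ordered pair
  xs <- standardize_expression(rand_expr(40, 6, seed = 3))
  pr3 <- part_residuals(xs)
  for (j in 1:6) for (k in 1:6) {
    if (j == k) next
    expect_lt(abs(cor(xs[, k], pr3$residual(j, k))), 1e-10)
  }
})

test_that("part_residuals slopes are consistent for a linear signal", {
  set.seed(4)
  n <- 10000
  xk <- rnorm(n)
  xj <- 0.5 * xk + rnorm(n, sd = 0.1)
  pr <- suppressWarnings(part_residuals(cbind(gj = xj, gk = xk)))
  expect_gt(pr$slopes[1, 2], 0.48)
  expect_lt(pr$slopes[1, 2], 0.52)
})

test_that("part_correlation vanishes without truncation and matches group_correlation on orthogonal designs", {
  xs <- standardize_expression(rand_expr(200, 5, seed = 5))
  pr <- part_residuals(xs)
  full <- part_correlation(xs, rep(TRUE, 200), pr)
  expect_lt(max(abs(full)), 1e-10)

  # exactly orthogonal full-sample columns: part-correlation == correlation
  xo <- orthogonal_expr(60, 5, seed = 6)
  pro <- part_residuals(xo)
  mask <- c(rep(TRUE, 30), rep(FALSE, 30))
  expect_lt(max(abs(unclass(part_correlation(xo, mask, pro)) -
                      unclass(group_correlation(xo, mask)))), 1e-8)
})

test_that("part-correlations show the opposite-sign product-interaction pattern", {
  set.seed(7)
  n <- 20000
  xs <- standardize_expression(rand_expr(n, 3, seed = 7))
  y <- xs[, 1] * xs[, 2] + rnorm(n)
  groups <- assign_groups(y, a = 0.5, basis = "phenotype")
  pr <- part_residuals(xs)
  hi <- part_correlation(xs, groups$high, pr, group = "high")
  lo <- part_correlation(xs, groups$low, pr, group = "low")
  expect_gt(hi[1, 2], 0.05)
  expect_lt(lo[1, 2], -0.05)
  expect_lt(abs(hi[1, 2] + lo[1, 2]), 0.03)
})

test_that("a tail-disrupted pair produces a large group part-correlation contrast", {
  set.seed(8)
  n <- 20000
  xs <- standardize_expression(rand_expr(n, 4, seed = 8))
  y <- rnorm(n)
  xd <- apply_disruption(xs, y, list(list(pair = c(1L, 2L), sign = 1)),
                         cut_quantile = 4/5, seed = 9)
  groups <- assign_groups(y, a = 0.5, basis = "phenotype")
  pr <- part_residuals(standardize_expression(xd))
  xds <- standardize_expression(xd)
  hi <- part_correlation(xds, groups$high, pr, group = "high")
  lo <- part_correlation(xds, groups$low, pr, group = "low")
  # the disrupted pair stands far out of the null background
  expect_gt(abs(hi[1, 2] - lo[1, 2]), 0.2)
  null_contrast <- abs(hi[3, 4] - lo[3, 4])
  expect_lt(null_contrast, 0.05)
})

test_that("null pairs have vanishing differential correlation (invariant property)", {
  set.seed(9)
  n <- 4000
  xs <- standardize_expression(rand_expr(n, 8, seed = 9))
  y <- rnorm(n)  # independent of every pair
  groups <- assign_groups(y, a = 0.5, basis = "phenotype")
  hi <- group_correlation(xs, groups$high, group = "high")
  lo <- group_correlation(xs, groups$low, group = "low")
  d <- abs(unclass(hi) - unclass(lo))
  expect_lt(mean(d[upper.tri(d)]), 3 / sqrt(n / 2))
})

test_that("collinear interacting pairs are missed by dCCN but caught by dPCCN", {
  set.seed(10)
  n <- 5000
  x <- rand_expr(n, 4, seed = 10)
  x[, 1] <- x[, 2] + rnorm(n, sd = 0.25)
  y <- x[, 1] * x[, 2] + rnorm(n)
  xs <- standardize_expression(x)
  groups <- assign_groups(y, a = 0.5, basis = "phenotype")
  hi_c <- group_correlation(xs, groups$high, group = "high")
  lo_c <- group_correlation(xs, groups$low, group = "low")
  pr <- part_residuals(xs)
  hi_p <- part_correlation(xs, groups$high, pr, group = "high")
  lo_p <- part_correlation(xs, groups$low, pr, group = "low")
  dccn <- abs(hi_c[1, 2] - lo_c[1, 2])
  dpccn <- abs(hi_p[1, 2] - lo_p[1, 2])
  expect_lt(dccn, 0.1)   # truncation cannot break the strong correlation
  expect_gt(dpccn, dccn * 3)
})

test_that("a within-group zero-variance residual is zeroed with a warning", {
  x <- standardize_expression(cbind(g1 = rnorm(20), g2 = 1:20))
  x <- cbind(x, g3 = x[, "g2"])  # g3 duplicates g2 exactly
  pr <- suppressWarnings(part_residuals(x))
  expect_warning(net <- part_correlation(x, c(rep(TRUE, 10), rep(FALSE, 10)),
                                         pr),
                 "zero within-group residual variance")
  expect_equal(net[3, 2], 0)
})

test_that("is_zero implements both zero-decision rules", {
  hard <- zero_rule(r = 0.1)
  expect_true(is_zero(0.05, hard))
  expect_false(is_zero(0.15, hard))
  expect_true(is_zero(0, hard))
  expect_true(is_zero(-0.099, hard))
  expect_false(is_zero(-0.1, hard))  # strict inequality

  bonf <- zero_rule("bonferroni", alpha_level = 0.05, n_tests = 10)
  # oracle: p-value from cor.test on a constructed sample with that r
  expect_true(is_zero(0, bonf, n_group = 50))
  r <- 0.7; n <- 50
  p_oracle <- 2 * pt(abs(r * sqrt(n - 2) / sqrt(1 - r^2)), df = n - 2,
                     lower.tail = FALSE)
  expect_false(is_zero(r, bonf, n_group = n))
  expect_true(p_oracle < 0.05 / 10)
  # weak value: nonzero marginally but zero after correction
  expect_true(is_zero(0.28, bonf, n_group = 50))
  expect_error(is_zero(0.5, bonf, n_group = 2), "n_group")
  expect_error(is_zero(1.5, hard), "<= 1")
})
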