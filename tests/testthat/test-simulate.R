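test_that("generate_backbone produces standardized near-independent or block-correlated columns", {
  x <- generate_backbone(n = 5000, p = 6, seed = 21)
  expect_true(is_standardized(x))
  r <- cor(x); diag(r) <- 0
  expect_lt(max(abs(r)), 0.05)

  xb <- generate_backbone(n = 5000, p = 20, structure = "block",
                          block_size = 5, rho = 0.6, seed = 22)
  rb <- cor(xb)
  within <- rb[1:5, 1:5][upper.tri(diag(5))]
  across <- rb[1:5, 6:10]
  expect_true(all(abs(within - 0.6) < 0.05))
  expect_lt(max(abs(across)), 0.05)

  # default dimensions mirror a 191-patient x 231-protein panel
  xd <- generate_backbone(seed = 1)
  expect_equal(dim(xd), c(191L, 231L))

  # fixed seed reproduces bit-identically
  expect_identical(generate_backbone(n = 50, p = 5, seed = 3),
                   generate_backbone(n = 50, p = 5, seed = 3))
})

test_that("relu_term keeps products at or above their median", {
  expect_equal(relu_term(c(1, 1, 1, 1), c(1, 2, 3, 4)), c(0, 0, 3, 4))
  expect_equal(relu_term(c(2, 2), c(3, 3)), c(6, 6))  # all equal: all kept
  set.seed(23)
  out <- relu_term(rnorm(10000), rnorm(10000))
  expect_equal(sum(out != 0), 5000L)  # continuous products, even n
})

test_that("apply_collinearity induces the closed-form correlation", {
  x <- rand_expr(20000, 4, seed = 24)
  x0 <- apply_collinearity(x, list(c(1L, 2L)), noise_sd = 0, seed = 1)
  expect_equal(cor(x0[, 1], x0[, 2]), 1)

  x1 <- apply_collinearity(standardize_expression(x), list(c(1L, 2L)),
                           noise_sd = 0.25, seed = 2)
  # unit-variance source: cor = (1 + 0.0625)^(-1/2) ~ 0.970
  expect_lt(abs(cor(x1[, 1], x1[, 2]) - (1 + 0.0625)^(-0.5)), 0.01)
  # untouched columns unchanged
  expect_identical(x1[, 3], standardize_expression(x)[, 3])

  expect_error(apply_collinearity(x, list(c(1L, 2L), c(1L, 3L)), seed = 1),
               "overlapping")
  expect_error(apply_collinearity(x, list(c(2L, 2L)), seed = 1), "distinct")
})

test_that("apply_disruption modifies only the designated rows and columns", {
  x <- standardize_expression(rand_expr(20000, 4, seed = 25))
  set.seed(26)
  y <- rnorm(20000)
  xd <- apply_disruption(x, y, list(list(pair = c(1L, 2L), sign = -1)),
                         cut_quantile = 4/5, noise_sd = 0.25, seed = 3)
  cut <- quantile(y, 4/5, type = 7)
  hot <- y >= cut
  expect_identical(xd[!hot, 2], x[!hot, 2])    # untouched rows
  expect_identical(xd[, c(1, 3, 4)], x[, c(1, 3, 4)])  # untouched columns
  expect_lt(cor(xd[hot, 1], xd[hot, 2]), -0.9)  # induced negative correlation
  expect_lt(abs(cor(xd[!hot, 1], xd[!hot, 2])), 0.05)

  # degenerate cut leaves the matrix unchanged
  expect_identical(apply_disruption(x, y, list(list(pair = c(1L, 2L), sign = 1)),
                                    cut_quantile = 1), x)
})

test_that("model A assembles products, activation terms and disruptions with exact truth bookkeeping", {
  bb <- generate_backbone(n = 400, p = 60, seed = 27)
  sim <- simulate_model_a(bb, seed = 28)
  expect_length(sim$y, 400)
  expect_length(sim$truth$type1_pairs, 6L)
  expect_length(sim$truth$relu_pairs, 2L)
  expect_length(sim$truth$disrupted, 6L)
  expect_length(truth_pairs(sim$truth), 14L)
  expect_identical(simulate_model_a(bb, seed = 28)$y, sim$y)

  # with every participating column zeroed and no noise, y is identically 0
  x0 <- bb; x0[, 1:28] <- 0
  sim0 <- simulate_model_a(x0, seed = 1, noise_sd = 0, collinearity = FALSE)
  expect_true(all(sim0$y == 0))

  # variance closed form: only the noise term remains
  bb2 <- generate_backbone(n = 20000, p = 32, seed = 29)
  x2 <- bb2; x2[, 1:28] <- 0
  sim2 <- simulate_model_a(x2, seed = 2, noise_sd = 1.75, collinearity = FALSE)
  expect_lt(abs(var(sim2$y) - 1.75^2), 0.15)
})

test_that("the reference layout uses the full 231-gene panel", {
  cfg <- interaction_config(231)
  expect_equal(cfg$type1_pairs[[1]], c(75L, 150L))
  expect_equal(cfg$relu_pairs[[2]], c(109L, 54L))
  expect_equal(vapply(cfg$disrupted, function(d) d$sign, numeric(1)),
               c(-1, -1, -1, 1, 1, 1))
  expect_equal(cfg$main_idx, c(10L, 30L, 50L, 70L, 90L, 100L))
  bb <- generate_backbone(n = 191, p = 231, seed = 30)
  sim <- simulate_model_a(bb, seed = 31)
  expect_length(truth_pairs(sim$truth), 14L)
  # the collinearity overwrites take effect before the phenotype; column 125
  # is later partially overwritten by the C+(60,125) disruption, so its
  # induced correlation survives intact only below the disruption cut
  expect_gt(cor(sim$x[, 75], sim$x[, 150]), 0.9)
  cold <- sim$y < quantile(sim$y, 4/5, type = 7)
  expect_gt(cor(sim$x[cold, 125], sim$x[cold, 215]), 0.9)
})

test_that("model B adds six strong main effects recoverable by OLS", {
  bb <- generate_backbone(n = 20000, p = 60, seed = 32)
  cfg <- interaction_config(60)
  sim <- simulate_model_b(bb, seed = 33)
  expect_length(sim$truth$main_effects, 6L)
  expect_true(all(sim$truth$main_effects == 2))
  cf <- coef(lm(sim$y ~ sim$x[, cfg$main_idx]))[-1]
  expect_true(all(abs(cf - 2) < 0.1))

  # zeroing the main-effect columns reduces model B to model A plus noise
  x0 <- bb; x0[, cfg$main_idx] <- 0
  simA <- simulate_model_a(x0, seed = 34)
  simB <- simulate_model_b(x0, seed = 34)
  extra <- simB$y - simA$y
  expect_lt(abs(sd(extra) - 1.75), 0.05)
  expect_lt(abs(cor(extra, simA$y)), 0.05)
})

test_that("simulated replicates round-trip through the TSV/JSON writers", {
  skip_if_not_installed("jsonlite")
  bb <- generate_backbone(n = 50, p = 32, seed = 35)
  sim <- simulate_model_a(bb, seed = 36)
  prefix <- file.path(withr::local_tempdir(), "rep1")
  paths <- write_simulation(sim, prefix)
  expect_true(all(file.exists(paths)))
  x_back <- as.matrix(utils::read.table(paths[1], header = TRUE, sep = "\t"))
  expect_equal(unname(x_back), unname(sim$x), tolerance = 1e-10,
               ignore_attr = TRUE)
  tr <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  expect_equal(tr$noise_sd, 1.75)
})
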