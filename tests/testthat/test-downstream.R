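test_that("PCA eigenvalues sum to the total Procrustes variance and axes are
           retained to 95%", {
  set.seed(50)
  Y <- matrix(rnorm(30 * 12), 30)
  sh <- mat_shapes(Y)
  ord <- shape_pca(sh)
  expect_equal(sum(ord$eigenvalues),
               unname(procrustes_variance(Y, rep("g", 30))),
               tolerance = 1e-10)
  expect_gte(ord$cum_share[ord$k95], 0.95)
  if (ord$k95 > 1) expect_lt(ord$cum_share[ord$k95 - 1], 0.95)
  # score covariance (n divisor) reproduces the eigenvalues
  sc <- ord$scores_all
  expect_equal(colSums(sc^2) / nrow(sc), ord$eigenvalues, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(shape_pca(mat_shapes(Y[1:2, ])), "at least 3")
})

test_that("data on a line loads 100% on PC1", {
  set.seed(51)
  dir <- rnorm(12)
  Y <- rnorm(20) %o% dir
  ord <- shape_pca(mat_shapes(sweep(Y, 2, rnorm(12), "+")))
  expect_equal(ord$var_share[1], 1, tolerance = 1e-10)
  expect_equal(ord$k95, 1L)
})

test_that("PC1-PLS1 correlation handles identical, independent and mismatched
           scores", {
  set.seed(52)
  Y <- rmvn(50, block_corr(2, 2, 0.4, 0.4, 0.25))
  ord <- shape_pca(mat_shapes(Y))
  pls <- two_block_pls(Y, half_map(2, 2), n_perm = 99, seed = 1)
  out <- pc1_pls1_correlation(ord, pls)
  expect_equal(out$block, c("NC", "MD"))
  expect_true(all(out$r_abs >= 0 & out$r_abs <= 1))
  # perfectly aligned scores
  fake <- pls
  fake$x_scores <- ord$pc_scores[, 1]
  fake$y_scores <- -ord$pc_scores[, 1]   # sign must not matter
  aligned <- pc1_pls1_correlation(ord, fake)
  expect_equal(aligned$r_abs, c(1, 1), tolerance = 1e-12)
  # independent scores stay small on average
  fake2 <- pls
  fake2$x_scores <- rnorm(50); fake2$y_scores <- rnorm(50)
  indep <- pc1_pls1_correlation(ord, fake2)
  expect_true(all(indep$r_abs < 0.5))
  fake3 <- pls
  fake3$x_scores <- rnorm(10)
  expect_error(pc1_pls1_correlation(ord, fake3), "different lengths")
})

test_that("dispersion t-contrasts behave at the degenerate corners and detect
           a real module gap", {
  pairs <- paste0("pair", 1:6)
  grid <- expand.grid(pair = pairs, form = c("wild", "domestic"),
                      module = c("NC", "MD"), stringsAsFactors = FALSE)
  # identical values on both sides: t = 0, p = 1
  same <- transform(grid, value = 0.02)
  tt0 <- dispersion_ttests(same)
  expect_true(all(tt0$t == 0))
  expect_true(all(tt0$p_value == 1))
  # constant nonzero offset with zero noise: zero-variance error
  off <- transform(grid, value = ifelse(module == "MD", 0.03, 0.01))
  expect_error(dispersion_ttests(off), "zero variance")
  # MD ~4x NC with noise: module contrasts significant
  set.seed(53)
  noisy <- transform(grid, value = ifelse(module == "MD", 0.028, 0.007) *
                       exp(rnorm(nrow(grid), 0, 0.2)))
  tt <- dispersion_ttests(noisy)
  nc_md <- tt[tt$contrast == "NC vs MD (all forms)", ]
  expect_lt(nc_md$t, 0)
  expect_lt(nc_md$p_value, 0.01)
  expect_error(dispersion_ttests(noisy[noisy$pair == "pair1", ]),
               "at least 2 pairs")
})

test_that("disparity-integration regression recovers slopes and flags
           form-dependent ones", {
  set.seed(54)
  n <- 12
  disp <- runif(2 * n, 0.5, 1.5)
  form <- rep(c("wild", "domestic"), each = n)
  integ <- 0.3 + 2 * disp + rnorm(2 * n, 0, 1e-4)
  same <- disparity_integration_regression(disp, integ, form)
  expect_equal(unname(same$slopes), c(2, 2), tolerance = 1e-2)
  expect_gt(same$interaction_p, 0.5)
  expect_equal(same$interaction_df[2], 2 * n - 4)

  integ2 <- ifelse(form == "wild", 1, -1) * disp + rnorm(2 * n, 0, 0.02)
  diffslope <- disparity_integration_regression(disp, integ2, form)
  expect_lt(diffslope$interaction_p, 0.001)
  expect_lt(abs(diffslope$slopes["domestic"] + 1), 0.1)
  expect_true(is.finite(diffslope$var_F))

  expect_error(disparity_integration_regression(
    c(1, 2), c(1, 2), c("wild", "domestic")), "at least 2")
})
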