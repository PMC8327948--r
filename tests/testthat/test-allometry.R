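linear_shapes <- function(n, p, slope_scale = 1, noise = 0, seed = 20,
                          logsize = NULL, group = NULL) {
  set.seed(seed)
  if (is.null(logsize)) logsize <- rnorm(n, 5, 0.2)
  base <- as.vector(t(rand_config(p)))
  b <- rnorm(3 * p) * slope_scale
  Y <- rep(1, n) %o% base + logsize %o% b +
    matrix(rnorm(n * 3 * p, 0, noise), n)
  if (is.null(group)) group <- rep(c("wild", "domestic"), length.out = n)
  mat_shapes(Y, group = group, cs = exp(logsize))
}

test_that("an exact linear size-shape relation gives R2 = 1 and flat residuals", {
  sh <- linear_shapes(12, 5, noise = 0)
  fit <- procrustes_anova(sh, n_perm = 99, seed = 1)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_lt(fit$p_value, 0.05)
  # noise-free residual shapes are identical across specimens
  res <- allometry_residuals(fit)
  expect_lt(max(apply(cranmod:::flatten_coords(res$aligned), 2, sd)), 1e-10)
})

test_that("sums of squares decompose exactly and residuals are size-orthogonal", {
  sh <- linear_shapes(25, 6, slope_scale = 0.3, noise = 0.5, seed = 21)
  fit <- procrustes_anova(sh, n_perm = 99, seed = 2)
  expect_equal(fit$ss_model + fit$ss_resid, fit$ss_total,
               tolerance = 1e-8 * fit$ss_total)
  refit <- procrustes_anova(allometry_residuals(fit), n_perm = 99, seed = 3)
  expect_lt(refit$r_squared, 1e-10)
  # recentre toggles the grand mean exactly
  r_on <- allometry_residuals(fit, recentre = TRUE)
  r_off <- allometry_residuals(fit, recentre = FALSE)
  diff <- cranmod:::flatten_coords(r_on$aligned) -
    cranmod:::flatten_coords(r_off$aligned)
  expect_equal(diff, rep(1, 25) %o% fit$grand_mean, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("permutation p-values are seed-reproducible and match exhaustive
           enumeration at small n", {
  sh <- linear_shapes(6, 4, slope_scale = 0.15, noise = 0.3, seed = 22)
  f1 <- procrustes_anova(sh, n_perm = 499, seed = 7)
  f2 <- procrustes_anova(sh, n_perm = 499, seed = 7)
  expect_identical(f1$p_value, f2$p_value)

  # exhaustive RRPP oracle over all 720 row permutations
  Y <- cranmod:::flatten_coords(sh$aligned)
  Yc <- scale(Y, scale = FALSE)
  x <- log(sh$centroid_size); xc <- x - mean(x)
  ssm <- function(M) sum(outer(xc, drop(crossprod(xc, M) / sum(xc^2)))^2)
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6), ]
  ss_all <- apply(perms, 1, function(r) ssm(Yc[r, , drop = FALSE]))
  p_exact <- mean(ss_all >= ssm(Yc))
  expect_lt(abs(f1$p_value - p_exact), 0.06)
})

test_that("constant size is rejected and errors are informative", {
  sh <- linear_shapes(10, 4, logsize = rep(2, 10))
  expect_error(procrustes_anova(sh, 99, 1), "constant")
  sh2 <- linear_shapes(10, 4)
  expect_error(procrustes_anova(sh2, n_perm = 0, seed = 1), "n_perm")
})

test_that("allometric vector comparison recovers shared and orthogonal slopes", {
  set.seed(23)
  n <- 60; p <- 6
  logsize <- rnorm(n, 5, 0.3)
  group <- rep(c("wild", "domestic"), each = n / 2)
  base <- as.vector(t(rand_config(p)))
  b_shared <- rnorm(3 * p); b_shared <- b_shared / sqrt(sum(b_shared^2))
  Y_same <- rep(1, n) %o% base + logsize %o% b_shared +
    matrix(rnorm(n * 3 * p, 0, 0.02), n)
  same <- compare_allometric_vectors(
    mat_shapes(Y_same, group, cs = exp(logsize)), n_perm = 199, seed = 1)
  expect_lt(same$angle_deg, 15)
  expect_gt(same$p_value, 0.05)

  b2 <- rnorm(3 * p); b2 <- b2 - sum(b2 * b_shared) * b_shared
  b2 <- b2 / sqrt(sum(b2^2))
  slope <- ifelse(group == "wild", 1, 0) %o% b_shared +
    ifelse(group == "wild", 0, 1) %o% b2
  Y_orth <- rep(1, n) %o% base + logsize * slope +
    matrix(rnorm(n * 3 * p, 0, 0.02), n)
  orth <- compare_allometric_vectors(
    mat_shapes(Y_orth, group, cs = exp(logsize)), n_perm = 199, seed = 1)
  expect_gt(orth$angle_deg, 75)
  expect_lte(orth$p_value, 0.05)

  expect_error(compare_allometric_vectors(
    mat_shapes(Y_same, rep("wild", n), cs = exp(logsize))), "two levels")
})

test_that("centroid-size t-test matches closed-form expectations", {
  set.seed(24)
  n <- 30
  arr <- array(rnorm(2 * n * 4 * 3), c(2 * n, 4, 3))
  group <- rep(c("wild", "domestic"), each = n)
  cs_same <- rep(exp(rnorm(n, 5, 0.1)), 2)  # identical distributions
  same <- centroid_size_ttest(arr_shapes(arr, group, cs = cs_same))
  expect_equal(same$t, 0, tolerance = 1e-12)
  cs_diff <- exp(c(rnorm(n, 5.5, 0.1), rnorm(n, 5.0, 0.1)))
  diff <- centroid_size_ttest(arr_shapes(arr, group, cs = cs_diff))
  expect_lt(diff$p_value, 1e-10)
  expect_error(
    centroid_size_ttest(arr_shapes(arr[1:3, , , drop = FALSE],
                                   c("wild", "domestic", "domestic"),
                                   cs = exp(rnorm(3)))),
    "at least 2")
})
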