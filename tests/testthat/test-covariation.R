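# Independent brute-force CR oracle: explicit double loops over the
# covariance entries, no matrix algebra shared with the implementation.
cr_oracle <- function(Y, nc_landmarks) {
  S <- cov(Y)
  p <- ncol(Y) / 3
  vars_of <- function(lms) as.vector(sapply(lms, function(j) 3 * (j - 1) + 1:3))
  i1 <- vars_of(nc_landmarks); i2 <- vars_of(setdiff(1:p, nc_landmarks))
  num <- 0
  for (a in i1) for (b in i2) num <- num + S[a, b]^2
  w1 <- 0
  for (a in i1) for (b in i1) if (a != b) w1 <- w1 + S[a, b]^2
  w2 <- 0
  for (a in i2) for (b in i2) if (a != b) w2 <- w2 + S[a, b]^2
  sqrt(num / sqrt(w1 * w2))
}

test_that("CR matches a brute-force evaluation and is label-symmetric", {
  set.seed(30)
  Y <- matrix(rnorm(8 * 12), 8, 12)   # 4 landmarks x 3
  map <- half_map(2, 2)
  expect_equal(covariance_ratio(Y, map), cr_oracle(Y, 1:2), tolerance = 1e-12)
  swapped <- module_map(c("MD", "MD", "NC", "NC"))
  expect_equal(covariance_ratio(Y, swapped), covariance_ratio(Y, map))
  expect_error(covariance_ratio(Y, module_map(c("NC", rep("MD", 3)))),
               "at least 2 landmarks")
})

test_that("CR calibrates to 0 under block-diagonal covariance and rises with
           between-module correlation", {
  set.seed(31)
  map <- half_map(4, 4)
  C0 <- block_corr(4, 4, 0.5, 0.5, 0)
  cr0 <- covariance_ratio(rmvn(500, C0), map)
  expect_lt(cr0, 0.1)
  # monotone in rho_between at fixed within-module correlation
  grid <- c(0.05, 0.2, 0.35, 0.5)
  cr_g <- vapply(grid, function(rb) {
    mean(replicate(5, covariance_ratio(
      rmvn(300, block_corr(4, 4, 0.5, 0.5, rb)), map)))
  }, numeric(1))
  expect_identical(order(cr_g), seq_along(grid))
  expect_equal(cor(grid, cr_g, method = "spearman"), 1)
})

test_that("the modularity test detects modular structure and is seed-stable", {
  set.seed(32)
  map <- half_map(5, 5)
  Ym <- rmvn(100, block_corr(5, 5, 0.6, 0.6, 0.05))
  m1 <- modularity_test(Ym, map, n_perm = 199, seed = 5)
  m2 <- modularity_test(Ym, map, n_perm = 199, seed = 5)
  expect_lt(m1$cr_observed, 1)
  expect_lte(m1$p_value, 0.05)
  expect_lt(m1$z, 0)
  expect_identical(m1$p_value, m2$p_value)
  expect_identical(m1$perm_distribution, m2$perm_distribution)
  expect_error(modularity_test(Ym, map, n_perm = 0), "n_perm")
})

test_that("PLS recovers exact linear dependence and the SVD identity", {
  set.seed(33)
  X <- matrix(rnorm(20 * 6), 20, 6)
  map <- half_map(2, 2)
  # block 2 an exact scaled copy of block 1: first-axis scores coincide
  res1 <- two_block_pls(cbind(X, 2 * X), map, n_perm = 99, seed = 1)
  expect_equal(res1$r_pls, 1, tolerance = 1e-10)
  expect_lte(res1$p_value, 0.05)
  # generic linear image: SVD identity and score-correlation definition
  A <- matrix(rnorm(36), 6, 6)
  Y <- cbind(X, X %*% A)
  res <- two_block_pls(Y, map, n_perm = 99, seed = 1)
  S12 <- cov(scale(Y[, 1:6], scale = FALSE),
             scale(Y[, 7:12], scale = FALSE))
  expect_equal(res$singular_values[1]^2,
               max(eigen(S12 %*% t(S12))$values), tolerance = 1e-8)
  expect_true(all(diff(res$singular_values) <= 1e-12))
  # r_pls equals the correlation of the first-axis scores
  expect_equal(res$r_pls, cor(res$x_scores, res$y_scores))
})

test_that("r-PLS is invariant to orthogonal rotation of either block's variables", {
  set.seed(34)
  Y <- rmvn(40, block_corr(2, 2, 0.5, 0.5, 0.3))
  map <- half_map(2, 2)
  r0 <- two_block_pls(Y, map, n_perm = 99, seed = 2)$r_pls
  Q <- qr.Q(qr(matrix(rnorm(36), 6)))
  Y2 <- Y
  Y2[, 1:6] <- Y[, 1:6] %*% Q
  r1 <- two_block_pls(Y2, map, n_perm = 99, seed = 2)$r_pls
  expect_equal(r0, r1, tolerance = 1e-10)
})

test_that("independent blocks yield small r-PLS and a calm p-value", {
  set.seed(35)
  Y <- rmvn(100, diag(12))
  res <- two_block_pls(Y, half_map(2, 2), n_perm = 199, seed = 3)
  expect_lt(res$r_pls, 0.6)
  expect_gt(res$p_value, 0.01)
})

test_that("effect-size comparison is null for self and separates strong contrasts", {
  set.seed(36)
  map <- half_map(2, 2)
  # generating first-axis correlations ~0.2 and ~0.9
  X1 <- matrix(rnorm(100 * 6), 100)
  weak_Y <- cbind(X1, 0.2 * X1 + matrix(rnorm(100 * 6), 100))
  X2 <- matrix(rnorm(100 * 6), 100)
  strong_Y <- cbind(X2, X2 + matrix(rnorm(100 * 6, 0, 0.5), 100))
  weak <- two_block_pls(weak_Y, map, n_perm = 199, seed = 4)
  strong <- two_block_pls(strong_Y, map, n_perm = 199, seed = 4)
  self <- compare_pls_effects(list(a = weak, b = weak))
  expect_equal(self$z_diff["a", "b"], 0)
  expect_equal(self$p_values["a", "b"], 1)
  both <- compare_pls_effects(list(weak = weak, strong = strong))
  expect_lt(both$p_values["weak", "strong"], 0.05)
  degenerate <- weak
  degenerate$perm_distribution <- rep(0.5, 199)
  expect_error(compare_pls_effects(list(a = weak, b = degenerate)),
               "degenerate")
  expect_error(compare_pls_effects(list(a = weak)), "at least 2")
})

test_that("eigenvalue dispersion hits its closed forms and increases with rho", {
  expect_equal(rel_eig_sd(diag(6)), 0)
  expect_equal(rel_eig_sd(matrix(1, 6, 6)), 1, tolerance = 1e-12)
  expect_equal(rel_eig_sd(exch_corr(6, 0.5)), 0.5, tolerance = 1e-12)
  rhos <- seq(0.1, 0.9, by = 0.1)
  vals <- vapply(rhos, function(r) rel_eig_sd(exch_corr(9, r)), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_equal(vals, rhos, tolerance = 1e-10)  # exact for exchangeable
})

test_that("module dispersion works on data and rejects zero-variance input", {
  set.seed(37)
  Y <- rmvn(200, block_corr(3, 3, 0.4, 0.4, 0.1))
  d <- eigenvalue_dispersion(Y, half_map(3, 3), "NC")
  expect_gt(d$rel_eig_sd, 0.25)
  expect_lt(d$rel_eig_sd, 0.55)
  Y[, 2] <- 1
  colnames(Y) <- paste0("v", 1:18)
  expect_error(eigenvalue_dispersion(Y, half_map(3, 3), "NC"), "v2")
})
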