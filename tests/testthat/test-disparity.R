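test_that("Procrustes variance follows its closed forms and conventions", {
  # identical shapes: zero disparity
  a <- array(rep(rand_config(4), each = 5), c(5, 4, 3))
  expect_equal(unname(procrustes_variance(arr_shapes(a))), 0)
  # two specimens +/- d/2 on one coordinate: PV = d^2/4 under the n divisor
  d <- 0.8
  Y <- matrix(0, 2, 12)
  Y[1, 5] <- d / 2; Y[2, 5] <- -d / 2
  expect_equal(unname(procrustes_variance(Y, rep("g", 2))), d^2 / 4)
  # large-n isotropic check: PV -> sigma^2 * 3p
  set.seed(40)
  p <- 5; sigma <- 0.3
  Yn <- matrix(rnorm(4000 * 3 * p, 0, sigma), 4000)
  expect_equal(unname(procrustes_variance(Yn, rep("g", 4000))),
               sigma^2 * 3 * p, tolerance = 0.02 * sigma^2 * 3 * p)
  expect_error(procrustes_variance(Y, c("a", "b")), "fewer than 2")
})

test_that("disparity is order-invariant, scales quadratically, and the trace
           splits additively over modules", {
  set.seed(41)
  a <- array(rnorm(20 * 6 * 3), c(20, 6, 3))
  sh <- arr_shapes(a, group = rep(c("wild", "domestic"), 10))
  pv <- procrustes_variance(sh)
  ord <- sample(20)
  sh_perm <- arr_shapes(a[ord, , ], group = sh$group[ord])
  expect_equal(procrustes_variance(sh_perm)[names(pv)], pv)
  expect_equal(procrustes_variance(arr_shapes(3 * a, group = sh$group)),
               9 * pv)
  map <- half_map(2, 4)
  pv_nc <- procrustes_variance(subset_module(sh, map, "NC"))
  pv_md <- procrustes_variance(subset_module(sh, map, "MD"))
  expect_equal(pv_nc + pv_md, pv, tolerance = 1e-12)
})

test_that("the disparity permutation test separates unequal variances", {
  set.seed(42)
  n <- 40
  Y <- rbind(matrix(rnorm(n * 12, 0, 1), n),
             matrix(rnorm(n * 12, 0, sqrt(3)), n))   # 3:1 variance ratio
  grp <- rep(c("wild", "domestic"), each = n)
  dt <- disparity_test(Y, grp, n_perm = 499, seed = 1)
  expect_gt(dt$proc_var["domestic"], dt$proc_var["wild"])
  expect_lte(dt$p_values["wild", "domestic"], 0.05)
  dt2 <- disparity_test(Y, grp, n_perm = 499, seed = 1)
  expect_identical(dt$p_values, dt2$p_values)
  expect_error(disparity_test(Y, rep("wild", 2 * n), 99, 1),
               "at least 2 groups")
  expect_error(disparity_test(Y, grp, n_perm = 0), "n_perm")
})

test_that("equal-variance groups are not flagged (type-I behaviour)", {
  set.seed(43)
  reps <- 40
  rej <- 0
  for (k in seq_len(reps)) {
    Y <- matrix(rnorm(60 * 9), 60)
    p <- disparity_test(Y, rep(c("wild", "domestic"), 30),
                        n_perm = 99, seed = k)$p_values["wild", "domestic"]
    rej <- rej + (p <= 0.05)
  }
  expect_lte(rej, 8)  # ~2 expected at the nominal rate
})

test_that("module disparity corrects for landmark counts and finds group effects", {
  set.seed(44)
  # equal per-landmark variance in unequal-sized modules
  a <- array(rnorm(200 * 9 * 3, 0, 0.1), c(200, 9, 3))
  sh <- arr_shapes(a, group = rep(c("wild", "domestic"), 100))
  md <- module_disparity(sh, half_map(3, 6), n_perm = 99, seed = 1)
  per_lm <- tapply(md$proc_var_per_landmark, md$module, mean)
  expect_equal(unname(per_lm["NC"] / per_lm["MD"]), 1, tolerance = 0.1)
  expect_equal(md$proc_var / md$proc_var_per_landmark,
               md$n_landmarks, ignore_attr = TRUE)

  # domestic dispersion scaled 2x in sd: recovered with small p at n=30+30
  b <- array(rnorm(60 * 9 * 3, 0, 0.1), c(60, 9, 3))
  b[31:60, , ] <- 2 * b[31:60, , ]
  sh2 <- arr_shapes(b, group = rep(c("wild", "domestic"), each = 30))
  md2 <- module_disparity(sh2, half_map(3, 6), n_perm = 199, seed = 2)
  dom <- md2[md2$group == "domestic", ]
  wld <- md2[md2$group == "wild", ]
  expect_true(all(dom$proc_var > wld$proc_var))
  expect_true(all(dom$p_vs_other_group <= 0.05))
})
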