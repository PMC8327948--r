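test_that("templates are symmetric, fully paired, and seed-deterministic", {
  prm <- synthetic_params(p_nc = 14, p_md = 12, midline_nc = 2,
                          midline_md = 2, seed = 60)
  tpl <- make_template(prm)
  p <- prm$p_nc + prm$p_md
  expect_equal(nrow(tpl$template), p)
  expect_setequal(c(tpl$pairing$pairs, tpl$pairing$midline), seq_len(p))
  # mirror-relabelled template equals itself (object symmetry by construction)
  expect_equal(cranmod:::mirror_swap(tpl$template, tpl$pairing),
               tpl$template, tolerance = 1e-12)
  expect_equal(centroid_size(tpl$template), 1)
  tpl2 <- make_template(prm)
  expect_identical(tpl$template, tpl2$template)
  expect_equal(unname(tpl$map$counts), c(prm$p_nc, prm$p_md))
})

test_that("parameter validation catches impossible schemes", {
  expect_error(synthetic_params(p_nc = 2, p_md = 1, midline_nc = 0,
                                midline_md = 1), "at least 4")
  expect_error(synthetic_params(p_nc = 5, midline_nc = 2), "even")
  expect_error(synthetic_params(rho_within_nc = 0, rho_within_md = 0,
                                rho_between = 0.5), "non-PSD")
  expect_error(synthetic_params(sigma_shape = -1), "non-negative")
})

test_that("simulation is bit-reproducible from its seed", {
  prm <- synthetic_params(seed = 61)
  s1 <- simulate_dataset(prm)
  s2 <- simulate_dataset(prm)
  expect_identical(s1$dataset$coords, s2$dataset$coords)
  expect_identical(s1$truth$logsize, s2$truth$logsize)
})

test_that("with no antisymmetric noise the data are exactly object-symmetric", {
  prm <- synthetic_params(asym_sd = 0, n_wild = 5, n_domestic = 5, seed = 62)
  sim <- simulate_dataset(prm)
  sym <- symmetric_component(sim$dataset, sim$pairing)
  expect_lt(max(abs(attr(sym, "asymmetric"))), 1e-6)
})

test_that("equal within/between correlation erases modular structure (CR ~ 1)", {
  prm <- synthetic_params(rho_within_nc = 0.3, rho_within_md = 0.3,
                          rho_between = 0.3, n_wild = 200, n_domestic = 200,
                          allometry_norm = 0, group_mean_offset = 0,
                          disparity_scale_domestic = 1, asym_sd = 0,
                          seed = 63)
  sim <- simulate_dataset(prm)
  sym <- symmetric_component(sim$dataset, sim$pairing)
  # calibration is on the deduplicated landmark set: the symmetric
  # component carries each bilateral pair twice, which by itself inflates
  # within-module covariation
  hl <- half_landmarks(sim$pairing, sim$map)
  cr <- covariance_ratio(subset_landmarks(sym, hl$landmarks), hl$map)
  expect_gt(cr, 0.85)
  expect_lt(cr, 1.15)
})

test_that("the domestic dispersion multiplier is recovered as a variance ratio", {
  prm <- synthetic_params(disparity_scale_domestic = 2, n_wild = 400,
                          n_domestic = 400, allometry_norm = 0,
                          group_mean_offset = 0, asym_sd = 0,
                          logsize_sd = 0.05, seed = 64)
  sim <- simulate_dataset(prm)
  sym <- symmetric_component(sim$dataset, sim$pairing)
  rec <- recover_covariance_params(sym, sim)
  expect_equal(rec$disparity_ratio, 4, tolerance = 0.1 * 4)
})

test_that("study-sized presets mirror the published sample structure", {
  presets <- study_presets()
  expect_length(presets, 6)
  horse <- presets$horse_przewalski
  expect_equal(horse$n_domestic, 133L)
  expect_equal(horse$n_wild, 83L)
  dog <- presets$dog_wolf
  expect_equal(dog$p_nc + dog$p_md, 26L)
  goat <- presets$goat_bezoar
  expect_equal(goat$p_nc + goat$p_md, 60L)
  sim <- simulate_dataset(synthetic_params(
    n_wild = goat$n_wild, n_domestic = goat$n_domestic, seed = 65))
  halves <- split_pair(sim$dataset)
  expect_equal(dim(halves$domestic$coords)[1], 41L)
  expect_equal(dim(halves$wild$coords)[1], 22L)
  # MD within-module correlation at least NC's in every preset (the
  # integration-magnitude pattern the presets encode)
  expect_true(all(vapply(presets, function(pr)
    pr$rho_within_md >= pr$rho_within_nc, logical(1))))
})

test_that("null generating conditions give uniform p-values at the level each
           test permutes, and superimposition-induced covariance is visible
           end-to-end", {
  reps <- 120
  p_mod_gen <- p_pls_gen <- p_mod_e2e <- p_disp <- numeric(reps)
  null_params <- function(k)
    synthetic_params(rho_within_nc = 0, rho_within_md = 0,
                     rho_between = 0, disparity_scale_domestic = 1,
                     group_mean_offset = 0, allometry_norm = 0,
                     n_wild = 20, n_domestic = 20,
                     p_nc = 8, p_md = 6, midline_nc = 2,
                     midline_md = 2, seed = 3000 + k)
  hmap <- module_map(rep(c("NC", "MD"), c(5, 4)))  # half-landmark modules
  set.seed(3999)
  for (k in seq_len(reps)) {
    # the tests are calibrated on the generating (pre-superimposition)
    # deviations: exchangeable landmarks, independent blocks
    Z <- matrix(rnorm(40 * 27), 40)   # 9 half landmarks x 3, iid
    p_mod_gen[k] <- modularity_test(Z, hmap, 99, seed = k)$p_value
    p_pls_gen[k] <- two_block_pls(Z, hmap, 99, seed = k)$p_value
    # end-to-end through simulation, GPA and symmetry extraction
    sim <- simulate_dataset(null_params(k))
    sym <- symmetric_component(sim$dataset, sim$pairing)
    hl <- half_landmarks(sim$pairing, sim$map)
    half <- subset_landmarks(sym, hl$landmarks)
    p_mod_e2e[k] <- modularity_test(half, hl$map, 99, seed = k)$p_value
    p_disp[k] <- disparity_test(sym, n_perm = 99,
                                seed = k)$p_values["wild", "domestic"]
  }
  expect_gt(suppressWarnings(ks.test(p_mod_gen, "punif"))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(p_pls_gen, "punif"))$p.value, 0.01)
  # group-permutation disparity contrasts stay uniform through the pipeline
  expect_gt(suppressWarnings(ks.test(p_disp, "punif"))$p.value, 0.01)
  # Procrustes superimposition induces block-structured covariance from the
  # similarity-dimension removal (loadings follow the template's anatomical
  # blocks), so the landmark-permutation modularity test over-rejects on
  # superimposed null data: a property of Procrustes shape data the methods
  # vignette documents, not a defect of the statistic
  expect_gt(mean(p_mod_e2e <= 0.05), 0.10)
})
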