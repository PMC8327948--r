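#' Pipeline configuration for one wild/domestic pair
#'
#' Exactly one input source must be given: either `dataset` + `map` +
#' `pairing` (real or pre-simulated data), or a `preset`
#' ([synthetic_params()]) to simulate from.
#'
#' @param dataset optional [landmark_dataset()].
#' @param map optional [module_map()].
#' @param pairing optional [symmetry_pairing()].
#' @param preset optional [synthetic_params()].
#' @param branch `"both"`, `"uncorrected"` or `"corrected"`.
#' @param n_perm permutations for every resampling test (>= 99).
#' @param seed base seed; stage seeds are derived by fixed offsets.
#' @param reduced_landmarks flag the pair as digitised on a reduced landmark
#'   set (excluded from cross-pair effect-size comparison, as a pair with
#'   fewer landmarks is not commensurable there).
#' @param output_dir optional directory for CSV/JSON reports.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(dataset = NULL, map = NULL, pairing = NULL,
                            preset = NULL,
                            branch = c("both", "uncorrected", "corrected"),
                            n_perm = 999L, seed = 1L,
                            reduced_landmarks = FALSE, output_dir = NULL) {
  branch <- match.arg(branch)
  has_data <- !is.null(dataset)
  has_preset <- !is.null(preset)
  if (has_data == has_preset)
    stop("exactly one input source required: dataset(+map+pairing) OR preset")
  if (has_data && (is.null(map) || is.null(pairing)))
    stop("dataset input requires 'map' and 'pairing'")
  if (n_perm < 99) stop("n_perm must be >= 99 for reported p-values")
  structure(list(dataset = dataset, map = map, pairing = pairing,
                 preset = preset, branch = branch, n_perm = as.integer(n_perm),
                 seed = as.integer(seed),
                 reduced_landmarks = reduced_landmarks,
                 output_dir = output_dir),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

subset_group <- function(shapes, g) {
  keep <- shapes$group == g
  shape_arrays(shapes$aligned[keep, , , drop = FALSE],
               shapes$centroid_size[keep], shapes$group[keep],
               symmetric = shapes$symmetric, pair_id = shapes$pair_id,
               specimen_ids = shapes$specimen_ids[keep])
}

branch_stats <- function(shapes, map, n_perm, seed) {
  cr <- stage("modularity", modularity_test(shapes, map, n_perm, seed))
  pls <- stage("integration", two_block_pls(shapes, map, n_perm, seed + 1L))
  disp <- NULL
  for (g in unique(shapes$group)) {
    sub <- subset_group(shapes, g)
    for (mod in c("NC", "MD")) {
      ed <- stage("dispersion", eigenvalue_dispersion(sub, map, mod))
      disp <- rbind(disp, data.frame(form = g, module = mod,
                                     rel_eig_sd = ed$rel_eig_sd))
    }
  }
  md <- stage("module_disparity",
              module_disparity(shapes, map, n_perm = n_perm,
                               seed = seed + 2L))
  whole <- stage("whole_disparity",
                 disparity_test(shapes, n_perm = n_perm, seed = seed + 3L))
  ord <- stage("pca", shape_pca(shapes))
  pcpls <- stage("pc1_pls1", pc1_pls1_correlation(ord, pls))
  by_form <- NULL
  for (g in unique(shapes$group)) {
    sub <- subset_group(shapes, g)
    pg <- stage("integration_by_form",
                two_block_pls(sub, map, n_perm, seed + 4L))
    by_form <- rbind(by_form, data.frame(
      form = g, r_pls = pg$r_pls, z = pg$effect_size_z,
      p_value = pg$p_value))
  }
  list(modularity = cr, pls = pls, dispersion = disp,
       module_disparity = md, whole_disparity = whole,
       pca = ord, pc1_pls1 = pcpls, pls_by_form = by_form)
}

#' Run the full per-pair analysis
#'
#' Stages, in order: GPA, symmetric component, shape-on-size regression
#' (with residual extraction, allometric-vector comparison and centroid-size
#' t-test), then per branch (uncorrected symmetric shapes / allometry
#' residuals): CR modularity test, NC-MD two-block PLS, per-module and
#' per-form eigenvalue dispersion, module and whole-cranium disparity with
#' wild/domestic contrasts, PCA, PC1-PLS1 correlation, and per-form PLS.
#' Optionally writes CSV tables and a JSON summary plus a run log.
#'
#' @param config a [pipeline_config()].
#' @return a report: nested list with `pair_id`, `allometry`, `branches`
#'   (one per analysed branch), `settings`, `timings`.
#' @export
run_pair <- function(config) {
  t0 <- proc.time()[3]
  if (!is.null(config$preset)) {
    sim <- stage("simulate", simulate_dataset(config$preset))
    dataset <- sim$dataset; map <- sim$map; pairing <- sim$pairing
  } else {
    dataset <- config$dataset; map <- config$map; pairing <- config$pairing
  }
  n_perm <- config$n_perm; seed <- config$seed

  sym <- stage("gpa_symmetry",
               symmetric_component(dataset, pairing))
  anova_fit <- stage("allometry",
                     procrustes_anova(sym, n_perm, seed + 10L))
  resid_shapes <- allometry_residuals(anova_fit)
  vec_cmp <- stage("allometric_vectors",
                   compare_allometric_vectors(sym, n_perm = n_perm,
                                              seed = seed + 11L))
  cs_test <- stage("size_ttest", centroid_size_ttest(sym))

  branches <- list()
  if (config$branch %in% c("both", "uncorrected"))
    branches$uncorrected <- branch_stats(sym, map, n_perm, seed + 20L)
  if (config$branch %in% c("both", "corrected"))
    branches$corrected <- branch_stats(resid_shapes, map, n_perm, seed + 40L)

  report <- list(
    pair_id = dataset$pair_id,
    n = stats::setNames(
      c(sum(dataset$group == "wild"), sum(dataset$group == "domestic")),
      c("wild", "domestic")),
    p_landmarks = n_landmarks(dataset),
    allometry = list(
      table = data.frame(SS_model = anova_fit$ss_model,
                         SS_resid = anova_fit$ss_resid,
                         SS_total = anova_fit$ss_total,
                         R2 = anova_fit$r_squared, F = anova_fit$f_stat,
                         Z = anova_fit$z, p_value = anova_fit$p_value),
      vector_comparison = vec_cmp[c("angle_deg", "vector_correlation",
                                    "p_value")],
      size_ttest = cs_test),
    branches = branches,
    reduced_landmarks = config$reduced_landmarks,
    settings = list(n_perm = n_perm, seed = seed, branch = config$branch,
                    gpa_tol = 1e-10),
    timings = c(total_s = unname(proc.time()[3] - t0)))
  if (!is.null(config$output_dir)) write_pair_report(report, config$output_dir)
  report
}

write_pair_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pfx <- file.path(dir, report$pair_id)
  utils::write.csv(report$allometry$table,
                   paste0(pfx, "_allometry.csv"), row.names = FALSE)
  for (br in names(report$branches)) {
    b <- report$branches[[br]]
    utils::write.csv(data.frame(
      statistic = c("CR", "CR_p", "CR_z", "r_PLS", "PLS_p", "PLS_z"),
      value = c(b$modularity$cr_observed, b$modularity$p_value,
                b$modularity$z, b$pls$r_pls, b$pls$p_value,
                b$pls$effect_size_z)),
      paste0(pfx, "_", br, "_covariation.csv"), row.names = FALSE)
    utils::write.csv(b$dispersion, paste0(pfx, "_", br, "_dispersion.csv"),
                     row.names = FALSE)
    utils::write.csv(b$module_disparity,
                     paste0(pfx, "_", br, "_disparity.csv"),
                     row.names = FALSE)
  }
  summary <- report
  summary$branches <- lapply(report$branches, function(b) list(
    cr = b$modularity$cr_observed, cr_p = b$modularity$p_value,
    r_pls = b$pls$r_pls, pls_z = b$pls$effect_size_z,
    pls_p = b$pls$p_value, dispersion = b$dispersion,
    module_disparity = b$module_disparity,
    pc1_pls1 = b$pc1_pls1, pls_by_form = b$pls_by_form))
  summary$branches <- lapply(summary$branches, function(b) b)
  jsonlite::write_json(summary[setdiff(names(summary), "allometry")],
                       paste0(pfx, "_summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  log_lines <- c(
    sprintf("pair=%s n_perm=%d seed=%d branch=%s gpa_tol=%g elapsed_s=%.2f",
            report$pair_id, report$settings$n_perm, report$settings$seed,
            report$settings$branch, report$settings$gpa_tol,
            report$timings["total_s"]))
  writeLines(log_lines, paste0(pfx, "_run.log"))
  invisible(pfx)
}

#' Cross-pair study summary
#'
#' Aggregates per-pair reports: average CR per branch, pooled eigenvalue
#' dispersion with the four t-contrasts, the pairwise PLS effect-size
#' comparison (pairs flagged `reduced_landmarks` excluded), per-form
#' between-module r-PLS ranges and wild-vs-domestic t-test, and the
#' disparity ~ integration regressions (against between-module z and
#' against within-module dispersion).
#'
#' @param reports list of [run_pair()] reports (>= 2), same branch
#'   selection in each.
#' @return nested list of cross-pair summaries, one element per branch.
#' @export
run_study <- function(reports) {
  if (length(reports) < 2) stop("need at least 2 pair reports")
  brs <- lapply(reports, function(r) sort(names(r$branches)))
  if (length(unique(vapply(brs, paste, character(1), collapse = ","))) != 1)
    stop("inconsistent branch selection across pair reports")
  pair_ids <- unname(vapply(reports, function(r) r$pair_id, character(1)))
  if (anyDuplicated(pair_ids))
    pair_ids <- make.unique(pair_ids)
  out <- list()
  for (br in brs[[1]]) {
    get_b <- function(r) r$branches[[br]]
    cr <- vapply(reports, function(r) get_b(r)$modularity$cr_observed,
                 numeric(1))
    cr_p <- vapply(reports, function(r) get_b(r)$modularity$p_value,
                   numeric(1))
    disp <- NULL
    md <- NULL
    h3 <- NULL
    for (i in seq_along(reports)) {
      b <- get_b(reports[[i]])
      disp <- rbind(disp, cbind(pair = pair_ids[i], b$dispersion))
      md <- rbind(md, cbind(pair = pair_ids[i], b$module_disparity))
      h3 <- rbind(h3, cbind(pair = pair_ids[i], b$pls_by_form))
    }
    names(disp)[names(disp) == "rel_eig_sd"] <- "value"
    tt <- dispersion_ttests(disp)

    keep <- !vapply(reports, function(r) isTRUE(r$reduced_landmarks),
                    logical(1))
    cmp <- if (sum(keep) >= 2) {
      pls_list <- lapply(reports[keep], function(r) get_b(r)$pls)
      names(pls_list) <- pair_ids[keep]
      compare_pls_effects(pls_list)
    } else NULL

    h3_t <- stats::t.test(h3$r_pls[h3$form == "wild"],
                          h3$r_pls[h3$form == "domestic"], paired = TRUE)

    # regressions over pair x module x form: module disparity (landmark
    # corrected) vs between-module z (per pair x form) and vs eigenvalue
    # dispersion (per pair x module x form)
    md$form <- md$group
    reg_df <- merge(md[, c("pair", "module", "form",
                           "proc_var_per_landmark")],
                    disp[, c("pair", "module", "form", "value")],
                    by = c("pair", "module", "form"))
    names(reg_df)[names(reg_df) == "value"] <- "dispersion"
    reg_df <- merge(reg_df, h3[, c("pair", "form", "z")],
                    by = c("pair", "form"))
    reg_between <- disparity_integration_regression(
      reg_df$proc_var_per_landmark, reg_df$z, reg_df$form)
    reg_within <- disparity_integration_regression(
      reg_df$proc_var_per_landmark, reg_df$dispersion, reg_df$form)

    out[[br]] <- list(
      cr = stats::setNames(cr, pair_ids), cr_p = stats::setNames(cr_p, pair_ids),
      cr_mean = mean(cr),
      dispersion = disp,
      dispersion_means = c(
        NC = mean(disp$value[disp$module == "NC"]),
        MD = mean(disp$value[disp$module == "MD"])),
      dispersion_ttests = tt,
      effect_size_comparison = cmp,
      pls_by_form = h3,
      pls_by_form_range = rbind(
        data.frame(form = "wild",
                   min = min(h3$r_pls[h3$form == "wild"]),
                   max = max(h3$r_pls[h3$form == "wild"])),
        data.frame(form = "domestic",
                   min = min(h3$r_pls[h3$form == "domestic"]),
                   max = max(h3$r_pls[h3$form == "domestic"]))),
      pls_by_form_ttest = list(t = unname(h3_t$statistic),
                               df = unname(h3_t$parameter),
                               p_value = h3_t$p.value),
      regression_between = reg_between[c("slopes", "interaction_F",
                                         "interaction_df", "interaction_p",
                                         "model_p", "var_F", "var_df",
                                         "var_p")],
      regression_within = reg_within[c("slopes", "interaction_F",
                                       "interaction_df", "interaction_p",
                                       "model_p", "var_F", "var_df",
                                       "var_p")])
  }
  out
}
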