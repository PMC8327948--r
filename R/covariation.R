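#' Covariance ratio (CR) between two landmark modules
#'
#' From the `3p x 3p` specimen covariance matrix `S` partitioned by module
#' into within-module blocks `S11`, `S22` and the between-module block
#' `S12`:
#' \deqn{CR = \sqrt{ \mathrm{tr}(S_{12}S_{12}^T) / \sqrt{\mathrm{tr}(\tilde S_{11}\tilde S_{11}^T)\,\mathrm{tr}(\tilde S_{22}\tilde S_{22}^T)} }}
#' where the tilde zeroes each within-module block's diagonal. `CR < 1`
#' indicates greater covariation within modules than between them (modular
#' structure). The statistic never inverts `S` and is well defined on
#' rank-deficient data (the usual situation after GPA, where `n < 3p`).
#'
#' @param shapes [shape_arrays()] (or an `n x q` numeric matrix, in which
#'   case `map` must be a `module_map` over `q/3` landmarks).
#' @param map [module_map()] aligned with the landmarks.
#' @return non-negative scalar.
#' @export
covariance_ratio <- function(shapes, map) {
  Y <- if (inherits(shapes, "shape_arrays")) flatten_coords(shapes$aligned)
       else as.matrix(shapes)
  if (nrow(Y) < 3) stop("need at least 3 specimens")
  if (any(map$counts < 2)) stop("each module needs at least 2 landmarks")
  S <- stats::cov(Y)
  cr_from_cov(S, module_columns(map, "NC"), module_columns(map, "MD"))
}

cr_from_cov <- function(S, idx1, idx2) {
  S11 <- S[idx1, idx1, drop = FALSE]
  S22 <- S[idx2, idx2, drop = FALSE]
  S12 <- S[idx1, idx2, drop = FALSE]
  diag(S11) <- 0
  diag(S22) <- 0
  w1 <- sum(S11^2)
  w2 <- sum(S22^2)
  if (w1 == 0 || w2 == 0)
    stop("zero within-module off-diagonal covariance; CR undefined")
  sqrt(sum(S12^2) / sqrt(w1 * w2))
}

#' Covariance-ratio modularity test
#'
#' Tests the a-priori NC/MD partition against a landmark-permutation null:
#' landmarks (their x,y,z triplets kept together) are randomly reassigned to
#' modules of the same sizes and CR recomputed. Small CR indicates
#' modularity, so the p-value is the proportion of permuted CR values less
#' than or equal to the observed one (the observed counted among them).
#'
#' @param shapes [shape_arrays()] or an `n x q` matrix.
#' @param map [module_map()].
#' @param n_perm random permutations (default 999).
#' @param seed RNG seed.
#' @return object of class `modularity_result`: list with `cr_observed`,
#'   `perm_distribution`, `p_value`, `z` (standardized deviate, negative for
#'   modular structure), `n_perm`, `seed`.
#' @export
modularity_test <- function(shapes, map, n_perm = 999L, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  Y <- if (inherits(shapes, "shape_arrays")) flatten_coords(shapes$aligned)
       else as.matrix(shapes)
  if (nrow(Y) < 3) stop("need at least 3 specimens")
  if (any(map$counts < 2)) stop("each module needs at least 2 landmarks")
  S <- stats::cov(Y)
  p <- length(map$assignment)
  obs <- cr_from_cov(S, module_columns(map, "NC"), module_columns(map, "MD"))
  n_nc <- unname(map$counts["NC"])
  cr_perm <- numeric(n_perm)
  withr_seed(seed, {
    for (k in seq_len(n_perm)) {
      lm_nc <- sample.int(p, n_nc)
      i1 <- as.vector(vapply(lm_nc, function(j) 3L * (j - 1L) + 1:3,
                             integer(3)))
      i2 <- setdiff(seq_len(3L * p), i1)
      cr_perm[k] <- cr_from_cov(S, i1, i2)
    }
  })
  p_value <- (1 + sum(cr_perm <= obs)) / (n_perm + 1)
  dist_all <- c(obs, cr_perm)
  z <- (obs - mean(dist_all)) / stats::sd(dist_all)
  structure(list(cr_observed = obs, perm_distribution = cr_perm,
                 p_value = p_value, z = z, n_perm = n_perm, seed = seed),
            class = "modularity_result")
}

#' @export
print.modularity_result <- function(x, ...) {
  cat(sprintf("CR modularity test: CR = %.4f, Z = %.2f, p = %.4g (%d perms)\n",
              x$cr_observed, x$z, x$p_value, x$n_perm))
  invisible(x)
}

#' Two-block partial least squares (singular warps) between modules
#'
#' Both blocks of Procrustes coordinates are column-centred and the
#' between-block covariance matrix decomposed by SVD. Specimens are
#' projected on the paired singular vectors; `r_pls` is the Pearson
#' correlation of the first-axis scores, measuring between-module
#' integration. Significance comes from randomly permuting specimens in one
#' block relative to the other (large `r` is significant; observed counted
#' among permutations), and the permutation effect size is
#' `z = (r_obs - mean(r_perm)) / sd(r_perm)` on the raw correlation scale.
#'
#' @param shapes [shape_arrays()] or `n x q` matrix.
#' @param map [module_map()]; block X is the NC module, block Y the MD
#'   module.
#' @param n_perm,seed permutation controls.
#' @return object of class `pls_result`: `r_pls`, `singular_values`,
#'   `x_scores`, `y_scores` (first axis), `left_vectors`, `right_vectors`,
#'   `p_value`, `effect_size_z`, `perm_distribution`, `n_perm`, `seed`.
#' @export
two_block_pls <- function(shapes, map, n_perm = 999L, seed = 1L) {
  Y <- if (inherits(shapes, "shape_arrays")) flatten_coords(shapes$aligned)
       else as.matrix(shapes)
  n <- nrow(Y)
  if (n < 3) stop("need at least 3 specimens")
  X1 <- scale(Y[, module_columns(map, "NC"), drop = FALSE], scale = FALSE)
  X2 <- scale(Y[, module_columns(map, "MD"), drop = FALSE], scale = FALSE)
  if (all(X1 == 0) || all(X2 == 0)) stop("constant block; PLS undefined")

  pls_r <- function(A, B) {
    s <- svd(crossprod(A, B) / (nrow(A) - 1))
    xs <- A %*% s$u[, 1]
    ys <- B %*% s$v[, 1]
    list(r = stats::cor(xs, ys)[1], s = s, xs = xs, ys = ys)
  }
  obs <- pls_r(X1, X2)
  r_perm <- numeric(n_perm)
  withr_seed(seed, {
    for (k in seq_len(n_perm))
      r_perm[k] <- pls_r(X1, X2[sample.int(n), , drop = FALSE])$r
  })
  p_value <- (1 + sum(r_perm >= obs$r)) / (n_perm + 1)
  dist_all <- c(obs$r, r_perm)
  z <- (obs$r - mean(dist_all)) / stats::sd(dist_all)
  structure(list(r_pls = obs$r, singular_values = obs$s$d,
                 x_scores = drop(obs$xs), y_scores = drop(obs$ys),
                 left_vectors = obs$s$u, right_vectors = obs$s$v,
                 p_value = p_value, effect_size_z = z,
                 perm_distribution = r_perm, n_perm = n_perm, seed = seed),
            class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf("two-block PLS: r-PLS = %.4f, Z = %.2f, p = %.4g (%d perms)\n",
              x$r_pls, x$effect_size_z, x$p_value, x$n_perm))
  invisible(x)
}

#' Pairwise comparison of PLS permutation effect sizes
#'
#' Effect sizes are standardized permutation deviates, each carrying unit
#' sampling scale, so two analyses are contrasted with a two-sample z
#' statistic `(z_i - z_j) / sqrt(2)` and a two-sided normal p-value.
#'
#' @param results named list of [two_block_pls()] results.
#' @return list with `z` (effect sizes per analysis), `z_diff` and
#'   `p_values` (pairwise matrices).
#' @export
compare_pls_effects <- function(results) {
  if (length(results) < 2) stop("need at least 2 PLS results to compare")
  if (is.null(names(results)))
    names(results) <- paste0("pls", seq_along(results))
  sds <- vapply(results, function(r) stats::sd(r$perm_distribution),
                numeric(1))
  if (any(sds == 0))
    stop("degenerate permutation distribution (sd = 0) for: ",
         paste(names(results)[sds == 0], collapse = ", "))
  z <- vapply(results, function(r) r$effect_size_z, numeric(1))
  k <- length(z)
  z_diff <- outer(z, z, "-") / sqrt(2)
  p <- 2 * stats::pnorm(-abs(z_diff))
  diag(p) <- 1
  dimnames(z_diff) <- dimnames(p) <- list(names(results), names(results))
  list(z = z, z_diff = z_diff, p_values = p)
}

#' Relative eigenvalue standard deviation of a correlation matrix
#'
#' Population standard deviation of the eigenvalues divided by
#' `sqrt(N - 1)` where `N` is the number of variables: 0 for an identity
#' correlation matrix (no integration), 1 for a rank-one all-ones matrix
#' (complete integration). Because the normalization is relative to the
#' variable count, values are comparable across modules with unequal
#' landmark numbers.
#'
#' @param R correlation matrix.
#' @return scalar in `[0, 1]`.
#' @examples
#' rel_eig_sd(diag(6))                    # 0
#' rel_eig_sd(matrix(1, 6, 6))            # 1
#' rel_eig_sd(0.5 * matrix(1, 6, 6) + 0.5 * diag(6)) # 0.5
#' @export
rel_eig_sd <- function(R) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  N <- length(ev)
  sqrt(sum((ev - mean(ev))^2) / N) / sqrt(N - 1)
}

#' Eigenvalue dispersion (within-module integration magnitude)
#'
#' Builds the correlation matrix of one module's `3 * p_module` coordinate
#' variables and returns its relative eigenvalue standard deviation, a
#' trait-count-independent measure of integration magnitude.
#'
#' @param shapes [shape_arrays()] or `n x q` matrix.
#' @param map [module_map()].
#' @param which `"NC"` or `"MD"`.
#' @return object of class `dispersion_result`: `rel_eig_sd`, `module`,
#'   `n_var`, `landmark_corrected = TRUE`.
#' @export
eigenvalue_dispersion <- function(shapes, map, which = c("NC", "MD")) {
  which <- match.arg(which)
  Y <- if (inherits(shapes, "shape_arrays")) flatten_coords(shapes$aligned)
       else as.matrix(shapes)
  if (nrow(Y) < 3) stop("need at least 3 specimens")
  cols <- module_columns(map, which)
  if (length(cols) < 6) stop("module needs at least 2 landmarks")
  Ym <- Y[, cols, drop = FALSE]
  v <- apply(Ym, 2, stats::var)
  if (any(v == 0))
    stop("zero-variance variable(s): ",
         paste(colnames(Ym)[v == 0], collapse = ", "))
  R <- stats::cor(Ym)
  structure(list(rel_eig_sd = rel_eig_sd(R), module = which,
                 n_var = length(cols), landmark_corrected = TRUE),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("eigenvalue dispersion (%s, %d variables): %.4f\n",
              x$module, x$n_var, x$rel_eig_sd))
  invisible(x)
}
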