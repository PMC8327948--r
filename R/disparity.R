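#' Procrustes variance (morphological disparity) per group
#'
#' For each group, the sum over specimens of squared deviations from the
#' group mean shape across all coordinates, divided by the group's sample
#' size `n` (not `n - 1`): the trace of the group covariance matrix under
#' the n-divisor convention.
#'
#' @param shapes [shape_arrays()] or `n x q` matrix.
#' @param grouping per-specimen labels (default the shapes' groups).
#' @return named numeric vector, one Procrustes variance per group.
#' @export
procrustes_variance <- function(shapes, grouping = NULL) {
  Y <- if (inherits(shapes, "shape_arrays")) flatten_coords(shapes$aligned)
       else as.matrix(shapes)
  if (is.null(grouping))
    grouping <- if (inherits(shapes, "shape_arrays")) shapes$group
                else rep("all", nrow(Y))
  grouping <- as.character(grouping)
  levs <- unique(grouping)
  out <- stats::setNames(numeric(length(levs)), levs)
  for (g in levs) {
    Yg <- Y[grouping == g, , drop = FALSE]
    if (nrow(Yg) < 2) stop("group '", g, "' has fewer than 2 specimens")
    Ygc <- sweep(Yg, 2, colMeans(Yg))
    out[g] <- sum(Ygc^2) / nrow(Yg)
  }
  out
}

#' Permutation test for disparity differences between groups
#'
#' Observed statistic: absolute difference in Procrustes variance between
#' each pair of groups. Null distribution: specimens' group-mean-centred
#' residual vectors are randomly reallocated to groups (of the original
#' sizes) and the absolute differences recomputed; p is the proportion of
#' permutations (observed counted) at least as large as observed.
#'
#' @param shapes [shape_arrays()] or `n x q` matrix.
#' @param grouping per-specimen labels (>= 2 groups).
#' @param n_perm,seed permutation controls.
#' @return object of class `disparity_result`: `proc_var` (named vector),
#'   `pairwise_diffs` and `p_values` (matrices), `n_perm`, `seed`.
#' @export
disparity_test <- function(shapes, grouping = NULL, n_perm = 999L,
                           seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  Y <- if (inherits(shapes, "shape_arrays")) flatten_coords(shapes$aligned)
       else as.matrix(shapes)
  if (is.null(grouping))
    grouping <- if (inherits(shapes, "shape_arrays")) shapes$group
                else stop("grouping required for matrix input")
  grouping <- as.character(grouping)
  levs <- unique(grouping)
  if (length(levs) < 2)
    stop("need at least 2 groups; got only '", levs, "'")
  pv <- procrustes_variance(Y, grouping)

  # group-mean-centred residual vectors, their squared norms
  res2 <- numeric(nrow(Y))
  for (g in levs) {
    sel <- grouping == g
    Ygc <- sweep(Y[sel, , drop = FALSE], 2,
                 colMeans(Y[sel, , drop = FALSE]))
    res2[sel] <- rowSums(Ygc^2)
  }
  k <- length(levs)
  obs_diff <- abs(outer(pv, pv, "-"))
  count_ge <- matrix(0, k, k, dimnames = dimnames(obs_diff))
  withr_seed(seed, {
    for (it in seq_len(n_perm)) {
      gp <- grouping[sample.int(length(grouping))]
      pvp <- vapply(levs, function(g) mean(res2[gp == g]), numeric(1))
      count_ge <- count_ge + (abs(outer(pvp, pvp, "-")) >= obs_diff)
    }
  })
  p <- (1 + count_ge) / (n_perm + 1)
  diag(p) <- 1
  structure(list(proc_var = pv, pairwise_diffs = obs_diff, p_values = p,
                 n_perm = n_perm, seed = seed),
            class = "disparity_result")
}

#' @export
print.disparity_result <- function(x, ...) {
  cat("Procrustes variance by group:\n")
  print(round(x$proc_var, 6))
  cat("pairwise p-values (", x$n_perm, " perms):\n", sep = "")
  print(round(x$p_values, 4))
  invisible(x)
}

#' Per-module disparity with landmark-count correction
#'
#' Computes per-group Procrustes variance within each module of the joint
#' fit, divides by the module's landmark count for cross-module
#' comparability, and runs the wild-vs-domestic permutation contrast within
#' each module.
#'
#' @param shapes [shape_arrays()].
#' @param map [module_map()].
#' @param grouping per-specimen labels (default the shapes' groups).
#' @param n_perm,seed permutation controls.
#' @return data.frame with columns `module`, `group`, `proc_var`,
#'   `proc_var_per_landmark`, `n_landmarks`, `p_vs_other_group`.
#' @export
module_disparity <- function(shapes, map, grouping = shapes$group,
                             n_perm = 999L, seed = 1L) {
  out <- NULL
  for (mod in c("NC", "MD")) {
    sub <- subset_module(shapes, map, mod)
    dt <- disparity_test(sub, grouping, n_perm = n_perm, seed = seed)
    p_lm <- unname(map$counts[mod])
    levs <- names(dt$proc_var)
    p_other <- vapply(seq_along(levs), function(i) {
      j <- if (length(levs) == 2) 3 - i else i
      dt$p_values[i, j]
    }, numeric(1))
    out <- rbind(out, data.frame(
      module = mod, group = levs, proc_var = unname(dt$proc_var),
      proc_var_per_landmark = unname(dt$proc_var) / p_lm,
      n_landmarks = p_lm, p_vs_other_group = p_other))
  }
  rownames(out) <- NULL
  out
}
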