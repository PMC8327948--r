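#' Procrustes ANOVA: multivariate regression of shape on log centroid size
#'
#' Least-squares fit of all `3p` Procrustes coordinates on natural-log
#' centroid size. Sums of squares are accumulated over all coordinate
#' variables; `R^2 = SS_model / SS_total`. Significance uses residual
#' randomization (RRPP): residuals of the intercept-only reduced model are
#' permuted across specimens, added back to the reduced-model fitted values,
#' and the full model is refit; the p-value is the proportion of permutations
#' (the observed fit counted among them) with `SS_model` at least as large
#' as observed.
#'
#' @param shapes [shape_arrays()] with centroid sizes.
#' @param n_perm number of random permutations (default 999).
#' @param seed RNG seed for the permutation schedule.
#' @return object of class `allometry_result`: list with `coefficients`
#'   (slope vector, length `3p`), `intercepts`, `r_squared`, `ss_model`,
#'   `ss_resid`, `ss_total`, `f_stat`, `z`, `p_value`, `residuals`
#'   (`n x p x 3`), `fitted`, `grand_mean`, `logsize`, and the input
#'   `shapes`.
#' @export
procrustes_anova <- function(shapes, n_perm = 999L, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  n <- dim(shapes$aligned)[1]
  if (n < 4) stop("need at least 4 specimens")
  x <- log(shapes$centroid_size)
  if (stats::sd(x) == 0) stop("log centroid size is constant; allometric fit undefined")
  Y <- flatten_coords(shapes$aligned)
  gm <- colMeans(Y)
  Yc <- sweep(Y, 2, gm)
  xc <- x - mean(x)
  b <- crossprod(xc, Yc) / sum(xc^2)          # 1 x 3p slope
  fitted_c <- outer(xc, drop(b))
  resid_mat <- Yc - fitted_c
  ss_total <- sum(Yc^2)
  ss_model <- sum(fitted_c^2)
  ss_resid <- sum(resid_mat^2)
  r2 <- ss_model / ss_total
  f_stat <- (ss_model / 1) / (ss_resid / (n - 2))

  # RRPP: reduced model = intercept only, so reduced residuals are Yc
  ss_perm <- numeric(n_perm)
  withr_seed(seed, {
    for (k in seq_len(n_perm)) {
      Yp <- Yc[sample.int(n), , drop = FALSE]
      fp <- outer(xc, drop(crossprod(xc, Yp) / sum(xc^2)))
      ss_perm[k] <- sum(fp^2)
    }
  })
  p_value <- (1 + sum(ss_perm >= ss_model)) / (n_perm + 1)
  dist_all <- c(ss_model, ss_perm)
  z <- (ss_model - mean(dist_all)) / stats::sd(dist_all)

  structure(list(coefficients = drop(b), intercepts = gm - drop(b) * mean(x),
                 r_squared = r2, ss_model = ss_model, ss_resid = ss_resid,
                 ss_total = ss_total, f_stat = f_stat, z = z,
                 p_value = p_value,
                 residuals = unflatten_coords(resid_mat),
                 fitted = unflatten_coords(sweep(fitted_c, 2, gm, "+")),
                 grand_mean = gm, logsize = x, n_perm = n_perm, seed = seed,
                 shapes = shapes),
            class = "allometry_result")
}

#' @export
print.allometry_result <- function(x, ...) {
  cat(sprintf("Procrustes ANOVA (shape ~ log CS): R2 = %.4f, F = %.3f, Z = %.2f, p = %.4g (%d perms)\n",
              x$r_squared, x$f_stat, x$z, x$p_value, x$n_perm))
  invisible(x)
}

#' Allometry-corrected residual shapes
#'
#' Repackages the residuals of a shape-on-size fit as [shape_arrays()] for
#' the downstream modules (the "allometry-corrected" branch). By default the
#' grand mean shape is added back so residual configurations live near the
#' consensus; with `recentre = FALSE` raw residual deviations are returned.
#'
#' @param result an [procrustes_anova()] fit.
#' @param recentre add the grand mean back (default TRUE).
#' @return [shape_arrays()] (centroid sizes and groups carried over).
#' @export
allometry_residuals <- function(result, recentre = TRUE) {
  res <- flatten_coords(result$residuals)
  if (recentre) res <- sweep(res, 2, result$grand_mean, "+")
  shape_arrays(unflatten_coords(res), result$shapes$centroid_size,
               result$shapes$group, symmetric = result$shapes$symmetric,
               pair_id = result$shapes$pair_id,
               specimen_ids = result$shapes$specimen_ids)
}

#' Compare allometric vectors between two groups of specimens
#'
#' Fits a shape-on-log-size slope vector within each group (optionally
#' restricted to one module's landmarks) and measures the angle between the
#' two vectors (arc-cosine of their vector correlation). The null
#' distribution of the angle comes from RRPP on the common-slope model:
#' residuals from the model with group-specific intercepts and a shared
#' slope are permuted, per-group slopes refit, and the angle recomputed;
#' p is the proportion of permutations (observed counted) with an angle at
#' least as large as observed.
#'
#' @param shapes [shape_arrays()].
#' @param grouping two-level factor over specimens (default the shapes'
#'   wild/domestic labels).
#' @param map,which optional module restriction (see [subset_module()]).
#' @param n_perm,seed permutation controls.
#' @return list with `angle_deg`, `vector_correlation`, `p_value`,
#'   `vectors` (2 x q matrix), `n_perm`.
#' @export
compare_allometric_vectors <- function(shapes, grouping = shapes$group,
                                       map = NULL, which = NULL,
                                       n_perm = 999L, seed = 1L) {
  if (!is.null(map) && !is.null(which))
    shapes <- subset_module(shapes, map, which)
  grouping <- as.character(grouping)
  levs <- unique(grouping)
  if (length(levs) != 2)
    stop("grouping must have exactly two levels; got ",
         paste(levs, collapse = ", "))
  if (any(table(grouping) < 4)) stop("each group needs n >= 4")
  x <- log(shapes$centroid_size)
  Y <- flatten_coords(shapes$aligned)
  g1 <- grouping == levs[1]

  fit_group_slopes <- function(Ymat) {
    slopes <- matrix(0, 2, ncol(Ymat))
    for (j in 1:2) {
      sel <- if (j == 1) g1 else !g1
      xg <- x[sel] - mean(x[sel])
      Yg <- sweep(Ymat[sel, , drop = FALSE], 2,
                  colMeans(Ymat[sel, , drop = FALSE]))
      slopes[j, ] <- crossprod(xg, Yg) / sum(xg^2)
    }
    slopes
  }
  angle_of <- function(slopes) {
    vc <- sum(slopes[1, ] * slopes[2, ]) /
      (sqrt(sum(slopes[1, ]^2)) * sqrt(sum(slopes[2, ]^2)))
    acos(max(-1, min(1, vc))) * 180 / pi
  }

  obs_slopes <- fit_group_slopes(Y)
  obs_angle <- angle_of(obs_slopes)

  # reduced (null) model: group intercepts + common slope
  X <- cbind(as.numeric(g1), as.numeric(!g1), x)
  qrX <- qr(X)
  fitted_red <- qr.fitted(qrX, Y)
  resid_red <- Y - fitted_red
  ang_perm <- numeric(n_perm)
  withr_seed(seed, {
    for (k in seq_len(n_perm)) {
      Yp <- fitted_red + resid_red[sample.int(nrow(Y)), , drop = FALSE]
      ang_perm[k] <- angle_of(fit_group_slopes(Yp))
    }
  })
  p_value <- (1 + sum(ang_perm >= obs_angle)) / (n_perm + 1)
  vc <- cos(obs_angle * pi / 180)
  list(angle_deg = obs_angle, vector_correlation = vc, p_value = p_value,
       vectors = obs_slopes, groups = levs, n_perm = n_perm, seed = seed)
}

#' Welch t-test on log centroid size between wild and domestic forms
#'
#' @param shapes [shape_arrays()].
#' @param grouping two-level factor (default the shapes' groups).
#' @return list with `t`, `df`, `p_value`, `means` (named, log CS scale).
#' @export
centroid_size_ttest <- function(shapes, grouping = shapes$group) {
  grouping <- as.character(grouping)
  levs <- sort(unique(grouping))
  if (length(levs) != 2) stop("grouping must have exactly two levels")
  x <- log(shapes$centroid_size)
  x1 <- x[grouping == levs[1]]; x2 <- x[grouping == levs[2]]
  if (length(x1) < 2 || length(x2) < 2)
    stop("both groups need at least 2 specimens")
  if (stats::sd(x1) == 0 && stats::sd(x2) == 0)
    stop("zero variance in both groups; t-test undefined")
  tt <- stats::t.test(x1, x2)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       means = stats::setNames(c(mean(x1), mean(x2)), levs))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so package functions never disturb the
# session RNG.
withr_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
}
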