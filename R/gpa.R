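#' Procrustes shape arrays
#'
#' Container for superimposed coordinates. Created by [gpa()] and
#' [symmetric_component()]; can also be assembled directly (e.g. from
#' simulated deviations) for the statistical layers, which only require the
#' `aligned` array, `centroid_size` and the `group` labels.
#'
#' @param aligned `n x p x 3` array of Procrustes coordinates (each
#'   configuration centred at the origin).
#' @param centroid_size positive length-`n` vector of pre-scaling sizes.
#' @param group per-specimen labels carried through from the dataset.
#' @param consensus `p x 3` mean shape (computed if missing).
#' @param symmetric logical flag: are these symmetric-component coordinates?
#' @param pair_id,specimen_ids metadata carried through.
#' @return object of class `shape_arrays`.
#' @export
shape_arrays <- function(aligned, centroid_size, group,
                         consensus = NULL, symmetric = FALSE,
                         pair_id = "pair", specimen_ids = NULL) {
  stopifnot(length(dim(aligned)) == 3L, dim(aligned)[3] == 3L)
  n <- dim(aligned)[1]
  if (length(centroid_size) != n || any(centroid_size <= 0))
    stop("centroid_size must be n positive scalars")
  if (is.null(consensus)) consensus <- apply(aligned, c(2, 3), mean)
  if (is.null(specimen_ids)) specimen_ids <- paste0("spec_", seq_len(n))
  structure(list(aligned = aligned, centroid_size = centroid_size,
                 group = as.character(group), consensus = consensus,
                 symmetric = symmetric, pair_id = pair_id,
                 specimen_ids = specimen_ids),
            class = "shape_arrays")
}

#' @export
print.shape_arrays <- function(x, ...) {
  cat(sprintf("shape_arrays '%s': %d specimens, %d landmarks%s\n",
              x$pair_id, dim(x$aligned)[1], dim(x$aligned)[2],
              if (isTRUE(x$symmetric)) " (symmetric component)" else ""))
  invisible(x)
}

#' Centroid size of a landmark configuration
#'
#' The standard geometric-morphometric size measure: square root of the sum
#' of squared distances of the landmarks from their centroid. Invariant to
#' translation and rotation; scales linearly under isotropic scaling.
#'
#' @param config `p x 3` coordinate matrix, `p >= 3`.
#' @return positive scalar.
#' @examples
#' sq <- cbind(c(-.5, .5, .5, -.5), c(-.5, -.5, .5, .5), 0)
#' centroid_size(sq) # sqrt(2)
#' @export
centroid_size <- function(config) {
  if (!is.matrix(config) || ncol(config) != 3 || nrow(config) < 3)
    stop("config must be a p x 3 matrix with p >= 3")
  if (any(!is.finite(config))) stop("non-finite coordinates")
  ctr <- sweep(config, 2, colMeans(config))
  cs <- sqrt(sum(ctr^2))
  if (cs == 0) stop("degenerate configuration: all landmarks coincide")
  cs
}

centre_config <- function(config) sweep(config, 2, colMeans(config))

# Optimal rotation (det +1) taking config B onto A: minimizes ||A - B R||_F.
# When the unconstrained optimum is a reflection, the determinant is forced
# positive by flipping the smallest singular direction; callers that treat
# reflection as a data error check the `reflection` attribute.
optimal_rotation <- function(A, B) {
  s <- svd(crossprod(B, A))
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  attr(R, "reflection") <- d < 0
  R
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition: every configuration is centred, scaled to unit
#' centroid size, and rotated onto the running consensus by orthogonal
#' Procrustes rotation (rotations only, determinant +1); the consensus is the
#' arithmetic mean of the rotated configurations, re-centred and re-scaled to
#' unit size, and iteration stops when its root-mean-square change drops
#' below `tol`. Rotations are always proper (determinant +1); a
#' configuration that aligns far better under a reflection signals
#' inconsistent left/right digitisation and raises an error rather than
#' being silently flipped.
#'
#' @param dataset a [landmark_dataset()] (or `shape_arrays`, whose aligned
#'   coordinates are then re-fit).
#' @param tol convergence tolerance on consensus RMS change (default 1e-10).
#' @param max_iter iteration cap (default 100).
#' @return [shape_arrays()] with `symmetric = FALSE`.
#' @export
gpa <- function(dataset, tol = 1e-10, max_iter = 100L) {
  coords <- if (inherits(dataset, "shape_arrays")) dataset$aligned
            else dataset$coords
  n <- dim(coords)[1]
  if (n < 2) stop("GPA needs at least 2 configurations")
  cs <- apply(coords, 1, function(i) NA_real_)
  scaled <- coords
  for (i in seq_len(n)) {
    cfg <- coords[i, , ]
    cs[i] <- centroid_size(cfg)
    scaled[i, , ] <- centre_config(cfg) / cs[i]
  }
  consensus <- scaled[1, , ]
  fit <- gpa_core(scaled, consensus, tol, max_iter)
  shape_arrays(fit$aligned, cs,
               group = if (!is.null(dataset$group)) dataset$group
                       else rep("wild", n),
               consensus = fit$consensus, symmetric = FALSE,
               pair_id = if (!is.null(dataset$pair_id)) dataset$pair_id else "pair",
               specimen_ids = if (!is.null(dataset$specimen_ids))
                 dataset$specimen_ids else NULL)
}

gpa_core <- function(scaled, consensus, tol, max_iter) {
  n <- dim(scaled)[1]; p <- dim(scaled)[2]
  aligned <- scaled
  for (iter in seq_len(max_iter)) {
    for (i in seq_len(n)) {
      R <- optimal_rotation(consensus, scaled[i, , ])
      if (attr(R, "reflection")) {
        # A proper rotation is always used; an error is raised only when a
        # reflection fits dramatically better (mirror-image digitising).
        s <- svd(crossprod(scaled[i, , ], consensus))
        R_improp <- s$u %*% diag(c(1, 1, -sign(det(s$u %*% t(s$v))))) %*%
          t(s$v)
        d_prop <- sum((consensus - scaled[i, , ] %*% R)^2)
        d_improp <- sum((consensus - scaled[i, , ] %*% R_improp)^2)
        if (d_prop > 4 * d_improp)
          stop("configuration ", i, " aligns far better under a reflection; ",
               "check left/right digitising consistency")
      }
      aligned[i, , ] <- scaled[i, , ] %*% R
    }
    new_cons <- apply(aligned, c(2, 3), mean)
    new_cons <- centre_config(new_cons)
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sqrt(mean((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol)
      return(list(aligned = aligned, consensus = consensus, iter = iter))
  }
  stop("GPA did not converge after ", max_iter,
       " iterations (last consensus RMS change ", signif(delta, 3), ")")
}

#' Procrustes distance between two aligned configurations
#'
#' Euclidean distance between flattened coordinate matrices; meaningful for
#' configurations from the same superimposition.
#'
#' @param a,b `p x 3` matrices.
#' @return non-negative scalar.
#' @export
procrustes_distance <- function(a, b) sqrt(sum((a - b)^2))

#' Subset aligned shapes to one module without re-superimposition
#'
#' Module statistics are computed in the shared coordinate system of the
#' joint fit ("simultaneous fit, then subset"): the selected landmarks'
#' coordinates are taken as-is, centroid sizes carried over unchanged. The
#' subset is deliberately NOT re-fit; re-running GPA on a subset generally
#' changes the coordinates.
#'
#' @param shapes [shape_arrays()].
#' @param map [module_map()] aligned with `shapes`.
#' @param which `"NC"` or `"MD"`.
#' @return [shape_arrays()] over the module's landmarks.
#' @export
subset_module <- function(shapes, map, which = c("NC", "MD")) {
  which <- match.arg(which)
  keep <- map$assignment == which
  if (!any(keep)) stop("empty landmark selection for module ", which)
  shape_arrays(shapes$aligned[, keep, , drop = FALSE],
               shapes$centroid_size, shapes$group,
               consensus = shapes$consensus[keep, , drop = FALSE],
               symmetric = shapes$symmetric, pair_id = shapes$pair_id,
               specimen_ids = shapes$specimen_ids)
}

#' Rigidly rotate an aligned sample onto a reference configuration
#'
#' Applies the single rotation that best maps the sample consensus onto
#' `reference` (scaled to unit centroid size) to every specimen. Used to put
#' GPA output into the coordinate frame of a known template, e.g. for
#' parameter-recovery checks against simulation truth.
#'
#' @param shapes [shape_arrays()].
#' @param reference `p x 3` matrix.
#' @return [shape_arrays()] in the reference frame.
#' @export
align_to_reference <- function(shapes, reference) {
  ref <- centre_config(reference)
  ref <- ref / sqrt(sum(ref^2))
  R <- optimal_rotation(ref, shapes$consensus)
  out <- shapes$aligned
  for (i in seq_len(dim(out)[1])) out[i, , ] <- out[i, , ] %*% R
  shape_arrays(out, shapes$centroid_size, shapes$group,
               consensus = shapes$consensus %*% R,
               symmetric = shapes$symmetric, pair_id = shapes$pair_id,
               specimen_ids = shapes$specimen_ids)
}

#' Subset aligned shapes to an arbitrary landmark selection
#'
#' Like [subset_module()] but with explicit landmark indices; coordinates are
#' taken from the joint fit without re-superimposition.
#'
#' @param shapes [shape_arrays()].
#' @param idx integer landmark indices (1-based).
#' @return [shape_arrays()] over the selected landmarks.
#' @export
subset_landmarks <- function(shapes, idx) {
  if (!length(idx)) stop("empty landmark selection")
  shape_arrays(shapes$aligned[, idx, , drop = FALSE],
               shapes$centroid_size, shapes$group,
               consensus = shapes$consensus[idx, , drop = FALSE],
               symmetric = shapes$symmetric, pair_id = shapes$pair_id,
               specimen_ids = shapes$specimen_ids)
}

#' Project aligned shapes onto the tangent space at the consensus
#'
#' Orthogonal projection of each unit-size aligned configuration onto the
#' tangent plane of the shape sphere at the consensus. The pipeline operates
#' on Procrustes coordinates directly (projection off by default everywhere);
#' for the small shape variation typical of intraspecific cranial data the
#' difference is far below the statistics' sampling error, and this function
#' makes the switch explicit for users who want it.
#'
#' @param shapes [shape_arrays()].
#' @return [shape_arrays()] with projected coordinates.
#' @export
project_tangent <- function(shapes) {
  cvec <- as.vector(t(shapes$consensus))
  cvec <- cvec / sqrt(sum(cvec^2))
  Y <- flatten_coords(shapes$aligned)
  proj <- Y - (Y %*% cvec - 1) %*% t(cvec)
  shape_arrays(unflatten_coords(proj), shapes$centroid_size, shapes$group,
               symmetric = shapes$symmetric, pair_id = shapes$pair_id,
               specimen_ids = shapes$specimen_ids)
}

#' Export aligned shapes as long-format CSV with a metadata header
#'
#' Writes `# key=value` comment lines (pair id, symmetric flag, GPA
#' tolerance) followed by a `specimen_id,group,landmark,x,y,z` table.
#'
#' @param shapes [shape_arrays()].
#' @param path output file.
#' @param tol the GPA tolerance to record (default 1e-10).
#' @return `path`, invisibly.
#' @export
export_aligned <- function(shapes, path, tol = 1e-10) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pair_id=%s", shapes$pair_id), con)
  writeLines(sprintf("# symmetric=%s", shapes$symmetric), con)
  writeLines(sprintf("# gpa_tol=%g", tol), con)
  n <- dim(shapes$aligned)[1]; p <- dim(shapes$aligned)[2]
  df <- data.frame(
    specimen_id = rep(shapes$specimen_ids, each = p),
    group = rep(shapes$group, each = p),
    landmark = rep(seq_len(p), times = n),
    x = as.vector(t(shapes$aligned[, , 1])),
    y = as.vector(t(shapes$aligned[, , 2])),
    z = as.vector(t(shapes$aligned[, , 3])))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
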