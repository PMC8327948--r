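#' Symmetric component of shape for object-symmetric configurations
#'
#' For structures with internal (object) symmetry, each specimen's
#' configuration and its mirrored, relabelled copy are superimposed jointly
#' in a single GPA over `2n` configurations; the per-specimen average of the
#' two aligned copies is the symmetric component, and the deviation of the
#' original from that average is the asymmetric component (so symmetric +
#' asymmetric reconstructs the aligned original exactly).
#'
#' After the joint fit the whole sample is rotated into a frame in which the
#' estimated symmetry plane is the coordinate plane normal to `axis`
#' (default: second axis, i.e. the plane y = 0), so midline landmarks of a
#' symmetric structure have (near-)zero coordinate on that axis. Midline
#' landmarks are not constrained onto the plane; a drift beyond
#' `midline_tol` (in unit-centroid-size shape units) triggers a warning
#' only.
#'
#' @param dataset a [landmark_dataset()] (raw coordinates; the joint fit is
#'   performed here) or [shape_arrays()].
#' @param pairing a [symmetry_pairing()] covering all landmarks.
#' @param axis symmetry-normal coordinate axis, 1, 2 or 3 (default 2).
#' @param midline_tol drift tolerance for the midline warning (default 0.05).
#' @param tol,max_iter GPA controls, see [gpa()].
#' @return [shape_arrays()] with `symmetric = TRUE` and attribute
#'   `asymmetric`: the `n x p x 3` array of asymmetric deviations.
#' @export
symmetric_component <- function(dataset, pairing, axis = 2L,
                                midline_tol = 0.05,
                                tol = 1e-10, max_iter = 100L) {
  coords <- if (inherits(dataset, "shape_arrays")) dataset$aligned
            else dataset$coords
  n <- dim(coords)[1]; p <- dim(coords)[2]
  if (pairing$p != p) stop("pairing covers ", pairing$p,
                           " landmarks but data has ", p)
  if (any(c(pairing$pairs, pairing$midline) > p))
    stop("pairing index out of range")

  # centre/scale originals, build mirrored relabelled copies
  cs <- numeric(n)
  scaled <- array(0, c(2L * n, p, 3L))
  for (i in seq_len(n)) {
    cfg <- coords[i, , ]
    cs[i] <- centroid_size(cfg)
    sc <- centre_config(cfg) / cs[i]
    scaled[i, , ] <- sc
    scaled[n + i, , ] <- mirror_swap(sc, pairing, axis)
  }

  fit <- gpa_core(scaled, scaled[1, , ], tol, max_iter)
  oriented <- orient_symmetry_plane(fit$aligned, fit$consensus, pairing, axis)

  sym <- array(0, c(n, p, 3L))
  asym <- array(0, c(n, p, 3L))
  for (i in seq_len(n)) {
    sym[i, , ] <- (oriented$aligned[i, , ] + oriented$aligned[n + i, , ]) / 2
    asym[i, , ] <- oriented$aligned[i, , ] - sym[i, , ]
  }

  if (length(pairing$midline)) {
    drift <- max(abs(sym[, pairing$midline, axis]))
    if (drift > midline_tol)
      warning(sprintf(
        "midline landmarks drift up to %.4g off the symmetry plane (tol %.4g)",
        drift, midline_tol))
  }

  out <- shape_arrays(sym, cs,
                      group = if (!is.null(dataset$group)) dataset$group
                              else rep("wild", n),
                      symmetric = TRUE,
                      pair_id = if (!is.null(dataset$pair_id))
                        dataset$pair_id else "pair",
                      specimen_ids = if (!is.null(dataset$specimen_ids))
                        dataset$specimen_ids else NULL)
  attr(out, "asymmetric") <- asym
  out
}

# Mirror a configuration across the plane normal to `axis` and swap the
# left/right landmark labels; a perfectly symmetric configuration maps onto
# itself.
mirror_swap <- function(config, pairing, axis = 2L) {
  m <- config
  m[, axis] <- -m[, axis]
  out <- m
  out[pairing$pairs[, 1], ] <- m[pairing$pairs[, 2], ]
  out[pairing$pairs[, 2], ] <- m[pairing$pairs[, 1], ]
  out
}

# Rotate an aligned sample so the estimated symmetry plane of its consensus
# is the coordinate plane normal to `axis`. The best-fitting reflection Q
# (orthogonal, det -1) mapping the relabelled consensus onto the consensus is
# found by constrained orthogonal Procrustes; its -1 eigenvector is the plane
# normal, which is rotated onto the requested axis.
orient_symmetry_plane <- function(aligned, consensus, pairing, axis) {
  A <- consensus
  A[pairing$pairs[, 1], ] <- consensus[pairing$pairs[, 2], ]
  A[pairing$pairs[, 2], ] <- consensus[pairing$pairs[, 1], ]
  s <- svd(crossprod(A, consensus))
  d <- sign(det(s$u %*% t(s$v)))
  Q <- s$u %*% diag(c(1, 1, -d)) %*% t(s$v)  # orthogonal with det(Q) = -1
  e <- eigen((Q + t(Q)) / 2, symmetric = TRUE)
  v <- e$vectors[, which.min(e$values)]
  # rotation whose `axis`-th column is v, remaining columns an orthonormal
  # complement with det +1 (deterministic Gram-Schmidt seed)
  seed <- diag(3)[, -axis, drop = FALSE]
  b1 <- seed[, 1] - sum(seed[, 1] * v) * v; b1 <- b1 / sqrt(sum(b1^2))
  b2v <- c(v[2] * b1[3] - v[3] * b1[2],
           v[3] * b1[1] - v[1] * b1[3],
           v[1] * b1[2] - v[2] * b1[1])
  R <- matrix(0, 3, 3)
  R[, axis] <- v
  others <- setdiff(1:3, axis)
  R[, others[1]] <- b1
  R[, others[2]] <- b2v
  if (det(R) < 0) R[, others[2]] <- -b2v
  out <- aligned
  for (i in seq_len(dim(aligned)[1])) out[i, , ] <- aligned[i, , ] %*% R
  list(aligned = out, consensus = consensus %*% R)
}
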