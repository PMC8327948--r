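# Shared fixtures and independent oracles used across the suite.

rand_config <- function(p) matrix(rnorm(p * 3), p, 3)

unitize <- function(config) {
  ctr <- sweep(config, 2, colMeans(config))
  ctr / sqrt(sum(ctr^2))
}

# uniform random rotation from a quaternion
rand_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

# small rotation about a random axis, angle ~ N(0, delta)
rand_small_rotation <- function(delta) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- rnorm(1, 0, delta)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# Brute-force minimum of ||A - B R|| over rotations: global random search
# followed by zoomed local refinement. Derivative-free and independent of
# the SVD solution used by the package.
bf_procrustes_dist <- function(A, B, n_global = 20000) {
  A <- unitize(A); B <- unitize(B)
  best_d <- Inf; best_R <- diag(3)
  for (k in seq_len(n_global)) {
    R <- rand_rotation()
    d <- sum((A - B %*% R)^2)
    if (d < best_d) { best_d <- d; best_R <- R }
  }
  delta <- 0.2
  while (delta > 1e-8) {
    improved <- FALSE
    for (k in 1:200) {
      R <- best_R %*% rand_small_rotation(delta)
      d <- sum((A - B %*% R)^2)
      if (d < best_d) { best_d <- d; best_R <- R; improved <- TRUE }
    }
    if (!improved) delta <- delta / 3
  }
  sqrt(best_d)
}

# draw n rows from N(0, Sigma)
rmvn <- function(n, Sigma) {
  ch <- chol(Sigma + diag(1e-12, nrow(Sigma)))
  matrix(rnorm(n * nrow(Sigma)), n) %*% ch
}

exch_corr <- function(q, rho) {
  C <- matrix(rho, q, q); diag(C) <- 1; C
}

# block correlation over two landmark modules (3 vars per landmark)
block_corr <- function(p1, p2, rho1, rho2, rho_b) {
  mod <- rep(c("a", "b"), times = c(3 * p1, 3 * p2))
  C <- matrix(rho_b, 3 * (p1 + p2), 3 * (p1 + p2))
  C[mod == "a", mod == "a"] <- rho1
  C[mod == "b", mod == "b"] <- rho2
  diag(C) <- 1
  C
}

# wrap an n x p x 3 array (already comparable coordinates) as shape_arrays
arr_shapes <- function(arr, group = rep("wild", dim(arr)[1]), cs = NULL) {
  if (is.null(cs)) cs <- rep(1, dim(arr)[1])
  shape_arrays(arr, cs, group)
}

# shape_arrays from an n x 3p matrix of flat coordinates
mat_shapes <- function(Y, group = rep("wild", nrow(Y)), cs = NULL) {
  arr_shapes(cranmod:::unflatten_coords(as.matrix(Y)), group, cs)
}

half_map <- function(p1, p2) module_map(rep(c("NC", "MD"), c(p1, p2)))
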