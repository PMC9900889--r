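make_ring <- function(P, N, centroid = rep(0, N), radius = 1, axes = NULL,
                      noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(axes)) {
    axes <- qr.Q(qr(matrix(rnorm(N * 2), N, 2)))
  }
  th <- (seq_len(P) - 0.5) * 2 * pi / P
  m <- cbind(cos(th), sin(th)) %*% t(axes) * radius
  m <- sweep(m, 2, centroid, "+")
  if (noise > 0) m <- m + matrix(rnorm(P * N, 0, noise), P, N)
  m
}

test_that("PCA spectrum: planar data is rank 2, isotropic noise is flat", {
  ring <- make_ring(100, 12, seed = 1)
  spec <- pca_variance_spectrum(ring)
  expect_equal(spec$cum_fraction[2], 1, tolerance = 1e-10)
  expect_true(all(diff(spec$cum_fraction) >= -1e-12))
  expect_equal(spec$cum_fraction[nrow(spec)], 1, tolerance = 1e-12)
  set.seed(2)
  iso <- matrix(rnorm(8000 * 20), 8000, 20)
  spec_iso <- pca_variance_spectrum(iso)
  expect_equal(spec_iso$var_fraction, rep(1 / 20, 20), tolerance = 0.15)
})

test_that("Procrustes misalignment is 0 for copies and rotations, ~1 for noise", {
  m1 <- make_ring(50, 30, noise = 0.05, seed = 3)
  same <- procrustes_misalignment(m1, m1, n_null = 200, seed = 4)
  expect_equal(same$rmse_observed, same$rmse_optimal, tolerance = 1e-12)
  expect_equal(same$score, 0, tolerance = 1e-9)
  R <- ringremap:::random_rotation(30)
  rot <- procrustes_misalignment(m1, m1 %*% R, n_null = 200, seed = 5)
  # a rotated copy has identical shape (optimal RMSE 0) but is maximally
  # misaligned in the ambient space, like a draw from the rotation null
  expect_lt(rot$rmse_optimal, 1e-10)
  expect_gt(rot$score, 0.5)
  expect_lte(rot$rmse_optimal, rot$rmse_observed)
  set.seed(6)
  g1 <- matrix(rnorm(50 * 30), 50, 30)
  g2 <- matrix(rnorm(50 * 30), 50, 30)
  indep <- procrustes_misalignment(g1, g2, n_null = 500, seed = 7)
  expect_gt(indep$score, 0.7)
  expect_lt(indep$score, 2)
})

test_that("Procrustes score is invariant to a common rotation of both manifolds", {
  m1 <- make_ring(40, 16, noise = 0.1, seed = 8)
  m2 <- make_ring(40, 16, noise = 0.1, seed = 9)
  base <- procrustes_misalignment(m1, m2, n_null = 300, seed = 10)
  Q <- ringremap:::random_rotation(16)
  both <- procrustes_misalignment(m1 %*% Q, m2 %*% Q, n_null = 300, seed = 10)
  expect_equal(both$rmse_observed, base$rmse_observed, tolerance = 1e-9)
  expect_equal(both$rmse_optimal, base$rmse_optimal, tolerance = 1e-9)
  expect_equal(both$score, base$score, tolerance = 0.05) # null is re-sampled
})

test_that("optimal rotation agrees with the vegan Procrustes oracle", {
  skip_if_not_installed("vegan")
  m1raw <- make_ring(40, 10, noise = 0.2, seed = 11)
  set.seed(12)
  # a noisy rotation of m1, so the unconstrained optimum is a proper rotation
  m2raw <- m1raw %*% ringremap:::random_rotation(10) +
    matrix(rnorm(400, 0, 0.05), 40, 10)
  m1 <- as_manifold(m1raw)
  m2 <- as_manifold(m2raw)
  ours <- procrustes_misalignment(m1, m2, n_null = 10, seed = 13)
  veg <- vegan::procrustes(as.matrix(m1), as.matrix(m2), scale = FALSE,
                           symmetric = FALSE)
  rmse_veg <- sqrt(sum((as.matrix(m1) - veg$Yrot)^2) / (40 * 10))
  # vegan permits reflections; ours is rotation-only, so ours >= vegan
  expect_gte(ours$rmse_optimal + 1e-12, rmse_veg)
  expect_equal(ours$rmse_optimal, rmse_veg, tolerance = 1e-6)
})

test_that("position subspace recovers a planted plane with orthonormal basis", {
  N <- 20
  axes <- diag(N)[, 1:2]
  ring <- make_ring(250, N, axes = axes, noise = 0.01, seed = 14)
  basis <- position_subspace(ring)
  expect_equal(unname(crossprod(basis)), diag(2), tolerance = 1e-10)
  expect_gt(subspace_cosine(axes[, 1], basis), 0.99)
  expect_gt(subspace_cosine(axes[, 2], basis), 0.99)
  # projection preserves the angular ordering of bins
  proj <- ring %*% basis
  ang <- atan2(proj[, 2], proj[, 1])
  shifts <- vapply(1:250, function(s) {
    cor(rank(c(ang[-seq_len(s)], ang[seq_len(s)])), 1:250)
  }, numeric(1))
  expect_gt(max(abs(shifts)), 0.99)
  expect_error(position_subspace(matrix(rep(1:5, 3), 5, 3)), "rank")
})

test_that("remapping dimension is the normalized centroid difference", {
  m1 <- make_ring(50, 12, seed = 15)
  v <- rnorm(12)
  m2 <- sweep(m1, 2, v, "+")
  dim12 <- remapping_dimension(list(m1, m2), 1, 2)
  expect_equal(dim12, v / sqrt(sum(v^2)), tolerance = 1e-10)
  expect_equal(remapping_dimension(list(m1, m2), 2, 1), -dim12, tolerance = 1e-10)
  expect_error(remapping_dimension(list(m1, m1), 1, 2), "identical")
})

test_that("remapping vectors of a pure translation are constant and rank 1", {
  m1 <- make_ring(50, 16, noise = 0.02, seed = 16)
  v <- rnorm(16, 0, 0.5)
  m2 <- sweep(m1, 2, v, "+")
  W <- matrix(rnorm(2 * 16), 2, 16)
  rv <- remap_vector_analysis(m1, m2, W)
  expect_equal(rv$v, v, tolerance = 1e-12)
  expect_equal(rv$bins$residual, rep(0, 50), tolerance = 1e-10)
  expect_equal(rv$spectrum$var_fraction[1], 1, tolerance = 1e-10)
  expect_equal(mean(rv$bins$residual) / mean(sqrt(rowSums(rv$xi^2))), 0,
               tolerance = 1e-10)
  # the linearity identity: W xi_p = W x_p(2) - W x_p(1), exactly
  expect_equal(rv$bins$w_norm,
               sqrt(rowSums((m2 %*% t(W) - m1 %*% t(W))^2)), tolerance = 1e-12)
})

test_that("nullspace rotation preserves decoded position but scrambles alignment", {
  N <- 24
  m1 <- make_ring(50, N, noise = 0.05, seed = 17)
  v <- rnorm(N, 0, 0.4)
  m2 <- sweep(m1, 2, v, "+")
  W <- matrix(rnorm(2 * N), 2, N)
  m2rot <- nullspace_rotation_control(m2, W, seed = 18)
  expect_equal(m2rot %*% t(W), m2 %*% t(W), tolerance = 1e-9)
  # identity rotation leaves the manifold untouched
  m2id <- nullspace_rotation_control(m2, W, rotation = diag(N - 2))
  expect_equal(m2id, m2, tolerance = 1e-9)
  # residuals around the mean remapping vector inflate under rotation
  rv_obs <- remap_vector_analysis(m1, m2, W)
  rv_rot <- remap_vector_analysis(m1, m2rot, W)
  expect_gt(mean(rv_rot$bins$norm_residual), mean(rv_obs$bins$norm_residual))
  # and the Procrustes misalignment increases
  s_obs <- procrustes_misalignment(m1, m2, n_null = 200, seed = 19)$score
  s_rot <- procrustes_misalignment(m1, m2rot, n_null = 200, seed = 19)$score
  expect_gt(s_rot, s_obs + 0.1)
})

test_that("subspace cosine hits its limits and its random-vector expectation", {
  N <- 100
  basis <- diag(N)[, 1:2]
  expect_equal(subspace_cosine(3 * basis[, 1] - 2 * basis[, 2], basis), 1,
               tolerance = 1e-12)
  expect_equal(subspace_cosine(diag(N)[, 5], basis), 0, tolerance = 1e-12)
  expect_error(subspace_cosine(rep(0, N), basis), "nonzero")
  set.seed(20)
  cs <- replicate(400, subspace_cosine(rnorm(N), basis))
  expect_lt(abs(mean(cs) - sqrt(2 / N)), 0.025)
})

test_that("pairwise remapping angles: equilateral centroids give 60 degrees", {
  N <- 10
  base <- make_ring(30, N, noise = 0.01, seed = 21)
  e1 <- diag(N)[, 1]
  e2 <- diag(N)[, 2]
  c2 <- e1
  c3 <- 0.5 * e1 + sqrt(3) / 2 * e2
  curves <- list(base, sweep(base, 2, c2, "+"), sweep(base, 2, c3, "+"))
  ang <- pairwise_remap_angles(curves)
  expect_equal(nrow(ang), 3)
  expect_equal(ang$angle_deg, rep(60, 3), tolerance = 0.5)
  # identical and orthogonal dimensions via the underlying cosine
  d12 <- remapping_dimension(curves, 1, 2)
  expect_equal(acos(abs(sum(d12 * d12))) * 180 / pi, 0, tolerance = 1e-6)
  expect_equal(acos(abs(sum(e1 * e2))) * 180 / pi, 90)
})

test_that("manifold preprocessing centers and normalizes", {
  m <- as_manifold(make_ring(40, 8, centroid = rnorm(8, 2), seed = 22))
  expect_equal(colMeans(m), rep(0, 8), tolerance = 1e-12)
  expect_equal(sqrt(sum(m^2)), 1, tolerance = 1e-12)
  expect_error(as_manifold(matrix(1, 10, 4)), "degenerate")
})
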