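#' Preprocess a tuning-curve matrix into a shape-analysis manifold
#'
#' Mean-centers each unit (column) and rescales the whole matrix to unit
#' Frobenius norm, the standard preprocessing before Procrustes shape
#' comparison.
#'
#' @param curves A `P x N` matrix of position-binned activity for one map.
#' @return A `manifold` matrix (columns mean zero, Frobenius norm 1).
#' @export
as_manifold <- function(curves) {
  x <- as.matrix(curves)
  x <- sweep(x, 2, colMeans(x))
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) stop("degenerate manifold: no variance.", call. = FALSE)
  structure(x / nrm, class = c("manifold", "matrix"))
}

#' Cumulative PCA variance spectrum
#'
#' Eigen-decomposes the covariance of mean-centered activity (rows =
#' samples, columns = units) and reports per-component and cumulative
#' explained-variance fractions. Rank-deficient inputs yield trailing
#' zero-variance components.
#'
#' @param activity Samples x N matrix (time steps, or stacked tuning-curve
#'   bins across maps).
#' @return Tibble with `component`, `var_fraction`, `cum_fraction`
#'   (nondecreasing, ending at 1).
#' @export
pca_variance_spectrum <- function(activity) {
  x <- as.matrix(activity)
  if (nrow(x) < 2) stop("need at least 2 samples.", call. = FALSE)
  sv <- prcomp(x, center = TRUE, scale. = FALSE)$sdev^2
  sv <- c(sv, rep(0, max(0, min(dim(x)) - length(sv))))
  tot <- sum(sv)
  tibble::tibble(
    component = seq_along(sv),
    var_fraction = sv / tot,
    cum_fraction = cumsum(sv) / tot
  )
}

# random rotation matrix (uniform over SO(n)): QR of a Gaussian matrix with
# sign correction, then determinant forced to +1
random_rotation <- function(n) {
  qrd <- qr(matrix(rnorm(n * n), n, n))
  q <- qr.Q(qrd)
  q <- sweep(q, 2, sign(diag(qr.R(qrd))), "*")
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# rotation (det +1) optimally aligning m2 to m1 in least squares
optimal_rotation <- function(m1, m2) {
  sv <- svd(crossprod(m2, m1))
  r <- tcrossprod(sv$u, sv$v)
  if (det(r) < 0) { # project to nearest proper rotation
    u <- sv$u
    u[, ncol(u)] <- -u[, ncol(u)]
    r <- tcrossprod(u, sv$v)
  }
  r
}

rmse_mat <- function(a, b) sqrt(mean((a - b)^2))

#' Procrustes misalignment between two manifolds
#'
#' Compares two bin-matched manifolds after mean-centering and unit-norm
#' rescaling. Reports the observed RMSE, the RMSE after the optimal
#' rotation (rotation only, determinant +1), a null distribution of RMSEs
#' under random rotations of the second manifold, and the normalized
#' misalignment score
#' `(RMSE_obs - RMSE_opt) / (RMSE_null - RMSE_opt)`, where `RMSE_null` is
#' the 25th percentile of the null. A score of 0 means the manifolds are as
#' aligned as a rotated copy; 1 means alignment is indistinguishable from a
#' random rotation (at the null's lower quartile).
#'
#' @param m1,m2 `P x N` matrices (tuning curves or [as_manifold()] objects)
#'   with rows corresponding to the same position bins.
#' @param n_null Number of random rotations in the null.
#' @param seed Optional integer seed.
#' @param null_quantile Quantile of the null used as the score's unit
#'   anchor (0.25 by default).
#' @return An object of class `alignment_result`.
#' @export
procrustes_misalignment <- function(m1, m2, n_null = 1000, seed = NULL,
                                    null_quantile = 0.25) {
  if (!is.null(seed)) set.seed(seed)
  m1 <- as_manifold(m1)
  m2 <- as_manifold(m2)
  stopifnot(all(dim(m1) == dim(m2)))
  n <- ncol(m1)
  obs <- rmse_mat(m1, m2)
  rot <- optimal_rotation(m1, m2)
  opt <- rmse_mat(m1, m2 %*% rot)
  null <- vapply(seq_len(n_null), function(i) {
    rmse_mat(m1, m2 %*% random_rotation(n))
  }, numeric(1))
  anchor <- quantile(null, null_quantile, names = FALSE)
  structure(
    list(
      rmse_observed = obs, rmse_optimal = opt, rmse_null = null,
      null_anchor = anchor, null_quantile = null_quantile,
      score = (obs - opt) / (anchor - opt), rotation = rot
    ),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment_result> misalignment score %.3f (RMSE observed %.4f, optimal %.4f, null q%.2f %.4f)\n",
    x$score, x$rmse_observed, x$rmse_optimal, x$null_quantile, x$null_anchor
  ))
  invisible(x)
}

#' @rdname procrustes_misalignment
#' @param x An `alignment_result`.
#' @param ... Unused.
#' @method glance alignment_result
#' @export
glance.alignment_result <- function(x, ...) {
  tibble::tibble(
    score = x$score, rmse_observed = x$rmse_observed,
    rmse_optimal = x$rmse_optimal, null_anchor = x$null_anchor,
    n_null = length(x$rmse_null)
  )
}

#' @rdname procrustes_misalignment
#' @method tidy alignment_result
#' @export
tidy.alignment_result <- function(x, ...) {
  tibble::tibble(draw = seq_along(x$rmse_null), rmse_null = x$rmse_null)
}

#' Position subspace across maps
#'
#' The top-2 principal axes of the position-binned activity. With several
#' maps this is a two-factor decomposition: each map's curves are centered
#' on that map's own mean before stacking, so the between-map (context)
#' separation is removed and the plane captures within-map positional
#' coding only. Context coding is expected to be orthogonal to this plane.
#'
#' @param curves A [compute_tuning_curves()] object (typically with 250
#'   bins), or a `P x N` matrix for a single map.
#' @param maps Which maps to stack (default all).
#' @return An `N x 2` orthonormal basis matrix.
#' @export
position_subspace <- function(curves, maps = NULL) {
  if (inherits(curves, "tuning_curves")) {
    labels <- attr(curves, "maps")
    if (is.null(maps)) maps <- labels
    x <- do.call(rbind, lapply(maps, function(m) {
      cm <- map_curves(curves, m)
      sweep(cm, 2, colMeans(cm)) # per-map (factor) centering
    }))
  } else {
    x <- as.matrix(curves)
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  if (length(pc$sdev) < 2 || pc$sdev[2] < 1e-12) {
    stop("activity has rank < 2; cannot extract a 2D position subspace.",
         call. = FALSE)
  }
  pc$rotation[, 1:2, drop = FALSE]
}

#' Remapping dimension between two maps
#'
#' The unit vector along the difference of the two maps' mean activations
#' (manifold centroids): `(mean of map j) - (mean of map i)`, normalized.
#' Context coding lives along this direction.
#'
#' @param curves A [compute_tuning_curves()] object or list of `P x N`
#'   matrices.
#' @param map_i,map_j Map labels or indices (direction points from i to j).
#' @return Unit-norm numeric vector of length N.
#' @export
remapping_dimension <- function(curves, map_i = 1, map_j = 2) {
  ci <- if (inherits(curves, "tuning_curves")) map_curves(curves, map_i) else curves[[map_i]]
  cj <- if (inherits(curves, "tuning_curves")) map_curves(curves, map_j) else curves[[map_j]]
  v <- colMeans(cj) - colMeans(ci)
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-12) stop("maps have identical centroids.", call. = FALSE)
  v / nrm
}

#' Remapping-vector analysis between two maps
#'
#' Computes the per-bin remapping vectors `xi_p = x_p(2) - x_p(1)` from two
#' bin-matched (raw, unpreprocessed) tuning-curve matrices, their average
#' `v`, the per-bin residuals `||xi_p - v||` (also normalized by the mean
#' remapping-vector length), the per-bin norms `||W xi_p||` of the
#' position-readout projection (which the linear decoder forces toward 0),
#' the singular spectrum of the `P x N` xi matrix (uncentered, so a pure
#' translation is exactly rank 1), and the bin-by-bin correlation of the
#' remapping vectors (smoothness over position).
#'
#' @param m1,m2 `P x N` raw tuning-curve matrices for maps 1 and 2.
#' @param W Position readout block from [position_readout()] (`2d x N`).
#' @return An object of class `remap_vectors`: list with `xi`, `v`, `bins`
#'   (tibble: `bin`, `residual`, `norm_residual`, `w_norm`), `spectrum`
#'   (tibble: variance fractions of the xi matrix), and `bin_cor`
#'   (`P x P`).
#' @export
remap_vector_analysis <- function(m1, m2, W = NULL) {
  m1 <- as.matrix(m1)
  m2 <- as.matrix(m2)
  stopifnot(all(dim(m1) == dim(m2)))
  xi <- m2 - m1
  v <- colMeans(xi)
  dev <- sweep(xi, 2, v)
  resid <- sqrt(rowSums(dev^2))
  mean_len <- mean(sqrt(rowSums(xi^2)))
  w_norm <- if (is.null(W)) rep(NA_real_, nrow(xi)) else {
    sqrt(rowSums((xi %*% t(W))^2))
  }
  sv <- svd(xi, nu = 0, nv = 0)$d^2
  spectrum <- tibble::tibble(
    component = seq_along(sv),
    var_fraction = sv / sum(sv),
    cum_fraction = cumsum(sv) / sum(sv)
  )
  structure(
    list(
      xi = xi, v = v,
      bins = tibble::tibble(
        bin = seq_len(nrow(xi)), residual = resid,
        norm_residual = resid / mean_len, w_norm = w_norm
      ),
      spectrum = spectrum,
      bin_cor = suppressWarnings(cor(t(xi)))
    ),
    class = "remap_vectors"
  )
}

#' @export
print.remap_vectors <- function(x, ...) {
  cat(sprintf(
    "<remap_vectors> %d bins x %d units; mean normalized residual %.3f; top-2 components %.1f%% of xi variance\n",
    nrow(x$xi), ncol(x$xi), mean(x$bins$norm_residual),
    100 * x$spectrum$cum_fraction[min(2, nrow(x$spectrum))]
  ))
  invisible(x)
}

#' @rdname remap_vector_analysis
#' @param x A `remap_vectors` object.
#' @param ... Unused.
#' @method tidy remap_vectors
#' @export
tidy.remap_vectors <- function(x, ...) x$bins

#' Rotate a manifold inside the nullspace of the position readout
#'
#' Control transformation: applies a random orthogonal rotation, restricted
#' to the nullspace of `W`, to the manifold's deviations from its centroid.
#' Decoded position (`W x_p`) is preserved at every bin (up to floating
#' point), while the manifold's orientation relative to a partner manifold
#' is scrambled — the null model against which the observed alignment of
#' two maps is judged.
#'
#' @param m2 `P x N` raw tuning-curve matrix.
#' @param W Position readout block (`2d x N`), full row rank.
#' @param seed Optional integer seed.
#' @param rotation Optional `(N - 2d) x (N - 2d)` rotation to apply in the
#'   nullspace (identity leaves the manifold unchanged); default random.
#' @return Rotated `P x N` matrix.
#' @export
nullspace_rotation_control <- function(m2, W, seed = NULL, rotation = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m2 <- as.matrix(m2)
  N <- ncol(m2)
  r <- nrow(W)
  qrw <- qr(t(W))
  if (qrw$rank < r) stop("`W` must have full row rank.", call. = FALSE)
  qfull <- qr.Q(qrw, complete = TRUE)
  vw <- qfull[, seq_len(r), drop = FALSE] # row space of W
  qn <- qfull[, (r + 1):N, drop = FALSE] # nullspace of W
  if (is.null(rotation)) rotation <- random_rotation(N - r)
  ctr <- colMeans(m2)
  dev <- sweep(m2, 2, ctr)
  mrot <- tcrossprod(vw) + qn %*% rotation %*% t(qn)
  sweep(dev %*% t(mrot), 2, ctr, "+")
}

#' Cosine similarity between a vector and a subspace
#'
#' The norm of the projection of `vec` onto the orthonormal `basis`,
#' divided by the norm of `vec`: 1 if the vector lies in the subspace, 0 if
#' orthogonal to it.
#'
#' @param vec Nonzero numeric vector of length N.
#' @param basis `N x k` orthonormal basis matrix (or a single vector).
#' @return Similarity in `[0, 1]`.
#' @export
subspace_cosine <- function(vec, basis) {
  basis <- as.matrix(basis)
  nrm <- sqrt(sum(vec^2))
  if (nrm < 1e-15) stop("`vec` must be nonzero.", call. = FALSE)
  min(1, sqrt(sum(crossprod(basis, vec)^2)) / nrm)
}

#' Pairwise acute angles between remapping dimensions
#'
#' For every pair of maps, the acute angle (degrees) between the two
#' unit-normalized centroid-difference vectors:
#' `acos(|cosine similarity|)`. With K maps arranged symmetrically (e.g.
#' three centroids at the vertices of an equilateral triangle) all pairwise
#' angles equal 60 degrees.
#'
#' @param curves A [compute_tuning_curves()] object with K >= 3 maps, or a
#'   list of `P x N` matrices.
#' @return Tibble with `map_i`, `map_j`, `angle_deg` for all unordered
#'   pairs of remapping dimensions (dimensions indexed against map 1's
#'   partner pairs: all pairs (i, j), i < j).
#' @export
pairwise_remap_angles <- function(curves) {
  labels <- if (inherits(curves, "tuning_curves")) attr(curves, "maps") else seq_along(curves)
  K <- length(labels)
  if (K < 3) stop("need at least 3 maps for pairwise remapping angles.", call. = FALSE)
  pairs <- utils::combn(K, 2)
  dims <- lapply(seq_len(ncol(pairs)), function(p) {
    remapping_dimension(curves, labels[pairs[1, p]], labels[pairs[2, p]])
  })
  dpairs <- utils::combn(length(dims), 2)
  tibble::tibble(
    dim_i = dpairs[1, ], dim_j = dpairs[2, ],
    angle_deg = vapply(seq_len(ncol(dpairs)), function(q) {
      cs <- abs(sum(dims[[dpairs[1, q]]] * dims[[dpairs[2, q]]]))
      acos(pmin(1, cs)) * 180 / pi
    }, numeric(1))
  )
}
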