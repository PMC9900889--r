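#' Sample initialization states for the fixed-point search
#'
#' Draws states uniformly from a recorded session's hidden trajectories and
#' adds noise-perturbed copies (isotropic Gaussian, SD a fraction of the
#' mean state norm), the standard way to seed a fixed-point search with
#' points near the manifold the dynamics actually visit.
#'
#' @param session A [build_session()] recording (or any list with a
#'   steps x N `hidden` matrix).
#' @param n_init Total number of initializations.
#' @param noise_frac Perturbation SD as a fraction of the mean state norm
#'   (half of the pool is perturbed).
#' @param seed Optional integer seed.
#' @return `N x n_init` matrix of initial states.
#' @export
sample_init_states <- function(session, n_init = 1024, noise_frac = 0.1,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  H <- session$hidden
  idx <- sample.int(nrow(H), n_init, replace = n_init > nrow(H))
  X0 <- t(H[idx, , drop = FALSE])
  n_pert <- n_init %/% 2
  if (n_pert > 0 && noise_frac > 0) {
    sdv <- noise_frac * mean(sqrt(colSums(X0^2)))
    cols <- (n_init - n_pert + 1):n_init
    X0[, cols] <- X0[, cols] + matrix(rnorm(nrow(X0) * n_pert, 0, sdv),
                                      nrow(X0), n_pert)
  }
  X0
}

#' Find approximate fixed points of the zero-input dynamics
#'
#' Minimizes `q(x) = ||x - ReLU(A x + beta)||^2` from each initialization
#' (input held at `u = 0`) by damped Gauss-Newton (Levenberg-Marquardt): the
#' residual is piecewise linear, so Gauss-Newton steps are exact within each
#' ReLU activation region and damping absorbs region crossings. Minima with
#' `q <` `tol` are retained and deduplicated: points closer than
#' `merge_radius` are merged, keeping the lowest-residual representative.
#' Each retained point's Jacobian spectrum is attached.
#'
#' @param params An [init_params()] object.
#' @param init_states `N x n` matrix of initial states (see
#'   [sample_init_states()]).
#' @param tol Convergence tolerance on the squared residual.
#' @param max_iter Iteration cap per initialization.
#' @param merge_radius Euclidean deduplication radius.
#' @return An object of class `fixed_points`: a tibble with one row per
#'   retained point (`id`, `residual`, `iterations`, `lambda_max` modulus,
#'   `n_unstable` eigenvalues outside the unit circle) plus attributes
#'   `states` (N x n matrix), `eigenvalues` (list of complex vectors) and
#'   `principal_eigenvectors` (N x n, eigenvector of the largest-modulus
#'   eigenvalue, real part, unit norm).
#' @export
find_fixed_points <- function(params, init_states, tol = 1e-8,
                              max_iter = 10000, merge_radius = 0.01) {
  check_params(params)
  init_states <- as.matrix(init_states)
  stopifnot(nrow(init_states) == params$n_units)
  res <- find_fixed_points_cpp(params$A, params$beta, init_states,
                               tol = tol, max_iter = max_iter)
  ok <- which(res$residual < tol)
  if (length(ok) == 0) {
    warning("no initialization converged below `tol`; returning empty set.")
    return(empty_fixed_points(params$n_units))
  }
  ord <- ok[order(res$residual[ok])]
  states <- res$states[, ord, drop = FALSE]
  keep <- integer(0)
  for (j in seq_len(ncol(states))) {
    if (length(keep) == 0) {
      keep <- j
    } else {
      d2 <- colSums((states[, keep, drop = FALSE] - states[, j])^2)
      if (min(d2) > merge_radius^2) keep <- c(keep, j)
    }
  }
  states <- states[, keep, drop = FALSE]
  n <- ncol(states)
  eigvals <- vector("list", n)
  pvecs <- matrix(0, params$n_units, n)
  lam <- numeric(n)
  nunst <- integer(n)
  for (j in seq_len(n)) {
    e <- eigen(jacobian_at(params, states[, j]))
    eigvals[[j]] <- e$values
    mods <- Mod(e$values)
    i1 <- which.max(mods)
    lam[j] <- mods[i1]
    nunst[j] <- sum(mods > 1 + 1e-9)
    v <- Re(e$vectors[, i1])
    pvecs[, j] <- v / sqrt(sum(v^2))
  }
  structure(
    tibble::tibble(
      id = seq_len(n),
      residual = res$residual[ord][keep],
      iterations = res$iterations[ord][keep],
      lambda_max = lam,
      n_unstable = nunst
    ),
    states = states, eigenvalues = eigvals,
    principal_eigenvectors = pvecs,
    class = c("fixed_points", "tbl_df", "tbl", "data.frame")
  )
}

empty_fixed_points <- function(N) {
  structure(
    tibble::tibble(
      id = integer(0), residual = numeric(0), iterations = integer(0),
      lambda_max = numeric(0), n_unstable = integer(0)
    ),
    states = matrix(0, N, 0), eigenvalues = list(),
    principal_eigenvectors = matrix(0, N, 0),
    class = c("fixed_points", "tbl_df", "tbl", "data.frame")
  )
}

#' Fixed-point hidden states
#'
#' @param fps A [find_fixed_points()] result.
#' @return `N x n` matrix of fixed-point states.
#' @export
fp_states <- function(fps) attr(fps, "states")

#' Jacobian of the zero-input update at a state
#'
#' The update `x -> ReLU(A x + beta)` is piecewise linear; its Jacobian at
#' `x*` is `diag(g) A` with `g_i = 1` where the pre-activation
#' `(A x* + beta)_i` is positive and 0 otherwise (the subgradient 0 is used
#' at an exact kink, and a warning is raised since the derivative is
#' undefined there).
#'
#' @param params An [init_params()] object.
#' @param x Hidden state vector (length N).
#' @return `N x N` Jacobian matrix.
#' @export
jacobian_at <- function(params, x) {
  check_params(params)
  h <- as.vector(params$A %*% x + params$beta)
  if (any(h == 0)) {
    warning("pre-activation exactly 0 for some unit; using subgradient 0.")
  }
  (h > 0) * params$A
}

#' Classify fixed points by their leading eigenvalue
#'
#' A fixed point is marginally stable when its largest Jacobian eigenvalue
#' modulus lies in `[1 - band, 1 + band]` (a slow direction along which
#' activity neither grows nor decays — the signature of an attractor
#' manifold), unstable when it exceeds `1 + band` (saddles routing activity
#' between attractors), and discarded otherwise.
#'
#' @param fps A [find_fixed_points()] result.
#' @param band Marginality half-width (default 0.05).
#' @return `fps` with a `class` column added
#'   (`"marginal"`, `"unstable"`, `"discarded"`).
#' @export
classify_fixed_points <- function(fps, band = 0.05) {
  fps$class <- dplyr::case_when(
    fps$lambda_max > 1 + band ~ "unstable",
    fps$lambda_max >= 1 - band ~ "marginal",
    TRUE ~ "discarded"
  )
  fps
}

#' Signed coordinate along the remapping dimension
#'
#' Projects states onto the unit vector between two map centroids, scaled
#' and shifted so the map-1 centroid maps to -1, the map-2 centroid to +1,
#' and the midpoint between the manifolds to 0. Components orthogonal to
#' the centroid-difference direction are ignored.
#'
#' @param x State vector, or `N x n` matrix of states.
#' @param centroid1,centroid2 Map centroids (length-N vectors).
#' @return Numeric coordinate(s).
#' @export
remap_projection <- function(x, centroid1, centroid2) {
  u <- centroid2 - centroid1
  mid <- (centroid1 + centroid2) / 2
  xm <- as.matrix(x)
  as.vector(2 * crossprod(xm - mid, u) / sum(u^2))
}

#' Assign fixed points to the ring manifolds or the space between them
#'
#' Separates fixed points resident on one of the two ring manifolds from
#' those between the rings. The default rule uses the signed coordinate
#' along the remapping dimension (map centroids at -1 and +1, midpoint at
#' 0): points with `|coordinate| >=` `coord_threshold` belong to a ring,
#' the rest lie between — mirroring how the census separates into clusters
#' at the centroids versus the midpoint. A distance rule (nearest
#' tuning-curve point within a quantile of the consecutive-bin spacings) is
#' available, but time-averaged tuning curves sit at a systematic offset
#' from the zero-input attractor backbone, so the distance rule is mainly
#' useful as a diagnostic; `dist_to_ring` is always reported.
#'
#' @param fps A [find_fixed_points()] result.
#' @param m1,m2 `P x N` raw tuning-curve matrices for the two maps.
#' @param method `"coordinate"` (default) or `"distance"`.
#' @param coord_threshold Coordinate cutoff for the ring assignment.
#' @param spacing_quantile Quantile of consecutive-bin spacings used as the
#'   on-ring threshold under the distance rule.
#' @return `fps` with `location` (`"ring"` or `"between"`), `dist_to_ring`,
#'   and `remap_coord` columns added.
#' @export
locate_fixed_points <- function(fps, m1, m2,
                                method = c("coordinate", "distance"),
                                coord_threshold = 0.5,
                                spacing_quantile = 0.05) {
  method <- match.arg(method)
  states <- fp_states(fps)
  ring <- rbind(as.matrix(m1), as.matrix(m2))
  d <- vapply(seq_len(ncol(states)), function(j) {
    sqrt(min(rowSums(sweep(ring, 2, states[, j])^2)))
  }, numeric(1))
  fps$dist_to_ring <- d
  fps$remap_coord <- remap_projection(states, colMeans(as.matrix(m1)),
                                      colMeans(as.matrix(m2)))
  if (method == "coordinate") {
    fps$location <- ifelse(abs(fps$remap_coord) >= coord_threshold,
                           "ring", "between")
  } else {
    spacing <- c(ring_spacings(m1), ring_spacings(m2))
    thr <- quantile(spacing, spacing_quantile, names = FALSE)
    fps$location <- ifelse(d < thr, "ring", "between")
  }
  fps
}

ring_spacings <- function(m) {
  m <- as.matrix(m)
  nxt <- rbind(m[-1, , drop = FALSE], m[1, , drop = FALSE])
  sqrt(rowSums((nxt - m)^2))
}

#' @rdname find_fixed_points
#' @param x A `fixed_points` object.
#' @param ... Unused.
#' @method tidy fixed_points
#' @export
tidy.fixed_points <- function(x, ...) tibble::as_tibble(x)
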