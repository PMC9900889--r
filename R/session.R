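#' Build a synthetic recording session from a trained network
#'
#' Emulates the structure of a trialized recording on a circular-linear
#' track: the trained network is driven with session-mode inputs (start at
#' angle 0, nonnegative velocities so the track is swept in one direction,
#' rare state changes — once per 500 steps by default), each sequence is
#' truncated to complete track traversals, and the sequences are
#' concatenated into one session. Each traversal is labelled with the most
#' commonly reported latent state over its steps (its "map").
#'
#' @param params An [init_params()] object (typically from [train_rnn()]).
#' @param task The task configuration the model was trained on.
#' @param seed Optional integer seed.
#' @param n_sequences Number of sequences to concatenate.
#' @param cue_rate Session-mode state-change rate per step.
#' @param seq_len Session sequence length; defaults to the task's `seq_len`.
#'   Simulating at the model's trained horizon keeps integration drift
#'   within the trained regime.
#' @return An object of class `session_recording`: a list with `steps`
#'   (tibble with one row per kept time step: sequence, traversal id, true
#'   and decoded angle and state, map label) and `hidden` (steps x N matrix
#'   of hidden activations).
#' @export
build_session <- function(params, task, seed = NULL, n_sequences = 50,
                          cue_rate = 1 / 500, seq_len = NULL) {
  check_params(params)
  stopifnot(inherits(task, "task_config"))
  if (task$n_spatial_dims != 1) {
    stop("sessions are built for 1D tasks (trialized track traversals).",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  cfg <- session_config(task, cue_rate = cue_rate)
  if (!is.null(seq_len)) cfg$seq_len <- as.integer(seq_len)
  trials <- generate_trials(cfg, n_trials = n_sequences)
  roll <- simulate_rnn(params, trials)

  n <- n_sequences
  Tn <- cfg$seq_len
  vel <- matrix(trials$inputs[1, , , drop = FALSE], n, Tn)
  kept <- vector("list", n)
  hidden_idx <- vector("list", n)
  trav_offset <- 0L
  for (i in seq_len(n)) {
    unwrapped <- cumsum(vel[i, ])
    lap <- 1L + as.integer(unwrapped %/% (2 * pi))
    n_complete <- max(lap) - 1L # laps fully finished within the sequence
    if (n_complete < 1L) next
    keep <- which(lap <= n_complete)
    st <- roll$steps[roll$steps$trial == i, ][keep, ]
    st$sequence <- i
    st$traversal <- trav_offset + lap[keep]
    kept[[i]] <- st
    # hidden slice column = trial i, slices keep+1 (slice 1 is x_0)
    hidden_idx[[i]] <- cbind(i, keep + 1L)
    trav_offset <- trav_offset + n_complete
  }
  kept <- dplyr::bind_rows(kept)
  if (nrow(kept) == 0) {
    stop("no complete traversals in the session; increase `seq_len`.",
         call. = FALSE)
  }
  N <- dim(roll$hidden)[1]
  hidden <- do.call(rbind, lapply(which(!vapply(hidden_idx, is.null, TRUE)),
    function(i) t(roll$hidden[, hidden_idx[[i]][1, 1], hidden_idx[[i]][, 2]])
  ))

  maps <- kept |>
    dplyr::group_by(.data$traversal) |>
    dplyr::summarise(map = modal_state(.data$true_state), .groups = "drop")
  kept <- dplyr::left_join(kept, maps, by = "traversal")
  steps <- dplyr::select(
    kept, "sequence", "traversal", "step",
    true_angle = "true_angle_1", decoded_angle = "decoded_angle_1",
    "true_state", "decoded_state", "map"
  )
  structure(
    list(steps = steps, hidden = hidden, n_units = N, task = cfg),
    class = "session_recording"
  )
}

modal_state <- function(s) {
  tab <- tabulate(s)
  which.max(tab) # ties broken toward the smaller label
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf(
    "<session_recording> %d steps, %d traversals, %d map(s), N=%d units\n",
    nrow(x$steps), dplyr::n_distinct(x$steps$traversal),
    dplyr::n_distinct(x$steps$map), x$n_units
  ))
  invisible(x)
}

#' @method as_tibble session_recording
#' @export
as_tibble.session_recording <- function(x, ...) x$steps

bin_index <- function(angle, n_bins) {
  # left-closed, right-open bins on [0, 2*pi)
  pmin(1L + as.integer(wrap_angle(angle) / (2 * pi) * n_bins), n_bins)
}

#' Position-binned tuning curves per map
#'
#' Divides the track into `n_bins` equal position bins on `[0, 2*pi)` and
#' averages each unit's activation over all steps falling in each bin,
#' separately per latent state (default) or per traversal map label.
#'
#' @param session A [build_session()] recording, or a list with `steps`
#'   (columns `true_angle`, `true_state` and/or `map`) and `hidden`.
#' @param n_bins Number of position bins (50 for alignment analyses, 250
#'   for subspace analyses, 80 for trial correlations).
#' @param by `"state"` to group steps by the true latent state, `"map"` to
#'   group by traversal map label.
#' @param angle `"true"` bins by the true track angle (the standard
#'   convention); `"decoded"` bins by the network's own position estimate,
#'   which parameterizes the ring manifold exactly even when a
#'   lightly-trained model's integrator has drifted.
#' @return An object of class `tuning_curves`: an `n_bins x N x n_maps`
#'   array with bin centers in `attr(, "bin_centers")`.
#' @export
compute_tuning_curves <- function(session, n_bins = 50,
                                  by = c("state", "map"),
                                  angle = c("true", "decoded")) {
  by <- match.arg(by)
  angle <- match.arg(angle)
  stopifnot(n_bins >= 2)
  st <- session$steps
  lab <- if (by == "state") st$true_state else st$map
  labels <- sort(unique(lab))
  ang <- if (angle == "true") st$true_angle else st$decoded_angle
  bins <- bin_index(ang, n_bins)
  out <- array(
    NA_real_, c(n_bins, session$n_units, length(labels)),
    dimnames = list(NULL, NULL, paste0("map", labels))
  )
  for (k in seq_along(labels)) {
    sel <- lab == labels[k]
    counts <- tabulate(bins[sel], n_bins)
    if (any(counts == 0)) {
      stop(sprintf(
        "empty position bin(s) %s for map %d; sample a longer session or use fewer bins.",
        paste(which(counts == 0), collapse = ", "), labels[k]
      ), call. = FALSE)
    }
    sums <- rowsum(session$hidden[sel, , drop = FALSE], bins[sel])
    out[, , k] <- sums / counts
  }
  structure(out,
    bin_centers = (seq_len(n_bins) - 0.5) * 2 * pi / n_bins,
    maps = labels, by = by, class = "tuning_curves"
  )
}

#' @export
print.tuning_curves <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<tuning_curves> %d bins x %d units x %d maps (by %s)\n",
    d[1], d[2], d[3], attr(x, "by")
  ))
  invisible(x)
}

#' @method as_tibble tuning_curves
#' @export
as_tibble.tuning_curves <- function(x, ...) {
  d <- dim(x)
  out <- tidyr::expand_grid(
    map = attr(x, "maps"), unit = seq_len(d[2]), bin = seq_len(d[1])
  )
  out$position <- attr(x, "bin_centers")[out$bin]
  out$activity <- x[cbind(out$bin, out$unit, match(out$map, attr(x, "maps")))]
  out
}

#' Extract one map's curve matrix
#'
#' @param curves A [compute_tuning_curves()] object.
#' @param map Map label (as in `attr(curves, "maps")`) or index.
#' @return A `P x N` matrix.
#' @export
map_curves <- function(curves, map) {
  stopifnot(inherits(curves, "tuning_curves"))
  k <- match(map, attr(curves, "maps"))
  if (is.na(k)) k <- as.integer(map)
  unclass(curves)[, , k]
}

#' Per-traversal position-binned population vectors and trial correlations
#'
#' Bins each traversal's population activity into `n_bins` position bins
#' and vectorizes it (bins x units, units fastest). Bins a traversal did
#' not visit are filled by circular linear interpolation across bins, since
#' a model traversal samples the track much more coarsely than a biological
#' trial. Pairwise Pearson correlations between traversal vectors give the
#' trial-by-trial similarity matrix.
#'
#' @param session A [build_session()] recording.
#' @param n_bins Position bins per traversal (80 by default).
#' @return An object of class `trial_matrix`: list with `vectors`
#'   (traversals x (bins*units) matrix), `cor` (traversal correlation
#'   matrix), and `trials` (tibble of traversal ids and map labels).
#' @export
trial_matrix <- function(session, n_bins = 80) {
  st <- session$steps
  travs <- sort(unique(st$traversal))
  N <- session$n_units
  vec <- matrix(NA_real_, length(travs), n_bins * N)
  for (i in seq_along(travs)) {
    sel <- st$traversal == travs[i]
    bins <- bin_index(st$true_angle[sel], n_bins)
    counts <- tabulate(bins, n_bins)
    m <- matrix(NA_real_, n_bins, N)
    m[counts > 0, ] <- rowsum(session$hidden[sel, , drop = FALSE], bins) /
      counts[counts > 0]
    if (any(counts == 0)) m <- apply(m, 2, interp_circular)
    vec[i, ] <- as.vector(t(m)) # units fastest within bin
  }
  trials <- st |>
    dplyr::distinct(.data$traversal, .data$map) |>
    dplyr::arrange(.data$traversal)
  cm <- cor(t(vec))
  structure(
    list(vectors = vec, cor = cm, trials = trials, n_bins = n_bins),
    class = "trial_matrix"
  )
}

# fill NA bins of a circular curve by linear interpolation around the ring
interp_circular <- function(v) {
  P <- length(v)
  known <- which(!is.na(v))
  if (length(known) == 0) return(rep(0, P))
  if (length(known) == P) return(v)
  ext_x <- c(known - P, known, known + P)
  ext_y <- rep(v[known], 3)
  stats::approx(ext_x, ext_y, xout = seq_len(P))$y
}

#' @export
print.trial_matrix <- function(x, ...) {
  cat(sprintf(
    "<trial_matrix> %d traversals x %d bins, correlation range [%.2f, %.2f]\n",
    nrow(x$vectors), x$n_bins, min(x$cor), max(x$cor)
  ))
  invisible(x)
}

#' Detect maps by k-means clustering of traversal vectors
#'
#' Clusters the per-traversal position-binned population vectors into `k`
#' maps. Vectors are z-scored per column (unit-bin) first; clustering uses
#' k-means++ seeding with 50 restarts, keeping the solution with the lowest
#' within-cluster sum of squares. Cluster ids are canonicalized by
#' descending cluster size (ties by centroid mean) so labels do not depend
#' on traversal order.
#'
#' @param trials A [trial_matrix()].
#' @param k Number of maps.
#' @param seed Optional integer seed.
#' @param n_restarts Number of k-means++ restarts.
#' @return Integer vector of per-traversal labels in `1..k`.
#' @export
detect_maps_kmeans <- function(trials, k, seed = NULL, n_restarts = 50) {
  stopifnot(inherits(trials, "trial_matrix"))
  x <- trials$vectors
  if (k > nrow(x)) {
    stop("`k` exceeds the number of traversals.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  if (k == 1) return(rep(1L, nrow(z)))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- kmeanspp_centers(z, k)
    km <- suppressWarnings(kmeans(z, centers = centers, iter.max = 100))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  relabel_clusters(best$cluster, best$centers)
}

kmeanspp_centers <- function(z, k) {
  n <- nrow(z)
  idx <- sample.int(n, 1)
  for (j in seq_len(k - 1)) {
    d2 <- apply(z[idx, , drop = FALSE], 1, function(c) rowSums(sweep(z, 2, c)^2))
    mind2 <- if (is.matrix(d2)) apply(d2, 1, min) else d2
    mind2[idx] <- 0
    if (sum(mind2) == 0) {
      idx <- c(idx, sample(setdiff(seq_len(n), idx), 1))
    } else {
      idx <- c(idx, sample.int(n, 1, prob = mind2))
    }
  }
  z[idx, , drop = FALSE]
}

relabel_clusters <- function(cluster, centers) {
  size <- tabulate(cluster, nrow(centers))
  ord <- order(-size, rowMeans(centers))
  match(cluster, ord)
}

#' Filter spatially unstable traversals
#'
#' Within each map, a traversal is kept iff its mean Pearson correlation
#' with all other traversals of the same map is at least `threshold`
#' (0.25 by default). Maps with fewer than two traversals are kept
#' trivially, with a warning.
#'
#' @param trials A [trial_matrix()].
#' @param labels Per-traversal map labels (defaults to the labels carried
#'   by the session).
#' @param threshold Minimum mean within-map correlation.
#' @return Logical vector: `TRUE` for kept traversals.
#' @export
stability_filter <- function(trials, labels = NULL, threshold = 0.25) {
  stopifnot(inherits(trials, "trial_matrix"))
  if (is.null(labels)) labels <- trials$trials$map
  stopifnot(length(labels) == nrow(trials$vectors))
  keep <- rep(TRUE, length(labels))
  for (m in unique(labels)) {
    sel <- which(labels == m)
    if (length(sel) < 2) {
      warning(sprintf("map %s has fewer than 2 traversals; kept trivially.", m))
      next
    }
    cm <- trials$cor[sel, sel, drop = FALSE]
    mean_cor <- (rowSums(cm) - 1) / (length(sel) - 1)
    keep[sel] <- mean_cor >= threshold
  }
  keep
}
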