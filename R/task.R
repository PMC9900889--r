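#' Wrap an angle onto the circular track
#'
#' Maps any finite angle to its representative in `[0, 2*pi)`. Positions on
#' the circular-linear track live on this interval throughout the package.
#'
#' @param angle Numeric vector of angles in radians.
#' @return Numeric vector of the same length, congruent to `angle` mod
#'   `2*pi` and lying in `[0, 2*pi)`.
#' @examples
#' wrap_angle(c(2 * pi, -pi / 2, 7))
#' @export
wrap_angle <- function(angle) {
  stopifnot(is.numeric(angle), all(is.finite(angle)))
  angle %% (2 * pi)
}

#' Task configuration for navigation with latent-state inference
#'
#' Parameterizes the synthetic task: a circular 1D (or toroidal 2D)
#' environment navigated by velocity integration, with a discrete latent
#' state ("context") among `n_states` alternatives that changes at random
#' times and is signalled only by a transient cue pulse.
#'
#' Per sequence, each spatial dimension gets an independent mean drift
#' `theta_bar ~ Normal(0, mean_drift_sd)` and per-step velocities
#' `delta_theta_t = theta_bar + eps_t`, `eps_t ~ Normal(0, step_noise_sd)`.
#' State changes arrive as a homogeneous Poisson process (realized per step
#' as Bernoulli(`cue_rate`)); at each change the new state is drawn
#' uniformly from the currently inactive states and announced by a unit
#' pulse of `cue_duration` steps on that state's cue channel. The initial
#' state is announced the same way during the first `cue_duration` steps.
#'
#' @param n_spatial_dims Number of spatial dimensions (1 or 2).
#' @param n_states Number of latent states K (at least 2).
#' @param seq_len Sequence length T in time steps.
#' @param mean_drift_sd SD of the per-sequence mean velocity (radians/step).
#' @param step_noise_sd SD of the per-step velocity noise (radians/step).
#' @param cue_rate Expected state changes per time step.
#' @param cue_duration Cue pulse length in time steps.
#' @param nonnegative_velocity If `TRUE`, velocities are `abs(theta_bar + eps_t)`
#'   so the trajectory sweeps the track in one direction (session regime).
#' @param init_angle Optional fixed initial angle (radians, recycled across
#'   dimensions); default `NULL` samples uniformly on `[0, 2*pi)`.
#' @return An object of class `task_config`.
#' @seealso [session_config()], [generate_trials()]
#' @export
task_config <- function(n_spatial_dims = 1, n_states = 2, seq_len = 600,
                        mean_drift_sd = 0.1, step_noise_sd = 0.3,
                        cue_rate = 1 / 50, cue_duration = 2,
                        nonnegative_velocity = FALSE, init_angle = NULL) {
  if (!n_spatial_dims %in% c(1L, 2L)) {
    stop("`n_spatial_dims` must be 1 or 2.", call. = FALSE)
  }
  if (n_states < 2) stop("`n_states` must be at least 2.", call. = FALSE)
  if (cue_duration < 1) stop("`cue_duration` must be at least 1.", call. = FALSE)
  if (cue_rate <= 0) stop("`cue_rate` must be positive.", call. = FALSE)
  if (seq_len < 1) stop("`seq_len` must be at least 1.", call. = FALSE)
  if (mean_drift_sd < 0 || step_noise_sd < 0) {
    stop("noise standard deviations must be nonnegative.", call. = FALSE)
  }
  structure(
    list(
      n_spatial_dims = as.integer(n_spatial_dims),
      n_states = as.integer(n_states),
      seq_len = as.integer(seq_len),
      mean_drift_sd = mean_drift_sd,
      step_noise_sd = step_noise_sd,
      cue_rate = cue_rate,
      cue_duration = as.integer(cue_duration),
      nonnegative_velocity = isTRUE(nonnegative_velocity),
      init_angle = init_angle
    ),
    class = "task_config"
  )
}

#' Session-mode variant of a task configuration
#'
#' Returns the configuration used to emulate a recording session: the
#' trajectory starts at angle 0, velocities are rectified so the track is
#' traversed repeatedly in one direction, and remapping is rare
#' (`cue_rate` once per 500 steps by default) to match the biologically
#' observed remapping rate.
#'
#' @param task A [task_config()].
#' @param cue_rate Expected state changes per step in session mode.
#' @return A `task_config` with session-mode settings.
#' @export
session_config <- function(task, cue_rate = 1 / 500) {
  stopifnot(inherits(task, "task_config"))
  task$cue_rate <- cue_rate
  task$nonnegative_velocity <- TRUE
  task$init_angle <- 0
  task
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf(
    "<task_config> %dD track, K=%d states, T=%d steps\n", x$n_spatial_dims,
    x$n_states, x$seq_len
  ))
  cat(sprintf(
    "  drift sd %.3g, step noise sd %.3g rad; cue rate 1/%.4g, pulse %d steps%s\n",
    x$mean_drift_sd, x$step_noise_sd, 1 / x$cue_rate, x$cue_duration,
    if (x$nonnegative_velocity) "; nonnegative velocity" else ""
  ))
  invisible(x)
}

#' Generate random task sequences
#'
#' Draws `n_trials` independent sequences from a task configuration:
#' velocity inputs, transient state cues, the initial-condition encoding
#' `z = (sin theta_0, cos theta_0)` per dimension, and ground-truth targets
#' (`sin theta_t`, `cos theta_t` per dimension, plus the active state label
#' at every step).
#'
#' The input vector at each step has `M = n_states + n_spatial_dims`
#' channels: velocities (radians/step) first, then one binary cue channel
#' per state. Positions evolve as
#' `theta_t = wrap(theta_{t-1} + delta_theta_t)`. A state-change event that
#' arrives while a cue pulse is still active is deferred until the pulse
#' ends; the state target switches at the first step of the new pulse.
#'
#' @param config A [task_config()].
#' @param n_trials Number of independent sequences.
#' @param seed Optional integer seed (sets the R RNG).
#' @return An object of class `trial_batch`: a list with arrays
#'   `inputs` (M x n x T), `init` (M0 x n), `target_pos` (2d x n x T,
#'   rows `(sin, cos)` per dimension), `target_state` (T x n),
#'   `angles` (d x n x T, wrapped true angles), `angle0` (d x n), and the
#'   generating `config`.
#' @examples
#' trials <- generate_trials(task_config(seq_len = 100), n_trials = 4, seed = 1)
#' dplyr::glimpse(tibble::as_tibble(trials))
#' @export
generate_trials <- function(config, n_trials = 1, seed = NULL) {
  stopifnot(inherits(config, "task_config"))
  if (!is.null(seed)) set.seed(seed)
  d <- config$n_spatial_dims
  K <- config$n_states
  Tn <- config$seq_len
  n <- as.integer(n_trials)
  M <- K + d

  theta_bar <- matrix(rnorm(d * n, 0, config$mean_drift_sd), d, n)
  vel <- array(rnorm(d * n * Tn, 0, config$step_noise_sd), c(d, n, Tn)) +
    as.vector(theta_bar) # theta_bar recycles over the time slices
  if (config$nonnegative_velocity) vel <- abs(vel)

  theta0 <- if (is.null(config$init_angle)) {
    matrix(runif(d * n, 0, 2 * pi), d, n)
  } else {
    matrix(wrap_angle(config$init_angle), d, n)
  }

  angles <- array(0, c(d, n, Tn))
  for (j in seq_len(d)) {
    vj <- matrix(vel[j, , , drop = FALSE], n, Tn)
    cum <- if (Tn == 1) vj else t(apply(vj, 1, cumsum))
    angles[j, , ] <- wrap_angle(theta0[j, ] + cum)
  }

  # latent-state process: initial uniform state, per-step Bernoulli events,
  # events arriving during an active pulse deferred by one step
  s <- sample.int(K, n, replace = TRUE)
  events <- matrix(runif(Tn * n) < config$cue_rate, Tn, n)
  target_state <- matrix(0L, Tn, n)
  inputs <- array(0, c(M, n, Tn))
  inputs[seq_len(d), , ] <- vel
  pulse_state <- s
  pulse_remaining <- rep(config$cue_duration, n) # initial-state cue
  pending <- rep(FALSE, n)
  for (t in seq_len(Tn)) {
    if (t > 1) {
      pending <- pending | events[t, ]
      starts <- pending & pulse_remaining == 0L
      if (any(starts)) {
        u <- sample.int(K - 1, sum(starts), replace = TRUE)
        new_state <- u + (u >= s[starts]) # uniform over inactive states
        s[starts] <- new_state
        pulse_state[starts] <- new_state
        pulse_remaining[starts] <- config$cue_duration
        pending[starts] <- FALSE
      }
    }
    active <- pulse_remaining > 0L
    if (any(active)) {
      inputs[cbind(d + pulse_state[active], which(active), t)] <- 1
      pulse_remaining[active] <- pulse_remaining[active] - 1L
    }
    target_state[t, ] <- s
  }

  target_pos <- array(0, c(2 * d, n, Tn))
  for (j in seq_len(d)) {
    target_pos[2 * j - 1, , ] <- sin(angles[j, , ])
    target_pos[2 * j, , ] <- cos(angles[j, , ])
  }
  init <- matrix(0, 2 * d, n)
  for (j in seq_len(d)) {
    init[2 * j - 1, ] <- sin(theta0[j, ])
    init[2 * j, ] <- cos(theta0[j, ])
  }

  structure(
    list(
      inputs = inputs, init = init, target_pos = target_pos,
      target_state = target_state, angles = angles, angle0 = theta0,
      config = config
    ),
    class = "trial_batch"
  )
}

#' @rdname generate_trials
#' @export
generate_trial <- function(config, seed = NULL) {
  generate_trials(config, n_trials = 1, seed = seed)
}

#' @export
print.trial_batch <- function(x, ...) {
  dm <- dim(x$inputs)
  cat(sprintf(
    "<trial_batch> %d trial(s) x %d steps, %d input channels (%dD, K=%d)\n",
    dm[2], dm[3], dm[1], x$config$n_spatial_dims, x$config$n_states
  ))
  invisible(x)
}

#' Long-format view of a trial batch
#'
#' @param x A `trial_batch`.
#' @param ... Unused.
#' @return A tibble with one row per (trial, step): true angles per
#'   dimension, the active latent state, and whether a cue pulse is on.
#' @method as_tibble trial_batch
#' @export
as_tibble.trial_batch <- function(x, ...) {
  d <- x$config$n_spatial_dims
  n <- dim(x$inputs)[2]
  Tn <- dim(x$inputs)[3]
  out <- tidyr::expand_grid(trial = seq_len(n), step = seq_len(Tn))
  for (j in seq_len(d)) {
    aj <- matrix(x$angles[j, , , drop = FALSE], n, Tn)
    out[[paste0("angle_", j)]] <- as.vector(t(aj))
  }
  out$state <- as.vector(x$target_state[cbind(out$step, out$trial)])
  cue <- apply(x$inputs[-seq_len(d), , , drop = FALSE], c(2, 3), max)
  out$cue_on <- as.vector(cue[cbind(out$trial, out$step)]) > 0
  out
}
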