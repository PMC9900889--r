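#' Initialize network parameters
#'
#' Creates the seven trainable parameter groups of the Elman network:
#' recurrent weights `A` (N x N), input weights `B` (N x M), hidden bias
#' `beta` (N), readout weights `C` (L x N) and bias `alpha` (L), and the
#' initial-condition encoder `D` (N x M0) with bias `gamma` (N). Sizes
#' follow the task: `M = K + d` inputs, `L = K + 2d` outputs,
#' `M0 = 2d` initial-condition inputs, for `K` latent states and `d`
#' spatial dimensions.
#'
#' Entries are drawn i.i.d. uniform on `(-1/sqrt(k), 1/sqrt(k))` with
#' `k = N` for the recurrent map and the readout (the standard recurrent-
#' layer initialization) and `k = M0` for the initial-condition encoder
#' (standard linear-layer fan-in scaling).
#'
#' @param n_units Hidden-layer size N.
#' @param n_states Number of latent states K.
#' @param n_spatial_dims Number of spatial dimensions d (1 or 2).
#' @param seed Optional integer seed.
#' @return An object of class `rnn_params`.
#' @export
init_params <- function(n_units = 248, n_states = 2, n_spatial_dims = 1,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- as.integer(n_units)
  K <- as.integer(n_states)
  d <- as.integer(n_spatial_dims)
  stopifnot(N >= 1, K >= 2, d %in% c(1L, 2L))
  M <- K + d
  M0 <- 2L * d
  L <- K + 2L * d
  runi <- function(n, k) runif(n, -1 / sqrt(k), 1 / sqrt(k))
  structure(
    list(
      A = matrix(runi(N * N, N), N, N),
      B = matrix(runi(N * M, N), N, M),
      beta = runi(N, N),
      C = matrix(runi(L * N, N), L, N),
      alpha = runi(L, N),
      D = matrix(runi(N * M0, M0), N, M0),
      gamma = runi(N, M0),
      n_units = N, n_states = K, n_spatial_dims = d
    ),
    class = "rnn_params"
  )
}

#' @export
print.rnn_params <- function(x, ...) {
  cat(sprintf(
    "<rnn_params> N=%d units, K=%d states, %dD (%d inputs, %d outputs)\n",
    x$n_units, x$n_states, x$n_spatial_dims,
    ncol(x$B), nrow(x$C)
  ))
  invisible(x)
}

check_params <- function(params) {
  stopifnot(inherits(params, "rnn_params"))
  invisible(params)
}

#' One step of the recurrent dynamics
#'
#' Applies `x_{t+1} = ReLU(A x_t + B u_t + beta)`. `x` and `u` may be
#' vectors or matrices with one column per batch element.
#'
#' @param params An [init_params()] object.
#' @param x Hidden state (length N vector, or N x batch matrix).
#' @param u Input vector (length M, or M x batch matrix).
#' @return Hidden state(s) of the same shape as `x`; entries nonnegative.
#' @export
rnn_step <- function(params, x, u) {
  check_params(params)
  xm <- as.matrix(x)
  um <- as.matrix(u)
  if (nrow(xm) != params$n_units || nrow(um) != ncol(params$B)) {
    stop("state/input dimensions do not match the parameters.", call. = FALSE)
  }
  out <- pmax(params$A %*% xm + params$B %*% um + params$beta, 0)
  if (is.matrix(x)) out else as.vector(out)
}

#' Initial hidden state from the position encoding
#'
#' Applies the linear initial-condition encoder `x_0 = D z + gamma` where
#' `z = (sin theta_0, cos theta_0)` per spatial dimension. The map is linear
#' as defined, so (unlike later states) `x_0` may have negative entries.
#'
#' @param params An [init_params()] object.
#' @param z Initial encoding (length `2d` vector, or `2d` x batch matrix).
#' @return Hidden state(s), length N.
#' @export
initial_state <- function(params, z) {
  check_params(params)
  zm <- as.matrix(z)
  if (nrow(zm) != ncol(params$D)) {
    stop("`z` must have length ", ncol(params$D), ".", call. = FALSE)
  }
  out <- params$D %*% zm + params$gamma
  if (is.matrix(z)) out else as.vector(out)
}

#' Linear readout and decoding
#'
#' Computes `y = C x + alpha` and decodes it: the position block holds
#' `(sin theta, cos theta)` predictions per spatial dimension, decoded with
#' the two-argument arctangent (invariant to positive rescaling of the
#' pair); the remaining K entries are state logits, decoded by argmax.
#'
#' @param params An [init_params()] object.
#' @param x Hidden state (length N vector, or N x batch matrix).
#' @return A list with `y` (raw outputs), `angle` (d x batch matrix of
#'   decoded angles in `[0, 2*pi)`), and `state` (integer vector of decoded
#'   states).
#' @export
readout <- function(params, x) {
  check_params(params)
  xm <- as.matrix(x)
  y <- params$C %*% xm + params$alpha
  dec <- decode_outputs(y, params$n_spatial_dims, params$n_states)
  c(list(y = if (is.matrix(x)) y else as.vector(y)), dec)
}

#' Decode raw output vectors
#'
#' @param y Output matrix (L x batch) or vector.
#' @param n_spatial_dims,n_states Task dimensions.
#' @return List with `angle` (d x batch) and `state` (integer batch vector).
#' @export
decode_outputs <- function(y, n_spatial_dims, n_states) {
  ym <- as.matrix(y)
  d <- n_spatial_dims
  angle <- matrix(0, d, ncol(ym))
  for (j in seq_len(d)) {
    angle[j, ] <- wrap_angle(atan2(ym[2 * j - 1, ], ym[2 * j, ]))
  }
  logits <- ym[(2 * d + 1):(2 * d + n_states), , drop = FALSE]
  list(angle = angle, state = as.integer(apply(logits, 2, which.max)))
}

#' Roll out the network over a batch of sequences
#'
#' Runs the full deterministic rollout `x_0 = D z + gamma`,
#' `x_{t+1} = ReLU(A x_t + B u_t + beta)`, `y_t = C x_t + alpha` over every
#' trial in a batch, recording hidden states and decoded outputs at every
#' step. Equivalent to composing [initial_state()], [rnn_step()] and
#' [readout()], but vectorized in compiled code.
#'
#' @param params An [init_params()] object.
#' @param trials A [generate_trials()] batch with matching dimensions.
#' @return An object of class `rnn_rollout`: list with `hidden`
#'   (N x n x T+1 array, slice 1 the initial state), `outputs`
#'   (L x n x T array), and `steps`, a tibble with one row per (trial,
#'   step) holding true and decoded angle(s) and state.
#' @export
simulate_rnn <- function(params, trials) {
  check_params(params)
  stopifnot(inherits(trials, "trial_batch"))
  d <- params$n_spatial_dims
  K <- params$n_states
  if (trials$config$n_spatial_dims != d || trials$config$n_states != K) {
    stop("trial batch and parameters disagree on task dimensions.", call. = FALSE)
  }
  fw <- rnn_forward_cpp(
    params$A, params$B, params$beta, params$C, params$alpha,
    params$D, params$gamma, trials$inputs, trials$init
  )
  n <- dim(trials$inputs)[2]
  Tn <- dim(trials$inputs)[3]
  steps <- tidyr::expand_grid(trial = seq_len(n), step = seq_len(Tn))
  Y <- matrix(fw$Y, nrow = dim(fw$Y)[1]) # L x (n*T), column = (t-1)*n + trial
  dec <- decode_outputs(Y, d, K)
  col_of <- (steps$step - 1L) * n + steps$trial
  for (j in seq_len(d)) {
    steps[[paste0("true_angle_", j)]] <-
      as.vector(matrix(trials$angles[j, , , drop = FALSE], n, Tn))[col_of]
    steps[[paste0("decoded_angle_", j)]] <- dec$angle[j, col_of]
  }
  steps$true_state <- trials$target_state[cbind(steps$step, steps$trial)]
  steps$decoded_state <- dec$state[col_of]
  structure(
    list(hidden = fw$X, outputs = fw$Y, steps = steps, params_meta = list(
      n_units = params$n_units, n_states = K, n_spatial_dims = d
    )),
    class = "rnn_rollout"
  )
}

#' @export
print.rnn_rollout <- function(x, ...) {
  dm <- dim(x$outputs)
  cat(sprintf(
    "<rnn_rollout> %d trial(s) x %d steps, N=%d hidden units\n",
    dm[2], dm[3], dim(x$hidden)[1]
  ))
  invisible(x)
}

#' @method as_tibble rnn_rollout
#' @export
as_tibble.rnn_rollout <- function(x, ...) x$steps

#' Position readout block
#'
#' Extracts the `2d x N` sub-block `W` of the readout weights `C` that
#' predicts `(sin theta, cos theta)` for the spatial dimensions. For the 1D
#' task this is the 2 x N matrix whose nullspace constrains how two maps may
#' differ without corrupting decoded position.
#'
#' @param params An [init_params()] object.
#' @return A `2d x N` matrix.
#' @export
position_readout <- function(params) {
  check_params(params)
  params$C[seq_len(2 * params$n_spatial_dims), , drop = FALSE]
}
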