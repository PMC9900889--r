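# Independent scalar-loop oracles for the network equations, kept free of
# matrix shortcuts so they can vouch for the compiled implementations.

oracle_step <- function(params, x, u) {
  N <- params$n_units
  out <- numeric(N)
  for (i in seq_len(N)) {
    acc <- params$beta[i]
    for (j in seq_len(N)) acc <- acc + params$A[i, j] * x[j]
    for (j in seq_along(u)) acc <- acc + params$B[i, j] * u[j]
    out[i] <- max(0, acc)
  }
  out
}

oracle_initial_state <- function(params, z) {
  N <- params$n_units
  out <- numeric(N)
  for (i in seq_len(N)) {
    acc <- params$gamma[i]
    for (j in seq_along(z)) acc <- acc + params$D[i, j] * z[j]
    out[i] <- acc
  }
  out
}

oracle_rollout <- function(params, trials) {
  n <- dim(trials$inputs)[2]
  Tn <- dim(trials$inputs)[3]
  X <- array(0, c(params$n_units, n, Tn + 1))
  for (b in seq_len(n)) {
    x <- oracle_initial_state(params, trials$init[, b])
    X[, b, 1] <- x
    for (t in seq_len(Tn)) {
      x <- oracle_step(params, x, trials$inputs[, b, t])
      X[, b, t + 1] <- x
    }
  }
  X
}

# scalar-loop composite loss (position MSE + state cross-entropy)
oracle_loss <- function(outputs, trials) {
  d <- trials$config$n_spatial_dims
  K <- trials$config$n_states
  n <- dim(trials$inputs)[2]
  Tn <- dim(trials$inputs)[3]
  se <- 0
  xe <- 0
  for (b in seq_len(n)) {
    for (t in seq_len(Tn)) {
      for (r in seq_len(2 * d)) {
        se <- se + (outputs[r, b, t] - trials$target_pos[r, b, t])^2
      }
      logits <- outputs[(2 * d + 1):(2 * d + K), b, t]
      pr <- exp(logits) / sum(exp(logits))
      xe <- xe - log(pr[trials$target_state[t, b]])
    }
  }
  list(position_mse = se / (2 * d * n * Tn), state_xent = xe / (n * Tn))
}

# build a session_recording-like object from a known tuning function:
# activity of unit i at angle th is f(th)[i] (+ optional noise)
synthetic_session <- function(f, n_units, n_steps = 4000, n_traversals = 40,
                              states = 1L, noise_sd = 0, seed = 1) {
  set.seed(seed)
  angle <- runif(n_steps, 0, 2 * pi)
  traversal <- rep(seq_len(n_traversals), length.out = n_steps)
  state <- if (length(states) == 1) rep(states, n_steps) else states
  hidden <- t(vapply(angle, f, numeric(n_units)))
  if (noise_sd > 0) hidden <- hidden + rnorm(length(hidden), 0, noise_sd)
  steps <- tibble::tibble(
    sequence = 1L, traversal = traversal, step = seq_len(n_steps),
    true_angle = angle, decoded_angle = angle,
    true_state = state, decoded_state = state
  )
  steps$map <- as.integer(ave(steps$true_state, steps$traversal, FUN = function(s) {
    which.max(tabulate(s))
  }))
  structure(
    list(steps = steps, hidden = hidden, n_units = n_units,
         task = task_config(n_states = max(2L, max(state)))),
    class = "session_recording"
  )
}
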