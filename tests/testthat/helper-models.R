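# Trained models shared across acceptance tests. Training happens once per
# test run and is memoized here; sizes are the scaled study size (N = 128,
# thousands of updates) so the whole suite stays within a practical runtime.

.model_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .model_cache)) {
    assign(key, build(), envir = .model_cache)
  }
  get(key, envir = .model_cache)
}

two_state_fit <- function() {
  cached("fit_2s", function() {
    train_rnn(
      task_config(n_spatial_dims = 1, n_states = 2),
      train_config(n_updates = 6000, seed = 20241),
      n_units = 128
    )
  })
}

two_state_session <- function() {
  cached("ses_2s", function() {
    fit <- two_state_fit()
    build_session(fit$params, fit$task, seed = 31,
                  seq_len = max(fit$history$seq_len))
  })
}

three_state_fit <- function() {
  cached("fit_3s", function() {
    train_rnn(
      task_config(n_spatial_dims = 1, n_states = 3),
      train_config(n_updates = 5000, seed = 20242),
      n_units = 128
    )
  })
}

three_state_session <- function() {
  cached("ses_3s", function() {
    fit <- three_state_fit()
    build_session(fit$params, fit$task, seed = 32,
                  seq_len = max(fit$history$seq_len))
  })
}

two_dim_fit <- function() {
  cached("fit_2d", function() {
    train_rnn(
      task_config(n_spatial_dims = 2, n_states = 2),
      train_config(n_updates = 5000, seed = 20243),
      n_units = 128
    )
  })
}
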