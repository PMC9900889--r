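test_that("tuning curves recover constant and sinusoidal fields", {
  # two units: one constant, one cos(theta)
  f <- function(th) c(2.5, cos(th))
  ses <- synthetic_session(f, n_units = 2, n_steps = 20000, seed = 1)
  tc <- compute_tuning_curves(ses, n_bins = 50)
  expect_equal(dim(tc), c(50, 2, 1))
  expect_equal(unclass(tc)[, 1, 1], rep(2.5, 50), tolerance = 1e-12)
  centers <- attr(tc, "bin_centers")
  expect_equal(unclass(tc)[, 2, 1], cos(centers), tolerance = 0.01)
})

test_that("maps differing by an additive offset differ bin-by-bin by that offset", {
  v <- c(1, -0.5, 2)
  set.seed(2)
  state <- sample(1:2, 10000, replace = TRUE)
  # piecewise-constant tuning (constant within each of the 40 bins), so the
  # binned difference between maps is the offset exactly
  f <- function(th) {
    b <- floor(th / (2 * pi) * 40)
    c(sin(2 * pi * b / 40), cos(2 * pi * b / 40), sin(4 * pi * b / 40))
  }
  ses <- synthetic_session(f, n_units = 3, n_steps = 10000, states = state, seed = 2)
  ses$hidden <- ses$hidden + outer(as.numeric(state == 2), v)
  tc <- compute_tuning_curves(ses, n_bins = 40, by = "state")
  diff_pm <- map_curves(tc, 2) - map_curves(tc, 1)
  for (u in 1:3) expect_equal(diff_pm[, u], rep(v[u], 40), tolerance = 1e-10)
})

test_that("empty position bins raise an informative error", {
  f <- function(th) c(1, th)
  ses <- synthetic_session(f, n_units = 2, n_steps = 200, seed = 3)
  ses$steps$true_angle <- runif(200, 0, pi) # half the track never visited
  expect_error(compute_tuning_curves(ses, n_bins = 50), "empty position bin")
})

test_that("sessions from a network have complete traversals partitioning the steps", {
  p <- init_params(n_units = 16, seed = 4)
  task <- task_config(seq_len = 400)
  ses <- build_session(p, task, seed = 5, n_sequences = 4)
  st <- ses$steps
  expect_equal(nrow(st), nrow(ses$hidden))
  # traversal lengths partition the kept steps
  expect_equal(sum(table(st$traversal)), nrow(st))
  # each traversal has a single map label equal to its modal true state
  per <- st |>
    dplyr::group_by(traversal) |>
    dplyr::summarise(
      map = unique(map),
      modal = which.max(tabulate(true_state)), .groups = "drop"
    )
  expect_equal(per$map, per$modal)
  # hidden rows correspond to the listed steps (spot check via re-simulation)
  expect_true(all(ses$hidden >= 0))
})

test_that("a session with no state changes carries a single map", {
  p <- init_params(n_units = 12, seed = 6)
  task <- task_config(seq_len = 300)
  ses <- build_session(p, task, seed = 7, n_sequences = 3, cue_rate = 1e-12)
  expect_equal(dplyr::n_distinct(ses$steps$map), 1L)
})

test_that("session remap counts match the once-per-500-steps expectation", {
  cfg <- session_config(task_config(seq_len = 600))
  tr <- generate_trials(cfg, n_trials = 200, seed = 8)
  changes <- sum(apply(tr$target_state, 2, function(s) sum(diff(s) != 0)))
  expected <- 200 * 600 / 500
  expect_gt(changes, 0.7 * expected)
  expect_lt(changes, 1.3 * expected)
})

test_that("trial matrix is a valid correlation structure over traversals", {
  f <- function(th) 1 + c(sin(th), cos(th), sin(2 * th), cos(2 * th))
  ses <- synthetic_session(f, n_units = 4, n_steps = 8000,
                           n_traversals = 20, noise_sd = 0.05, seed = 9)
  tm <- trial_matrix(ses, n_bins = 40)
  expect_equal(dim(tm$cor), c(20, 20))
  expect_equal(tm$cor, t(tm$cor), tolerance = 1e-12)
  expect_equal(diag(tm$cor), rep(1, 20))
  # traversals share the same tuning, so correlations are high
  expect_gt(min(tm$cor), 0.8)
})

test_that("k-means recovers planted clusters up to relabeling, and k = 1 is trivial", {
  set.seed(10)
  base1 <- rnorm(60)
  base2 <- rnorm(60)
  vecs <- rbind(
    t(replicate(12, base1 + rnorm(60, 0, 0.1))),
    t(replicate(10, base2 + rnorm(60, 0, 0.1)))
  )
  tm <- structure(
    list(vectors = vecs, cor = cor(t(vecs)),
         trials = tibble::tibble(traversal = 1:22, map = rep(1:2, c(12, 10))),
         n_bins = 15),
    class = "trial_matrix"
  )
  labels <- detect_maps_kmeans(tm, k = 2, seed = 11)
  truth <- rep(1:2, c(12, 10))
  agreement <- max(mean(labels == truth), mean(labels == 3 - truth))
  expect_equal(agreement, 1)
  expect_equal(detect_maps_kmeans(tm, k = 1), rep(1L, 22))
  expect_error(detect_maps_kmeans(tm, k = 30), "exceeds")
  # labels do not depend on traversal order (up to nothing: canonical ids)
  perm <- sample(22)
  tm2 <- tm
  tm2$vectors <- vecs[perm, ]
  tm2$cor <- cor(t(tm2$vectors))
  labels2 <- detect_maps_kmeans(tm2, k = 2, seed = 12)
  expect_equal(labels2, labels[perm])
})

test_that("stability filter drops unstable traversals at the stated threshold", {
  set.seed(13)
  base <- sin(seq(0, 2 * pi, length.out = 50))
  structured <- t(replicate(8, base + rnorm(50, 0, 0.1)))
  noise_trial <- rnorm(50)
  vecs <- rbind(structured, noise_trial)
  tm <- structure(
    list(vectors = vecs, cor = cor(t(vecs)),
         trials = tibble::tibble(traversal = 1:9, map = rep(1, 9)),
         n_bins = 50),
    class = "trial_matrix"
  )
  keep <- stability_filter(tm, labels = rep(1, 9), threshold = 0.25)
  expect_true(all(keep[1:8]))
  expect_false(keep[9])
  # identical traversals all survive any threshold up to 1
  same <- matrix(rep(base, 5), 5, byrow = TRUE) + 0 # exact copies
  tms <- structure(
    list(vectors = same, cor = suppressWarnings(cor(t(same))),
         trials = tibble::tibble(traversal = 1:5, map = rep(1, 5)),
         n_bins = 50),
    class = "trial_matrix"
  )
  expect_true(all(stability_filter(tms, rep(1, 5), threshold = 1)))
  # a map with a single traversal is kept trivially, with a warning
  expect_warning(
    keep2 <- stability_filter(tm, labels = c(rep(1, 8), 2), threshold = 0.25),
    "fewer than 2"
  )
  expect_true(keep2[9])
})

test_that("split halves of a long synthetic session give matching tuning curves", {
  f <- function(th) 1 + c(sin(th), cos(th), sin(3 * th), cos(2 * th), 0.5)
  ses <- synthetic_session(f, n_units = 5, n_steps = 30000,
                           noise_sd = 0.3, seed = 14)
  half1 <- list(steps = ses$steps[1:15000, ], hidden = ses$hidden[1:15000, ],
                n_units = 5, task = ses$task)
  half2 <- list(steps = ses$steps[15001:30000, ], hidden = ses$hidden[15001:30000, ],
                n_units = 5, task = ses$task)
  t1 <- compute_tuning_curves(half1, n_bins = 50)
  t2 <- compute_tuning_curves(half2, n_bins = 50)
  cc <- cor(as.vector(map_curves(t1, 1)), as.vector(map_curves(t2, 1)))
  expect_gt(cc, 0.9)
})
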