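---
title: "Methods: remapping between ring attractors in trained recurrent networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: remapping between ring attractors in trained recurrent networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Neurons in navigational circuits such as the medial entorhinal cortex
"remap": the whole population switches between distinct spatial maps of an
unchanged environment, apparently in response to internal state changes.
`ringremap` implements a minimal computational account of this phenomenon:
a recurrent network is trained to do two things at once —

1. **Path integration.** Integrate an angular velocity signal to track
   position on a circular track (a periodic 1D environment, or a 2D torus),
   reporting `sin θ` and `cos θ` per spatial dimension through a linear
   readout.
2. **Latent-state inference.** Remember which of K discrete latent states
   ("contexts") is active. State changes occur at random times and are
   announced only by a transient two-step cue pulse; the network must hold
   the state persistently and report it through a softmax readout.

Networks trained this way develop one ring-shaped activity manifold per
latent state, all encoding position the same way, mutually aligned, and
separated along context-coding directions orthogonal to the position code —
the same geometry observed in entorhinal recordings. The package trains
these models, converts their rollouts into session-like recordings, and
quantifies the geometry and dynamics.

## Model

The network is a discrete-time vanilla (Elman) recurrent network with
N nonnegative units, which can be read as firing rates:

- update: `x[t+1] = ReLU(A x[t] + B u[t] + β)`
- readout: `y[t] = C x[t] + α`
- initial condition: `x[0] = D z + γ`, with `z = (sin θ0, cos θ0)` per
  spatial dimension.

The initial condition is a *linear* map, exactly as written: `x[0]` may
contain negative entries even though all later states are rectified. The
seven trainable groups are `{A, B, β, C, α, D, γ}`; weights initialize
i.i.d. uniform on `(-1/√k, 1/√k)` with `k = N` for the recurrent and
readout maps and `k = 2d` for the initial-condition encoder (the standard
recurrent- and linear-layer fan-in conventions).

Inputs have `M = K + d` channels (d velocities in radians/step, then one
binary cue channel per state). Outputs have `L = 2d + K` channels:
`(sin θ, cos θ)` per dimension — a periodic target a linear readout can
actually produce, unlike raw angle — followed by K state logits. Decoding
uses `atan2(sin, cos)` (invariant to positive rescaling of the pair) and
argmax respectively.

## The task generator

All data are synthetic and generated on the fly; there is no external
dataset. Per sequence and spatial dimension:

| parameter | default | meaning |
|---|---|---|
| `mean_drift_sd` | 0.1 rad/step | SD of the per-sequence mean velocity θ̄ |
| `step_noise_sd` | 0.3 rad/step | SD of the per-step velocity noise ε_t |
| `cue_rate` | 1/50 per step | expected latent-state changes per step |
| `cue_duration` | 2 steps | length of the unit-amplitude cue pulse |
| `seq_len` | 600 steps | sequence length (training curriculum ends here) |

Velocities are `Δθ_t = θ̄ + ε_t`; the initial angle is uniform on
`[0, 2π)`; the initial state is uniform over K. State changes follow a
homogeneous Poisson process realized as an independent per-step Bernoulli
draw; at each change the new state is drawn uniformly from the K−1
*inactive* states. A change arriving while a pulse is still on is deferred
until the pulse ends, so cue pulses never overlap and at most one cue
channel is active at a time. The state *target* switches at the first pulse
step: the network is graded on reporting the new context from the moment it
is announced.

Two design points the task description leaves open, decided here once:

- **Initial state announcement.** The initial-condition encoding `z` carries
  only position, so the first active state would be unlearnable. The
  generator therefore emits a cue pulse for the initial state during the
  first `cue_duration` steps, exactly like a state change at t = 0.
- **Signed training velocities.** Training uses signed velocities; only
  session emulation (below) rectifies them.

**Session mode** (`session_config()`, `build_session()`) emulates the trial
structure of a recorded session on a circular-linear track: the trajectory
starts at θ = 0, velocities are `abs(θ̄ + ε_t)` so the track is swept in one
direction, state changes are rare (1/500 per step, matching the observed
remapping rate), 50 sequences are concatenated, incomplete final laps are
truncated, and every completed traversal is labelled with its most common
true latent state — its "map".

What the generator deliberately does **not** emulate: continuous behaviour
(running-speed fluctuations correlated with remapping), sensory landmarks,
reward, spiking variability, or electrode drift. Passing tests therefore
certify the computational account and the analysis pipeline, not any claim
about biological recordings.

## Training

Stochastic gradient descent on freshly generated batches (124 sequences per
update; an infinite-data regime, so there is no training set to overfit).
The loss is the unweighted sum of the position term (mean squared error of
the sin/cos predictions over all steps and dimensions) and the state term
(categorical cross-entropy at every step, cue steps included). Two
stabilizers are essential and match standard practice for vanilla RNNs:

- **Curriculum.** Sequences start at length 1 and grow by one step every 50
  updates, reaching T = 600 after 30,000 updates. Short early sequences let
  the readout and initial-condition encoder settle before long-horizon
  credit assignment begins.
- **Gradient clipping.** The global gradient norm over all seven groups is
  clipped to 2 at every update.

Backpropagation through time is derived by hand and implemented in
compiled code (RcppArmadillo); tests verify it against central finite
differences to ~1e-10.

The optimizer is the one genuinely open choice: neither a step size nor a
concrete gradient method is published for this task family beyond
"stochastic gradient descent". At the scaled problem size, plain SGD failed
to learn position integration at every stable learning rate we tried
(0.05–1.0: the position loss *rose* as the curriculum lengthened), and
classical momentum (0.9) only reached a position MSE around 0.08 — too
imprecise for the geometry analyses, which presuppose a solved task. Adam
with learning rate 1e-3 (standard betas) reaches MSE ≈ 0.016 in the same
budget and is the package default; `train_config(optimizer = "sgd",
momentum = )` recovers the plain and momentum variants. The choice was
fixed once, after a small sweep on the training loss alone, and every fit
logs its optimizer settings.

Training is bitwise reproducible from `train_config(seed = )` on a given
platform, and a non-finite loss aborts with the history attached.

## Problem sizes

Full-size models (N = 248, 30,000 updates) take on the order of hours on a
single CPU. The package's tests and the acceptance script instead use the
scaled study size: N = 128 units and 6,000 updates for two-state models
(curriculum to length 121), 8,000 updates for the three-state model, and
100 held-out sequences of 300 steps for evaluation. At this size the
latent-state readout saturates (100% accuracy) and the ring geometry is
fully formed; position integration is less precise than in a full run
(tens of degrees of accumulated angular error after 300 steps rather than
~8°), because integration accuracy keeps improving with curriculum length.
Quantities that depend on the *geometry* of the solution (alignment,
orthogonality, remapping-dimension angles, variance spectra) are stable at
this scale; quantities that measure integration *precision* are not, and
the tests treat them accordingly.

## Sessions, tuning curves, and map detection

Tuning curves divide the track into P equal bins on `[0, 2π)` (left-closed)
and average each unit over all steps in a bin, per latent state (or per
traversal map label). Following standard usage, P = 50 for manifold
alignment, P = 250 for subspace estimation, and P = 80 for trial-by-trial
correlations. Empty bins are an error, not silently imputed — except in
*per-traversal* vectors, where a single model traversal (~25 steps per lap
at mean speed ~0.25 rad/step) cannot populate 80 bins; unvisited bins are
filled by circular linear interpolation before correlating traversals. This
is the one place the synthetic sessions are sparser than biological trials,
and it is confined to `trial_matrix()`.

Map detection mirrors the k-means procedure used for multi-map recordings:
traversal vectors are z-scored per column, seeded with k-means++, and
clustered with 50 restarts keeping the lowest within-cluster sum of
squares; labels are canonicalized by cluster size so they do not depend on
traversal order. Spatially unstable traversals are excluded when their mean
Pearson correlation with same-map traversals falls below 0.25.

## Geometry

**Procrustes misalignment.** Each map's P×N curve matrix is mean-centered
per unit and scaled to unit Frobenius norm. The observed RMSE between the
two manifolds is compared with (i) the RMSE after the optimal rotation
(proper rotation only: determinant +1, projecting to the nearest rotation
if the unconstrained optimum reflects) and (ii) a null of 1000 random
rotations (QR of a Gaussian matrix with sign correction). The score
`(RMSE_obs − RMSE_opt) / (RMSE_null − RMSE_opt)` anchors 0 at "aligned as a
rotated copy" and 1 at the null's 25th percentile — the quartile anchor is
how the misalignment scores in this literature are normalized ("1 = p 0.25
of shuffle"). Both the null size and the quantile are arguments.

**Position subspace and remapping dimension.** The position subspace is the
top-2 principal plane of the stacked position-binned activity (250 bins);
the remapping dimension between two maps is the unit-normalized difference
of their mean activations. Cosine similarity between a vector and a
subspace is the norm of its projection onto the orthonormal basis divided
by its own norm.

**Remapping vectors.** `ξ_p = x_p(2) − x_p(1)` per bin, with mean `v`.
Because both maps decode position through the same linear readout W, the
trained solution satisfies `W ξ_p ≈ 0`. Reported quantities: per-bin
`‖W ξ_p‖`, residuals `‖ξ_p − v‖` (normalized by the mean `‖ξ_p‖` — the
normalizer is stated explicitly because the convention varies), the
singular spectrum of the ξ matrix computed *uncentered* so that a pure
translation is exactly rank 1, and the bin-by-bin correlation of ξ
(smoothness over position). The control transformation rotates one
manifold's deviations inside the nullspace of W (about its own centroid):
decoded position is preserved to machine precision while alignment and
residuals inflate to null levels.

## Fixed points and linear stability

Approximate fixed points of the zero-input dynamics minimize
`q(x) = ‖x − ReLU(A x + β)‖²`, started from 1024 states sampled from a
session rollout, half of them perturbed with isotropic noise at 10% of the
mean state norm. The minimizer is damped Gauss–Newton
(Levenberg–Marquardt): the residual is piecewise linear in x, so
Gauss–Newton steps are exact within each ReLU activation region and the
damping absorbs region crossings. We first implemented plain gradient
descent with backtracking, but on trained models it stalls on the nearly
flat directions along the rings (fewer than 10% of starts reached the
tolerance); Gauss–Newton converges from essentially every start in under
ten iterations to residuals near machine precision. Minima with `q <` 1e−8
are kept and deduplicated with a 0.01 merge radius (lowest residual wins).
The Jacobian at a fixed point is the analytic piecewise-linear derivative
`diag(g) A`, `g = 1` where the pre-activation is positive (subgradient 0 at
an exact kink, which is flagged); tests check it against finite
differences.

Classification follows the leading eigenvalue modulus: *marginally stable*
within `1 ± 0.05` (a slow direction — the attractor manifold), *unstable*
above (saddles that funnel activity between rings); the band is an argument
and recorded in the output. Placement on versus between the rings uses the
signed remapping coordinate (map centroids at ±1, midpoint at 0): points
with `|coordinate| ≥ 0.5` belong to a ring. A distance-to-tuning-curve rule
is also provided but is only diagnostic: time-averaged tuning curves sit at
a systematic offset from the zero-input attractor backbone (states during
driven navigation are not relaxed states), so nearest-curve distances do
not separate the populations, while the remapping coordinate separates them
cleanly into clusters at ±1 and near 0.

## Single-unit scores

Curves are smoothed with a circular Gaussian kernel (SD 2 bins, kernel
normalized so constants and total mass are preserved). Rate remapping is
the percent change in peak rate, referenced to map 1's peak (absolute
value; a symmetric mean-of-peaks reference is available since the
convention is not pinned down). Global remapping is 1 minus the cosine
similarity of the two binned curves. Units with a zero reference peak or a
zero curve are flagged rather than scored.

## Known limitations

- Scaled models trade integration precision for runtime (see "Problem
  sizes"); error magnitudes at horizon 300 are not comparable to full runs.
- The per-traversal bin interpolation makes trial correlations smoother
  than a spike-count analysis would be.
- Checkpoints serialize to JSON text (portable, diff-able) rather than a
  binary array container; at N ≈ 250 this is a few megabytes.
- Fixed-point search at very tight tolerances can stall on the flattest
  directions of the rings; the residual and iteration count of every
  retained point are reported so such points can be filtered.

## Session binning at scaled precision

Two measurement choices matter only for lightly trained (scaled) models and
are therefore worth stating explicitly. First, sessions are simulated at
the model's trained sequence length (`build_session(seq_len = )`): a model
trained on a 121-step curriculum and driven for 600 open-loop steps
accumulates integration drift far beyond anything it saw in training, which
says nothing about its solution geometry. Second, tuning curves can be
binned by the network's own decoded angle (`angle = "decoded"`) instead of
the true angle. The manifold is parameterized by the network's internal
position estimate; for a precisely trained integrator the two coincide to
within a bin, but a drifting scaled model smears true-angle bins across
internal positions and dilutes every downstream geometry statistic. The
default remains `"true"` (the convention used for biological data, where
position is observed directly); analyses of scaled models in this package's
tests use `"decoded"` and say so.
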