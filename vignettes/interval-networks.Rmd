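---
title: "Interval networks for post-hoc uncertainty quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval networks for post-hoc uncertainty quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Deep networks used to post-process model-based inversions of ill-posed
measurement operators (`y = A x + eta`) produce reconstructions whose errors
are hard to see: artifacts blend into plausible-looking signals. `innuq`
equips an **already trained** ReLU reconstruction network `Phi` with
component-wise prediction intervals, so that the interval width acts as a
per-component uncertainty heatmap, and evaluates how well such heatmaps
detect three failure modes: plain prediction error, adversarial input
perturbations, and out-of-distribution artifacts.

## The interval network model

An interval network replaces every weight matrix `W` and bias `b` of the
trained network with component-wise intervals `[W_lo, W_hi]`, `[b_lo, b_hi]`
subject to the box constraints `W_lo <= W <= W_hi` and `b_lo <= b <= b_hi`.
A point input is propagated with exact interval arithmetic. Two closed-form
rules cover everything this package needs:

* **Point input** `z` (possibly signed), used at the first
  interval-equipped layer:
  upper bound `rho(W_hi max(z,0) + W_lo min(z,0) + b_hi)`, lower bound with
  the weight bounds swapped.
* **Nonnegative interval input** `[z_lo, z_hi]`, valid after any ReLU
  layer: upper bound `rho(min(W_hi,0) z_lo + max(W_hi,0) z_hi + b_hi)`,
  lower bound `rho(max(W_lo,0) z_lo + min(W_lo,0) z_hi + b_lo)`, with
  minima/maxima taken component-wise.

Because all hidden activations are restricted to ReLU, these two rules are
sufficient: the first layer sees a point, every later layer sees a
nonnegative interval. Architectures that would route a *signed interval*
into a hidden layer are rejected rather than approximated. The final layer
uses the identity activation, for which both rules hold unchanged.

The propagated output `[Phi_lo(z), Phi_hi(z)]` has two properties that the
test suite asserts rather than assumes:

* **Containment.** `Phi_lo(z) <= Phi(z) <= Phi_hi(z)` whenever the box
  constraints hold — the construction guarantees it, and
  `forward_interval()` refuses to run when a constraint is violated.
* **Soundness.** The output of the base architecture under *any* parameter
  selection inside the intervals lies inside the propagated interval
  (checked by Monte-Carlo parameter sampling), and enlarging any parameter
  interval never shrinks the output interval.

## Training the intervals

With the base network frozen, the interval parameters minimise

```
sum_i ||max(x_i - Phi_hi(z_i), 0)||_2^2 + ||max(Phi_lo(z_i) - x_i, 0)||_2^2
      + beta * ||Phi_hi(z_i) - Phi_lo(z_i)||_1
```

— a hinge penalty for targets escaping the interval plus an l1 width
penalty. The tightness parameter `beta` trades coverage against interval
size; `select_beta()` implements the heuristic of choosing it near the base
network's mean absolute error, and the deconvolution reference
configuration uses `beta = 2e-3`.

Three mechanisms here were genuinely open design choices:

* **Constraint handling.** The box constraints are enforced by *exact
  projection* after every optimiser step: each bound is clamped against the
  frozen base parameter (`project_constraints()`). This keeps the
  containment guarantee valid at every moment of training. A
  reparameterisation through nonnegative offsets would work too; projection
  was chosen because it leaves the loss surface untouched and is trivially
  correct.
* **Optimiser.** Adam with learning rate `1e-3` and minibatches of 32,
  matching the schedule used for the base networks. The full-scale
  schedule trains base and intervals for 100 epochs each; all schedules are
  configuration values.
* **Initialisation.** Intervals start at
  `[W - init_width |W| - eps0, W + init_width |W| + eps0]` with
  `init_width = 0` and a tiny floor `eps0 = 1e-6`. Exactly zero-width
  intervals are a valid starting point but the width gradient of the hinge
  terms vanishes there only on covered components; the floor makes the l1
  term and the hinge terms active from the first step.
* **Subgradients of the weight splits.** `max(W,0)`/`min(W,0)` are
  piecewise linear; at 0 the subgradient of the nonnegative branch is used.
  Ties in interval parts (`DR = 1`) treat the upper part as the "larger"
  side; both conventions only matter on measure-zero sets.

## Uncertainty scores and diagnostics

The uncertainty score is the interval width `u(z) = Phi_hi(z) - Phi_lo(z)`.
An interval network evaluation costs twice a base forward pass, against a
factor `T` (at least 10, typically 64-128) for Monte Carlo dropout.

* **Coverage.** If interval training converges to a stationary point of the
  loss in expectation, a Markov-inequality argument bounds the probability
  of a target component lying inside the interval enlarged by `lambda*beta`
  below by `1 - 1/lambda`. The vanishing-gradient premise is only
  approximately true for a finitely trained network, so
  `empirical_coverage()` is checked softly (at `lambda = 2`, coverage at
  least `0.5 - 0.05`) rather than as a hard invariant.
* **Directionality.** `directionality_ratio()` is the larger interval part
  over the smaller one around the prediction; `directionality_accuracy()`
  is the fraction of targets falling in the larger part, per DR bin. 0.5 is
  chance; values above mean the asymmetry of the interval points toward the
  target. Binning is log-spaced over `[1, max(DR)]` (default 20 bins) with
  per-bin counts reported; the binning itself is not prescribed by the
  method, so counts are always returned and summary statements should be
  restricted to bins with enough mass (the acceptance evaluation uses a
  minimum of 25 components per bin, chosen so that binomial noise at
  chance level stays well below the 0.5 threshold). Components where the
  prediction sits on an interval boundary (smaller part below `1e-12`) have
  undefined DR and are excluded.
* **PWCC.** Error detection is scored by the Pearson correlation between
  `u(z)` and the absolute error, divided by the *mean* squared error of the
  prediction. The reference formulation displays the normalisation as a
  squared norm while describing it as the mean squared error; the package
  follows the mean-squared-error reading, which also matches the worked
  example in its test. Degenerate correlations (constant arguments) are
  reported as `NA` and excluded from averages with a logged count.
* **Heatmap-change correlations.** The adversarial and artifact protocols
  correlate `|u(z) - u(z_pert)|` per sample with a change map (the
  reconstruction change, or the binary insertion mask), then average over
  samples.

## Baselines

* **MCDrop**: sample standard deviation of `T` stochastic forward passes
  with independent dropout masks (`T = 64` in the deconvolution reference
  configuration). The dropout rate is not prescribed by the reference
  experiments; the default is 0.1, and the uncertainty scale (though not
  its spatial structure) depends on it roughly monotonically.
* **ProbOut**: the output head is doubled into mean and variance channels
  trained jointly from scratch with a Gaussian-likelihood-style loss
  (`probout_loss()`). Positivity of the variance head is enforced by
  predicting the log-variance and exponentiating — an implementation choice;
  any positive link would do. ProbOut cannot be attached post hoc; it is
  retrained with the base schedule. Note that the `|log var|` penalty has a
  kink at `var = 1`: for a fixed residual `r` the scalar loss is minimised
  at `var = r^2` when `r^2 >= 1` but at the kink itself when `r^2 < 1`, so
  the variance head is only a calibrated error estimate above unit scale
  (targets in this package live in `[0, 1]`, so ProbOut variances saturate
  accordingly — visible in its noise-sweep response).

## The synthetic benchmark

The only data source is synthetic: a 1D deconvolution problem with
`A = t(D) S D`, `D` the orthonormal Type-I DCT and
`s_j = ((n-j)/(n-1))^nu`, `j = 1..n` (so `s_1 = 1`, `s_n = 0`; the 1-based
index convention is forced by the requirement `s_j` in `[0, 1]`). The
reference configuration uses `n = m = 512` and `nu = 8`. Signals are
piecewise constant with jump count uniform on 4-12, jump positions uniform
without replacement, plateau heights uniform on `[0, 1]` (the jump-count
and height ranges are package choices made to produce signals with visible
plateau structure; they are surfaced in the configuration). The model-based
inversion is the identity, so the network input is the measurement itself.
Noise modes: none, measurement-only (`y = A x + eta`), and
measurement-and-signal (`y = A(x + eta1) + eta2`), all with
`eta ~ N(0, sigma^2 Id)`.

What the generator emulates: band-limited blurring of edges, additive
Gaussian noise, out-of-distribution block artifacts. What it does not:
correlated/structured noise, model mismatch in `A`, the null-space
structure of limited-angle tomography, or natural-image statistics. Passing
tests on this benchmark therefore demonstrate the *mechanics* of the
uncertainty machinery (containment, directionality, noise response), not
performance on clinical data.

## Desk-scale reference configuration

The packaged experiments run on one CPU, so the reference run of the
acceptance evaluation scales the full-scale schedule down; the scaled
choices are the package's own:

* 2000 sample pairs of length 512, split 1600/200/200 — as in the reference
  description.
* Ten 1D convolution layers, kernel 5, with dropout after layers 3, 5 and
  7. Hidden width 24 channels (the reference leaves the width unspecified;
  24 channels learn the task to a mean absolute error of a few times
  `1e-2` while keeping a full training run in minutes).
* 12 Adam epochs for the base network and 10 for the intervals with
  `beta = 2e-3` (the full schedule of 100 + 100 epochs is configurable and
  changes the numbers only gradually past ~10 epochs).
* Interval parameters on the trailing layers (6-10) of the stack. Interval
  training on a trailing suffix is part of the method's design (the
  tomography reference experiment also restricts intervals to the last
  layers); at this problem size it halves the training cost while leaving
  directionality and coverage behaviour intact. Equipping all ten layers is
  one configuration flag away.

## Known limitations

* Only dense and 1D convolution layers propagate intervals; pooling,
  normalisation and attention layers are out of scope, as are architectures
  feeding signed intervals into hidden layers.
* Interval training inherits the local-optimisation caveats of the base
  network: the coverage bound is conditional on near-stationarity of the
  trained loss.
* MCDrop results depend on the dropout rate and `T`; the packaged defaults
  are reasonable but not tuned.
* The JSON network container stores dense arrays as text; it is meant for
  desk-scale models, not for shipping large CNNs.
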