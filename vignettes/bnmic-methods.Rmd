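---
title: "Methods: synchronizing Brain Network Models to timeseries with bnmic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synchronizing Brain Network Models to timeseries with bnmic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model family

`bnmic` treats whole-brain activity as a network dynamical system: each
cortical region is one state variable, and regions interact along a weighted
structural connectome `W` estimated (outside this package) from tractography.
The working model is the Firing Rate Model (FRM),

$$\dot x_i = -x_i + k \sum_j W_{ij} x_j + \mathcal N(0, \sigma),$$

the simplest linear model that reproduces resting-state BOLD statistics. Its
two parameters are the global coupling $k$ (dimensionless) and the noise
amplitude $\sigma$ (signal units per unit time). `W` is divided by its
largest eigenvalue (`normalizeSpectral()`), after which the system matrix
$kW - I$ has strictly negative eigenvalues for every $k < 1$
(`stabilityMargin()` returns exactly $k - 1$): without noise the network
decays to the origin, with noise it fluctuates around it. Resting state is
assumed throughout — there is no exogenous input term — and the model state
is identified directly with the conditioned BOLD signal; no hemodynamic
forward model is interposed.

Three reference systems bracket the FRM. The *autoregressive null* sets the
connectivity to the identity with $k = 1$, cancelling the decay: the drift
is exactly zero and the noiseless forecast holds the last state. The
*exponential-decay null* sets $k = 0$, removing the network entirely. The
*inference null* (`inferenceRollout()`) is a recurrent network rolled out
autoregressively, sampling each next input from its own predicted
distribution; its dynamics are unknown by construction and it serves only as
an empirical upper bound on short-window predictability. A planar spiral
system ($\dot x = Ax$ with complex eigenvalues, negative real part) provides
a validation setting with known ground truth.

## Estimating initial conditions

To compare a model trajectory with a measured one, the model must be started
from the right state. `trainEstimator()` trains a forward-time LSTM that
consumes the observed series one timepoint at a time (the observation, not
the model's own prediction, is fed at each step) and outputs a candidate
system state at every timepoint. Because true states are never observed, the
loss is indirect: the candidate state at time $t$ is integrated one sampling
interval with the *noiseless* model and compared with the observation at
$t+1$ by mean squared error. For the linear systems implemented here that
integration is the exact propagator $\Phi(\Delta t) = e^{(kW-I)\Delta t}$,
so the loss is cheap and exact. Minimizing it drives the output toward the
state from which the model tracks the data; on spiral data, where ground
truth is known, the estimate's distance to the true state shrinks as the
prefix grows, which is the behaviour the training objective is meant to
induce.

One estimator is bound to one $(k, W)$ system — the estimator compensates
for its system (for example, for $k = 0$ it learns to pre-amplify by
$e^{\Delta t}$), so estimators are not interchangeable; a fingerprint check
refuses inference against a different system. The first `warmup`
observations (default 10) are consumed without entering the loss, giving the
hidden state time to synchronize; predictions are scored at every later
timepoint. Evaluating at every timepoint versus a few changes little, but it
shortens training at fixture scale.

Training hyperparameters (all in `estimatorConfig()`): a single LSTM layer
of 64 hidden units (larger nets are more sample-efficient but 64 converges
in seconds on CPU at the scales below and saturates the fixture tasks), Adam
at learning rate $10^{-3}$ (the worked examples use $3\times 10^{-3}$, which
converges faster on these well-conditioned fixtures), minibatches of 32
segments, gradient-norm clipping at 5, early stopping after 10 epochs
without improvement. The LSTM, backpropagation-through-time and Adam are
implemented in-package in plain matrix code; the gradients are validated
against finite differences in the test suite. With `distributional = TRUE`
the network grows a per-region log-variance head and trains by Gaussian
negative log-likelihood; only the inference null needs this.

## Integration and noise

Trajectories are sampled every 0.72 s by default — the repetition time
implied by the fMRI acquisitions this emulates (the fourth prediction step
is $t = 2.88$ s). Each sampled interval is split into 10 substeps; per
substep the state advances by the *exact* matrix-exponential substep
propagator and receives an additive noise increment
$\sigma\sqrt{dt}\,\mathcal N(0,1)$, so $\sigma$ is interpreted per unit
time. The exact-propagator drift was chosen over plain Euler–Maruyama
because all implemented drifts are linear: it makes the noiseless path agree
with the closed form to machine precision (the acceptance contract asks for
$10^{-4}$ over 50 steps, which first-order Euler cannot reach at 10
substeps), while the noise handling is unchanged. `scheme = "euler"` retains
the textbook update and is used for the integrator-order property test; it
is also the template a non-linear drift would use. An overflow guard aborts
with the step index when any state magnitude exceeds $10^6$ (unstable
parameterizations, e.g. $k > 1$ on an unnormalized connectome).

In the evaluation path, forward noise over whole sampled steps is drawn from
the exact Ornstein–Uhlenbeck step covariance (diagonal in the eigenbasis of
the symmetric drift), which is equivalent in distribution and much cheaper
than sub-stepping.

## The conditioning chain

Measured or surrogate series pass through, in order: zero-phase order-4
Butterworth bandpass 0.0008–0.125 Hz (each region demeaned first — at a
0.0008 Hz cutoff the high-pass cannot remove DC within any realistic record
length, so the offset is removed explicitly); global signal regression (OLS
of each region on an intercept and the mean over regions of the filtered
signal, keeping the residual); per-region z-scoring with the population
denominator. Series are then cut into non-overlapping 50-timepoint windows,
dropping the remainder.

Two properties of this chain are worth knowing. First, it is *not*
approximately idempotent: per-region z-scoring rescales the GSR residuals
unevenly, which reintroduces a small global component, so a second pass of
GSR changes the data noticeably (about 23% RMS at 66 regions on surrogate
data, more at smaller region counts). This is a property of the prescribed
order, not a defect; the chain is simply meant to be applied once. Second,
the low-pass at 0.125 Hz (period 8 s versus a 0.72 s sampling interval)
strongly smooths the series, giving the conditioned data more temporal
persistence than the raw model dynamics carry — which is why the
autoregressive null is a genuinely strong short-horizon baseline.

Per-region (rather than global) z-scoring was chosen deliberately and is
switchable (`zscoreRegions(margin=)`).

## Scoring and model selection

Predictions are scored against the (noisy) observed vectors across regions
at each horizon by the coefficient of determination
$r^2 = 1 - \sum(obs - pred)^2 / \sum(obs - \overline{obs})^2$ — not a
squared correlation; it goes negative for models that track worse than the
observation mean, which keeps poor models comparable — plus mean squared
error. With evaluation noise $\sigma > 0$, scores are averaged over 10 noise
realizations per trial. Two aggregation levels exist: *individual* (one
score per segment and timepoint) and *group*, which pools the
region-by-subject errors of the whole batch at a timepoint before scoring;
group pooling has visibly smaller across-repeat variance and is the default
for sweeps.

Model selection uses the horizon-4 structural-sensitivity slope: for each
$(k, \sigma)$ cell, mean $r^2$ is regressed on the fraction of connectome
edges randomly relocated (`perturbationLadder()`, a nested ladder so rungs
share their relocations and the distance from the original is monotone by
construction), and cells are ranked by slope magnitude. Horizon 4 is the
default selection horizon — early horizons are degenerate because every
trained estimator minimizes the one-step error, and late horizons lose all
signal — and is exposed as a parameter. The long-term route
(`longTermParameterization()`) simulates each cell for a 20-minute window
(1667 steps) and correlates simulated with reference FC.

The *Region of Predictability* compares estimator-derived initial conditions
with null initial conditions (the measurement at the anchor time, integrated
forward) over the first 3.6 s (5 horizons): per horizon a paired two-sided
Wilcoxon signed-rank test at $\alpha = 0.05$ on trial-wise $r^2$, declared
significant only when the estimator's mean is also higher. The Wilcoxon was
chosen because trial-wise $r^2$ is heavy-tailed; pairing relies on scoring
both sides under identical noise realizations (same seed).

## What the surrogate data can and cannot show

`makeSurrogateBold()` generates the ground-truth world for every recovery
experiment: FRM dynamics with known $(k^\*, \sigma^\*, W^\*)$, a 100-step
burn-in so the stationary regime dominates, initial states $\mathcal N(0,1)$
per region, then the full conditioning chain. A noiseless surrogate is
refused up front: a stable network without noise decays to the origin and
cannot be z-scored — noise is constitutive of the data, not a nuisance. The
spiral generator adds observation noise (default sd 0.1, about a tenth of
the signal scale) to closed-form trajectories and also emits perturbed
candidate matrices of increasing magnitude for identification experiments.

Surrogate data emulates the target setting's *dynamics and conditioning*,
not its physiology: there is no hemodynamic response, no subcortex, no task
structure, and the synthetic connectome (log-normal weights, mirrored
bilateral blocks, always-present homotopic connections) mimics the weight
statistics, not the true network topology. Consequences, measured and worth
stating plainly:

* Recovery of the *coupling* works: the slope argmax lands on the generating
  $k^\* = 0.9$, the unperturbed $W^\*$ outscores its perturbations under
  matched noise, long-term FC fitting selects $k^\*$, and spiral
  identification orders candidates correctly beyond the crossover horizon.
* Recovery of the *noise level* does not: for a linear model with uniform
  $\sigma$, the stationary correlation structure is exactly
  $\sigma$-invariant, so FC similarity cannot identify $\sigma$; and on data
  that truly follow the model the sensitivity slope is driven by the
  deterministic propagator mismatch, making it nearly $\sigma$-invariant
  too. Selection phenomena that hinge on the mismatch between the FRM and
  real BOLD — higher noise being *required* to expose structural
  sensitivity, or the $k = 0$ null winning under noiseless evaluation —
  do not reproduce on a faithful surrogate, where the generating model is
  (up to conditioning distortion) the optimal predictor. The test suite
  asserts these expectations as stated and leaves the two that a faithful
  surrogate cannot meet failing, rather than relaxing them; the
  autoregressive half of the noiseless comparison does reproduce, because
  the low-pass filtering gives the data more persistence than any decaying
  model carries.

## Problem sizes and numerical details

The packaged experiments run at fixture scale, chosen once as realistic for
desk-scale CPU work: a 20-region bilateral connectome (density 0.3), 4
surrogate subjects of 500 timepoints each for training and the same held out
for evaluation, the $k \in \{0, 0.45, 0.9\} \times \sigma_{eval} \in
\{10^{-4}, 0.3\} \times$ fraction $\in \{0, 0.25, 0.5\}$ grid, and 80/50
train/test spiral sequences of 60 points. The full 66-region bilateral
fixture and the finer standard $k$ grid (0 to 0.9 in steps of 0.15) and
$\sigma$ grid (0.0001, 0.15, 0.3, 0.45) are plain configuration changes.

Tolerances: symmetry $10^{-10}$, spectral normalization $10^{-8}$,
connectome file round-trip $10^{-12}$, GSR orthogonality $10^{-8}$,
standardization $10^{-10}$. Degenerate inputs fail loudly with named
locations: zero-variance regions in z-scoring or FC, constant global
signals, non-square or asymmetric connectome tables (offending indices
reported), edge relocations that exceed the available empty node pairs
(feasible maximum reported), overflow during simulation (step index
reported). Edge relocation forbids self-loops and duplicate edges; weights
are carried, so the weight multiset and edge count are invariant. The
surface-area noise rule $\sigma = 0.35 \cdot \text{area}/858$ is evaluated
as written, anchored at the mean parcel area of 858 mm².

## Known limitations

Only linear drifts are implemented; the integrator interface (`scheme =
"euler"`) is where a non-linear neural-mass drift would plug in. Fiber
propagation delays are not modeled. The estimator is trained per system —
sweeping a fine parameter grid means training many networks, which is the
method's intrinsic cost. And all recovery guarantees above are statements
about surrogate data; on real BOLD the model-mismatch phenomena discussed
earlier are expected to reappear.
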