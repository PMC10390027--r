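# bnmic

Initial-condition estimation and short-horizon model selection for Brain
Network Models (BNMs).

## The problem

Whole-brain network models reproduce time-averaged statistics of resting-state
fMRI — most prominently functional connectivity (FC) — but comparing a model
*trajectory* with a measured BOLD trajectory requires knowing where the model
should start. `bnmic` implements a forward-time recurrent estimator that
consumes a window of multivariate BOLD-like observations one timepoint at a
time and outputs, at every timepoint, the state of a prescribed dynamical
system that best synchronizes the model with the data. Training needs no
ground-truth states: the loss is the mean squared error between the next
observation and the one-interval integration of the current state estimate,

```
loss(t) = || x(t+1) − Φ(Δt) x̂(t) ||²,     Φ(Δt) = exp((kW − I) Δt)
```

so the estimator converges toward the state from which the model tracks the
data. Once models can be synchronized to data, they can be *compared*: all
candidates fit the next timepoint about equally well, but their trajectories
diverge from the data at longer horizons at rates that reflect how well each
candidate captures the underlying dynamics.

The dynamical core is the Firing Rate Model (FRM), the simplest linear BNM,

```
ẋᵢ = −xᵢ + k Σⱼ Wᵢⱼ xⱼ + N(0, σ)
```

with global coupling `k`, noise amplitude `σ`, and a structural connectome
`W` normalized by its largest eigenvalue (so `k < 1` is stable). Null models
(autoregressive, pure exponential decay, and an autoregressive
machine-learning rollout), structural-connectome perturbation ladders, the
rs-fMRI conditioning chain (0.0008–0.125 Hz zero-phase bandpass, global
signal regression, per-region z-scoring, 50-timepoint segmentation), and the
scoring machinery (per-horizon r², structural-sensitivity slopes, long-term
FC fitting, the Region of Predictability) are all included, along with
generators for spiral validation data and surrogate BOLD from a known FRM so
every experiment runs offline.

## Worked example

Synthesize a connectome and surrogate BOLD from a known FRM, train an
estimator for that model, and score its forward predictions on held-out data
(about half a minute on a laptop CPU):

```r
library(bnmic)

conn <- normalizeSpectral(synthConnectome(20, density = 0.3, seed = 1,
                                          bilateral = TRUE))
bold <- makeSurrogateBold(conn, kTrue = 0.9, sigmaTrue = 0.3,
                          nSubjects = 4, nTimepoints = 500, seed = 2)
est <- trainEstimator(bold, frmModel(conn, k = 0.9),
                      estimatorConfig(hiddenSize = 64, nEpochs = 80,
                                      learningRate = 3e-3, seed = 3))
est
#> TrainedEstimator for <frm> (k = 0.9, 20 regions): 80 epochs, loss 0.9971 -> 0.04184

test <- makeSurrogateBold(conn, kTrue = 0.9, sigmaTrue = 0.3,
                          nSubjects = 4, nTimepoints = 500, seed = 4)
horizonScores(est, test, horizons = 1:4, sigma = 0.3, seed = 5)
#> HorizonScores (group aggregation, 37 trials/horizon)
#>   horizon 1: mean r2 = 0.8781
#>   horizon 2: mean r2 = 0.5510
#>   horizon 3: mean r2 = 0.2547
#>   horizon 4: mean r2 = 0.0839
```

The training loss falls from ~1 (the variance of the z-scored signal) to
0.042: the estimator has learned to synchronize the model one step ahead.
The per-horizon r² then shows trajectory divergence: predictions explain 88%
of the cross-regional variance one repetition time (0.72 s) ahead and decay
toward chance by the fourth step — and it is exactly this divergence profile
that separates well- from mis-parameterized models. Higher-level drivers run
the full experiments:

```r
runSpiralValidation(seed = 1)   # system identification with known ground truth
runSweep(outDir = "sweep")      # (k x sigma x perturbation) recovery sweep
```

A thin command-line front end with the same functionality is installed at
`system.file("cli", "bnmic", package = "bnmic")`.

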