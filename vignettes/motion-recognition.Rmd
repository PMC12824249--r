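---
title: "Recognising and predicting movement from rigid- and fabric-attached sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising and predicting movement from rigid- and fabric-attached sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(fabmotion)
```

## The problem

A sensor strapped to a rigid body part (a wrist, a robot end-effector, the
tip of a crank mechanism) reports the body's motion directly. A sensor on
loose fabric attached to that body reports a transformed version of the
same motion: the fabric's flexible dynamics amplify and reshape it. The
question this package operationalises is whether the fabric channel lets
us *recognise which of two movements is underway* from a shorter history
of observations than the rigid channel does — and, once the movement class
is recognised, *predict the future rigid-body trajectory*.

`fabmotion` implements the full analysis pipeline: synthetic generators
that emulate the three study scenarios, the preprocessing steps used for
wearable motion capture, a left-to-right hidden Markov model (LR-HMM)
fitted by Baum-Welch, likelihood-based prefix classification, a
Viterbi-ordered probabilistic trajectory model for prediction, and the
cross-fitness distance that quantifies how much class-discriminating
information a channel carries.

## The model

Each recorded movement is a trial $Y = [y_1, \dots, y_V]$ of $V$ time
steps with $M$ channels. The LR-HMM ties one hidden state to each time
step ($N = V$): state $i$ emits a diagonal-Gaussian observation
$b_i(y) = \prod_m \mathcal{N}(y_m;\, \mu_{im}, \sigma^2_{im})$, the
initial distribution $\pi$ concentrates on state 1, and transitions are
restricted to a left-to-right band in which advancing dominates remaining
($a_{i,i+1} \gg a_{ii}$), the last state being absorbing.

`lrhmm()` estimates $\{\pi, \mu, \sigma^2\}$ by expectation-maximisation:
the E-step computes state posteriors $\gamma_v(i)$ and pair posteriors
$\xi_v(i,j)$ with the scaled forward-backward recursions; the M-step
re-estimates $\pi_i$ as the mean first-step posterior, and $\mu_i,
\sigma^2_i$ as $\gamma$-weighted moments. The transition band is *not*
re-estimated by default — the M-step we mirror updates only $\pi$, $\mu$
and $\sigma^2$, and the band encodes the time-indexed topology rather
than a free parameter — but `update_trans = TRUE` re-estimates it within
the band from the $\xi$ statistics for users who want that behaviour.

Three numerical points matter at $N = V = 200$:

* All scoring runs in log-space (`forward_loglik()` uses log-sum-exp;
  `viterbi()` adds log-probabilities), so a grossly mismatched model
  returns its genuinely huge negative log-likelihood instead of
  underflowing. Training uses the classical per-step rescaling, batched
  across trials as states-by-trials matrix operations.
* Column maxima for rescaling are computed exactly. (Shortcuts such as
  `max.col()` apply a *relative* tie tolerance, which silently
  mis-selects maxima once log-densities span many orders of magnitude.)
* Variances are floored (default `1e-6` in squared channel units) and all
  argmax ties break toward the smaller state index, so decoded paths are
  deterministic.

Classification of a length-$v$ prefix compares
$\log P(y_{1:v} \mid \lambda_c)$ under the two fitted class models; the
forward sum is simply terminated at step $v$ — the model is never
truncated. Exact ties go to class 1.

## Prediction and the cross-fitness distance

Because states are time-indexed only implicitly, the state that describes
step $v$ must be read off the most likely state sequence: `viterbi()`
decodes each training trial and `build_trajectory_model()` takes the
per-step modal state (ties to the smaller index; a single-reference mode
is available via `method = "single"`). The resulting trajectory model is
the time-ordered sequence of emission Gaussians; `predict_future()`
recognises the class from a fabric prefix and returns the recognised
class's remaining steps as mean $\pm k \cdot$ sd envelopes. We provide
$k = 5$ (the physical-rig convention) and $k = 3$ (the human-reaching
convention) as presets; the envelope is read literally as per-dimension
Gaussian bands.

The cross-fitness distance between the two fitted models,
$$D = \log P(Y_1\mid\lambda_1) + \log P(Y_2\mid\lambda_2)
    - \log P(Y_1\mid\lambda_2) - \log P(Y_2\mid\lambda_1),$$
is computed with each term the *mean* forward log-likelihood over the
held-out prefixes of a split (the printed form is for single sequences;
averaging within splits and then across splits matches the mean ± sd
presentation of the accuracy curves). $D$ is exactly zero when the models
coincide, invariant to common translations, and unnormalised — an
optional per-step normalisation was considered and rejected because the
quantity we track is the *accumulated* discrimination information in a
prefix.

## What the synthetic generators emulate

**Crank rig (`gen_harmonic`)**: the yoke position is exact simple
harmonic motion `radius * cos(omega t + phi0)` with the crank radius 10 cm
and sampling at 40 Hz; the yaw channel is the crank angle (`atan2` of the
crank position, in degrees). The rig's "randomly assigned starting
position" is $\phi_0 \sim U[0, 2\pi)$. Recognition experiments
time-align trials at the first position crest after a full period
(`detect_crest()`), emulating the study's alignment that leaves initial
positions nearly identical; the residual crest-detection jitter under
sensor noise is precisely the within-class phase variability that makes
the task non-trivial.

**Fabric proxy (`gen_fabric_chain`)**: real cloth is replaced by a linear
chain of lumped unit masses joined by springs and dampers, driven at its
root by `gain` times the *physical* (pre-noise) rigid signal — sensor
noise is added at each sensor, not inside the mechanics. The chain is
integrated with `deSolve::lsoda` and is analytically checkable: its
steady-state response is the closed-form transfer function
`chain_frequency_response()`, and the test suite holds the simulation to
within 1% of it. The defaults (3 links, stiffness 12, damping 4,
gain 3) were chosen from that transfer function so that the chain
resonates between the two smallest crank frequencies: at
$\omega = 0.63\pi$ and $0.75\pi$ rad/s the tap amplitudes differ by a
factor ≈ 1.5, i.e. the chain converts a small *frequency* difference into
an *amplitude* difference that is visible in a short prefix, while the
slowest mode settles within a few seconds. That is the mechanism — not a
claim about cloth physics — by which the fabric channel carries earlier
discriminative information; nonlinear cloth dynamics, aerodynamics and
the cloth-to-Euler-angle map are out of scope.

**Patterns and reaching**: `gen_pattern()` traces linear, curved
(quadratic Bézier) or circular paths with a minimum-jerk arclength
profile at a configurable peak speed; class 2 is class 1's path rotated
by $\Delta\theta$ about the shared start. `gen_reaching()` places targets
on a 45 cm arc at 5° spacing and reaches along straight minimum-jerk
profiles (the standard smooth-reach model — the study records but does
not model hand kinematics), with per-trial start jitter, a rest lead-in
so the 10 mm onset threshold has something to detect, and sleeve channels
produced by the fabric chain. `inject_gaps()` emulates tracker dropouts
as i.i.d. per-sample missingness with runs truncated at `max_gap`,
endpoints always retained.

What passing tests on these generators do *not* show: performance on real
garment recordings. The generators have Gaussian sensor noise, linear
fabric dynamics and stationary trial-to-trial variability; real data add
attachment slip, aerodynamic forcing and participant variability, so the
package's acceptance checks are qualitative (directions, orderings and
calibration), not reproductions of figure-level accuracy values.

## Preprocessing rules and their order

The pipeline is `fill_gaps` → `align_trials` → `standardize/baseline` →
`resample`, each a pure function:

* gaps: piecewise cubic splines (`stats::spline`, FMM end conditions,
  which reproduce cubic polynomials exactly); missing endpoints are an
  error rather than an extrapolation;
* alignment: the onset is the first inter-sample displacement of the
  rigid position channel exceeding the threshold — 1 mm and 0.5 mm for
  the two rig scenarios, 10 mm for reaching — inside a configurable
  search window (default: the whole trial, since only thresholds are
  prescribed); fabric channels always inherit the rigid channel's start
  indices; periodic trials use crest alignment instead, since a
  continuously oscillating rig has no displacement onset;
* `standardize_initial()` subtracts one shared constant per channel (the
  mean initial value over class-1 trials — a single reference trial would
  inject that trial's noise into every other trial) from *both* classes;
  `baseline_correct()` zeroes each trial's own first sample, which
  removes slow drift of hand-made mechanics; angles are unwrapped first,
  because subtraction across a ±180° wrap corrupts differences;
* resampling is linear interpolation onto a uniform grid (reaching trials
  are carried to 40 × 1.25 = 50 samples).

Storage is 0-based-free R convention: the mathematical step $v = 1$ is
row 1 everywhere.

## Experiment protocol and problem sizes

`split_protocol()` encodes the study protocol: 49 training trials per
class, the rest held out, repeated 100 times — with 50 trials per class
that is one held-out trial per class per repetition and 200 recognitions
in the accuracy denominator. Splits, model initialisations and generator
noise all draw from child seeds derived deterministically from one master
seed (`derive_seed()`), so rigid-vs-fabric comparisons are *paired*: both
channels see identical splits, and whole experiments replay
byte-identically. Dispersion is reported as the sd over repetitions,
matching the shaded-band convention of the accuracy figures.

Within one repetition the class models are fitted once on full-length
trials and every prefix length is scored in a single forward sweep
(`forward_cumloglik()`), so accuracy- and distance-versus-history curves
are paired across history lengths too.

The packaged experiments run at deliberately modest sizes chosen to keep
a laptop run comfortable while leaving the protocol intact: the
calibration checks use $V = 50$, $K = 50$ per class with the full
49/100 protocol; the parameter-recovery study uses a 20-state, 2-channel
model with 40 simulated trials; the headline rigid-vs-fabric comparison
uses $K = 50$ trials, a 2.5 s analysis window ($V = 100$) and 8
repetitions; EM runs with `max_iter = 12`, `rel_tol = 1e-5` in the
protocol loops (convergence is within ~1e-5 relative log-likelihood by
then; the fitting default is stricter).

```{r headline, eval = FALSE}
cfg <- experiment_config(
  scenario = "harmonic", omega1 = 0.63 * pi, omega2 = 0.75 * pi,
  n_trials = 50, duration = 2.5, noise_sd = 2,
  protocol = split_protocol(n_train = 49, n_repeats = 8, seed = 5),
  hmm = hmm_options(max_iter = 12, rel_tol = 1e-5), master_seed = 9)
result <- run_experiment(cfg)
plot(result$curves$rigid$accuracy, col = "grey40")
plot(result$curves$fabric$accuracy, add = TRUE, col = "firebrick")
```

## Design choices made where the design was open

* **Transition band**: states are time steps, so one-step progression
  dominates; the band is {self, successor} with initial self-probability
  0.1 and an absorbing final state. Wider bands (skips) are available via
  `band_width`.
* **Covariance**: diagonal. The emission density is written generally,
  but the variance update is per-dimension; full covariance is a
  non-goal.
* **Initialisation**: "chosen randomly from the sensor reading" is read
  literally — state means are copied from one seeded-randomly-chosen
  training trial, variances from per-step across-trial spread.
* **Reference sequence for the trajectory model**: the modal Viterbi
  state per step across training trials (robust to a single odd trial),
  with a single-reference option.
* **Repetitions refit**: each of the 100 repetitions refits both class
  models on its own training split; the split is the unit of replication.
* **Zero-occupancy states** keep their previous emission parameters and
  are recorded in the fit report rather than being deleted or
  re-seeded.

## Known limitations

* The fabric proxy is linear; it reproduces the amplification mechanism,
  not cloth.
* Gaussian emissions make the wrapped-angle representation hostile;
  `unwrap_angles()` must be applied before modelling orientation
  channels, as the harmonic pipeline does.
* Only binary recognition is implemented; multi-class and significance
  testing beyond descriptive dispersion are out of scope.
* `evaluate_accuracy()` refits 2 × `n_repeats` models; at the full
  protocol this is the dominant cost (seconds per fit at $V = 100$).
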