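# fabmotion

Motion recognition and prediction from rigid- and fabric-attached sensors
with left-to-right hidden Markov models.

## What problem this solves

Loose clothing moves when the body moves, and its flexible dynamics
amplify differences between movements. `fabmotion` is for researchers in
wearable sensing and human movement analysis who want to test — on
controlled synthetic data — whether a sensor on fabric lets a classifier
recognise *which* movement is underway from a shorter observation history
than a sensor on the rigid body, and to predict the future rigid-body
trajectory once the class is recognised.

The statistical core is a left-to-right hidden Markov model with one
state per time step (N = V). A trial `Y = [y_1 … y_V]` with M channels
has per-state diagonal-Gaussian emissions
`b_i(y) = ∏_m N(y_m; μ_im, σ²_im)`, an initial distribution concentrated
on state 1, and a banded transition matrix in which advancing dominates
remaining (`a_{i,i+1} ≫ a_ii`). The package provides:

* `lrhmm()` — Baum-Welch estimation in scaled/log arithmetic, with the
  usual methods (`print`, `summary`, `coef`, `logLik`, `predict`,
  `simulate`, `residuals`, `plot`);
* `forward_loglik()` / `classify_motion()` — prefix likelihoods
  `log P(y_{1:v} | λ_c)` by the forward algorithm, and the
  argmax-likelihood recognition rule;
* `viterbi()` / `build_trajectory_model()` / `predict_future()` — the
  most likely state sequence, the time-ordered emission Gaussians it
  induces, and future-motion envelopes `mean ± k·sd`;
* `cross_fitness()` — the four-term distance
  `D = logP(Y₁|λ₁) + logP(Y₂|λ₂) − logP(Y₁|λ₂) − logP(Y₂|λ₁)`
  measuring the class-discriminating information in a channel;
* `evaluate_accuracy()` / `accuracy_vs_history()` /
  `distance_vs_history()` — the 49-train/100-repeat split protocol and
  history-length curves with paired splits;
* synthetic generators (`gen_harmonic`, `gen_fabric_chain`,
  `gen_pattern`, `gen_reaching`, `inject_gaps`) and the preprocessing
  steps (`fill_gaps`, `detect_start`, `align_trials`,
  `standardize_initial`, `baseline_correct`, `resample_trajectory`,
  `unwrap_angles`) used for wearable motion capture;
* `run_experiment()` — the end-to-end simulate → preprocess → fit →
  evaluate pipeline with fully derived seeds.

See the vignette (`vignettes/motion-recognition.Rmd`) for the model,
the fabric-chain proxy, and every design decision.

## Worked example

Two crank-rig movement classes differing in angular frequency
(0.63π vs 0.92π rad/s, 40 Hz, 1.25 s trials, sensor noise sd 2):

```r
library(fabmotion)

c1 <- gen_harmonic(harmonic_config(omega = 0.63 * pi, duration = 1.25,
                                   phase_mode = "fixed", noise_sd = 2,
                                   n_trials = 50, seed = 101))
c2 <- gen_harmonic(harmonic_config(omega = 0.92 * pi, duration = 1.25,
                                   phase_mode = "fixed", noise_sd = 2,
                                   n_trials = 50, seed = 202))

m1 <- lrhmm(c1[1:49], seed = 1)
m2 <- lrhmm(c2[1:49], seed = 1)
m1
#> <lrhmm> left-to-right HMM: 50 states, 2 channels (pos_x, yaw)
#>   Baum-Welch: 8 iterations (converged), log-likelihood -10453.9673

# recognise a held-out class-2 trial from its first 20 samples (0.5 s)
classify_motion(trial_prefix(c2$trials[[50]], 20), m1, m2)$label
#> [1] 2

# how much discriminating information does the channel carry?
cross_fitness(m1, m2, c1[50], c2[50], prefix_len = 20)
#> [1] 278.441

curve <- accuracy_vs_history(c1, c2,
                             split_protocol(n_train = 49, n_repeats = 10,
                                            seed = 7),
                             c(10L, 25L, 50L),
                             hmm_options(max_iter = 12, rel_tol = 1e-5))
curve
#> <accuracy_curve> recognition accuracy vs history length
#>  prefix_len mean_accuracy sd_accuracy
#>          10             1           0
#>          25             1           0
#>          50             1           0
```

The fitted model's log-likelihood margin (277 nats at 0.5 s) and the
cross-fitness distance say the same thing: at this frequency gap the
classes separate almost immediately. The interesting regime — the
smallest frequency gap, where the fabric channel reaches 95% accuracy at
a strictly shorter history than the rigid channel — is run end-to-end by
`run_experiment(experiment_config(scenario = "harmonic", ...))`; see the
vignette.

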