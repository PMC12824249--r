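# Independent oracles and small fixtures, built in code.

# Brute-force path enumeration: total likelihood, best path and its score,
# by explicit summation over all N^V state sequences (dense transition
# matrix, per-path products in log space).
enumerate_paths <- function(model, y) {
  a_dense <- coef(model)$trans
  n <- model$n_states
  vlen <- nrow(y)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), vlen)))
  total <- -Inf
  best <- -Inf
  best_path <- NULL
  for (p in seq_len(nrow(paths))) {
    q <- paths[p, ]
    lp <- log(model$pi[q[1L]]) + emission_logdensity(model, q[1L], y[1L, ])
    if (vlen >= 2L) for (v in 2:vlen) {
      lp <- lp + log(a_dense[q[v - 1L], q[v]]) +
        emission_logdensity(model, q[v], y[v, ])
      if (lp == -Inf) break
    }
    hi <- max(total, lp)
    total <- if (hi == -Inf) -Inf else hi + log1p(exp(min(total, lp) - hi))
    if (lp > best) { best <- lp; best_path <- as.integer(unname(q)) }
  }
  list(loglik = total, best_logprob = best, best_path = best_path)
}

# A random small banded LR-HMM (for oracle-equivalence property tests).
random_small_model <- function(n, m, band_width, seed) {
  tr <- lapply(1:3, function(k) matrix(stats::rnorm(n * m), n, m))
  model <- lrhmm_init(tr, seed = seed, band_width = band_width,
                      self_prob = stats::runif(1, 0.05, 0.45))
  model$means <- matrix(stats::rnorm(n * m), n, m)
  model$variances <- matrix(stats::runif(n * m, 0.2, 2), n, m)
  model
}

# K noisy trials around a smooth mean curve (V x M), equal lengths.
noisy_curve_trials <- function(kk, vlen, m = 2, sd = 0.3, shift = 0,
                               seed = 1) {
  base <- cbind(3 * sin(seq(0, 2 * pi, length.out = vlen)),
                seq(-1, 1, length.out = vlen))[, seq_len(m), drop = FALSE]
  fabmotion:::with_seed(seed, lapply(seq_len(kk), function(k)
    base + shift + matrix(stats::rnorm(vlen * m, 0, sd), vlen, m)))
}

# Trajectory-set wrapper around noisy_curve_trials.
noisy_curve_set <- function(kk, vlen, m = 2, sd = 0.3, shift = 0, seed = 1,
                            label = NA_integer_) {
  trajectory_set(noisy_curve_trials(kk, vlen, m, sd, shift, seed),
                 sample_rate = 40, label = label)
}
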