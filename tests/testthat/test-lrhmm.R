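test_that("initialisation copies a training trial and floors variances", {
  one <- noisy_curve_trials(1, 15, seed = 1)
  m1 <- lrhmm_init(one, seed = 3)
  expect_equal(m1$means, unname(one[[1L]]))       # only candidate trial
  expect_true(all(m1$variances == m1$variance_floor))
  # constant-valued data: zero empirical variance -> all at the floor
  const <- lapply(1:4, function(k) matrix(2, 10, 2))
  mc <- lrhmm_init(const, seed = 1)
  expect_true(all(mc$variances == mc$variance_floor))
  # same seed, same initial parameters
  tr <- noisy_curve_trials(6, 15, seed = 2)
  expect_identical(lrhmm_init(tr, seed = 9), lrhmm_init(tr, seed = 9))
  # structure: pi concentrated on state 1, rows of the band sum to 1
  m <- lrhmm_init(tr, seed = 9, self_prob = 0.1)
  expect_equal(m$pi[1L], 0.9)
  expect_equal(sum(m$pi), 1)
  expect_equal(rowSums(m$trans_band), rep(1, 15))
  expect_error(lrhmm_init(list(matrix(0, 3, 1), matrix(0, 4, 1))),
               "same length")
})

test_that("emission log-density is the diagonal-Gaussian sum", {
  m <- lrhmm_init(noisy_curve_trials(3, 5, m = 1, seed = 1), seed = 1)
  m$means[2L, ] <- 0.7
  m$variances[2L, ] <- 1
  expect_equal(emission_logdensity(m, 2L, 0.7), log(1 / sqrt(2 * pi)))
  m3 <- lrhmm_init(noisy_curve_trials(3, 5, m = 2, seed = 1), seed = 1)
  y <- c(0.1, -0.4)
  expect_equal(emission_logdensity(m3, 3L, y),
               sum(stats::dnorm(y, m3$means[3L, ],
                                sqrt(m3$variances[3L, ]), log = TRUE)))
  # variances below the floor are clamped before evaluation
  m$variances[2L, ] <- 1e-12
  expect_equal(emission_logdensity(m, 2L, 0.7),
               stats::dnorm(0.7, 0.7, sqrt(m$variance_floor), log = TRUE))
  expect_error(emission_logdensity(m, 2L, NaN), "finite")
})

test_that("forward likelihood reduces correctly in closed-form cases", {
  # N = 1: the log-likelihood is the plain sum of emission log-densities
  m1 <- lrhmm_init(list(matrix(0.5, 1, 2)), seed = 1)
  m1$variances[] <- 0.8
  y <- matrix(c(0.2, 0.9), 1, 2)
  expect_equal(forward_loglik(m1, y), emission_logdensity(m1, 1L, y[1L, ]))
  # v = 1 on a larger model: log sum_i pi_i b_i(y1)
  m <- random_small_model(4, 2, band_width = 2, seed = 5)
  y1 <- matrix(stats::rnorm(2), 1, 2)
  direct <- log(sum(m$pi * exp(vapply(1:4, function(i)
    emission_logdensity(m, i, y1[1L, ]), numeric(1)))))
  expect_equal(forward_loglik(m, y1), direct, tolerance = 1e-12)
  expect_error(forward_loglik(m, y1, v = 0), "out of range")
})

test_that("forward, backward and Viterbi agree with path enumeration", {
  set.seed(100)
  for (case in 1:30) {
    n <- sample(2:4, 1)
    v <- sample(2:5, 1)
    m <- sample(1:2, 1)
    model <- random_small_model(n, m, band_width = sample(1:(n - 1), 1),
                                seed = case)
    y <- matrix(stats::rnorm(v * m), v, m)
    oracle <- enumerate_paths(model, y)
    expect_equal(forward_loglik(model, y), oracle$loglik,
                 tolerance = 1e-9)
    vit <- viterbi(model, y)
    expect_equal(vit$log_prob, oracle$best_logprob, tolerance = 1e-9)
    expect_equal(vit$path, oracle$best_path)
    # forward-backward consistency: sum_i pi_i b_i(y1) beta_1(i) = P(Y)
    po <- hmm_posteriors(model, y)
    expect_equal(po$loglik, oracle$loglik, tolerance = 1e-9)
  }
})

test_that("posterior tables satisfy their normalisation identities", {
  model <- random_small_model(4, 2, band_width = 2, seed = 8)
  y <- matrix(stats::rnorm(12), 6, 2)
  po <- hmm_posteriors(model, y)
  expect_equal(colSums(po$gamma), rep(1, 6), tolerance = 1e-12)
  # sum_j xi_v(i, j) = gamma_v(i)
  xs <- apply(po$xi, c(1, 3), sum)
  expect_equal(xs, po$gamma[, 1:5], tolerance = 1e-9)
  # N = 1: gamma is identically 1
  m1 <- lrhmm_init(list(matrix(0, 1, 1)), seed = 1)
  expect_equal(hmm_posteriors(m1, matrix(0.3, 1, 1))$gamma,
               matrix(1, 1, 1))
})

test_that("Baum-Welch log-likelihood is non-decreasing and honours max_iter", {
  tr <- noisy_curve_trials(10, 20, seed = 3)
  fit <- lrhmm(tr, max_iter = 40, seed = 2)
  expect_true(all(diff(fit$fit$trace) >= -1e-8 * abs(fit$fit$trace[-1])))
  init <- lrhmm_init(tr, seed = 2)
  fit0 <- lrhmm(tr, max_iter = 0, seed = 2)
  expect_equal(fit0$fit$stop_reason, "max_iter")
  expect_equal(fit0$means, init$means)
  expect_equal(fit0$pi, init$pi)
  # transition-band re-estimation keeps rows stochastic and the band shape
  fit_t <- lrhmm(tr, max_iter = 10, seed = 2, update_trans = TRUE)
  expect_equal(rowSums(fit_t$trans_band), rep(1, 20), tolerance = 1e-12)
  expect_equal(sum(fit_t$pi), 1, tolerance = 1e-12)
  expect_true(all(diff(fit_t$fit$trace) >= -1e-8 * abs(fit_t$fit$trace[-1])))
  # structural zeros beyond the last state stay zero
  expect_equal(fit_t$trans_band[20, 2], 0)
})

test_that("fitted parameters do not depend on trial order (shared init)", {
  tr <- noisy_curve_trials(8, 12, seed = 4)
  init <- lrhmm_init(tr, seed = 1)
  f1 <- lrhmm(tr, max_iter = 15, init = init)
  f2 <- lrhmm(tr[c(5, 2, 8, 1, 7, 3, 6, 4)], max_iter = 15, init = init)
  expect_equal(f1$means, f2$means, tolerance = 1e-10)
  expect_equal(f1$fit$loglik, f2$fit$loglik, tolerance = 1e-8)
})

test_that("constant training data drives all variances to the floor", {
  const <- lapply(1:5, function(k) matrix(1.5, 8, 2))
  fit <- lrhmm(const, max_iter = 3, seed = 1)
  expect_true(all(fit$variances == fit$variance_floor))
  expect_equal(unname(fit$means[, 1]), rep(1.5, 8), tolerance = 1e-9)
})

test_that("Viterbi recovers the designed path on near-deterministic chains", {
  vlen <- 12
  base <- noisy_curve_trials(1, vlen, sd = 0, seed = 1)[[1L]]
  model <- lrhmm_init(list(base), seed = 1, self_prob = 0.05)
  model$variances[] <- 0.01
  vit <- viterbi(model, base)
  expect_equal(vit$path, 1:vlen)           # the designed optimum
  expect_true(all(diff(vit$path) >= 0))    # non-decreasing under LR topology
  expect_lte(vit$log_prob, forward_loglik(model, base) + 1e-9)
})

test_that("model files round-trip bit-exactly", {
  tr <- noisy_curve_trials(6, 10, seed = 5)
  fit <- lrhmm(tr, max_iter = 8, seed = 3)
  path <- tempfile(fileext = ".txt")
  write_lrhmm(fit, path)
  back <- read_lrhmm(path)
  expect_identical(back$pi, fit$pi)
  expect_identical(back$trans_band, unname(fit$trans_band))
  expect_identical(back$means, unname(fit$means))
  expect_identical(back$variances, unname(fit$variances))
  expect_identical(back$fit$loglik, fit$fit$loglik)
  expect_identical(back$fit$trace, fit$fit$trace)
  unlink(path)
})

test_that("simulation respects the left-to-right topology", {
  tr <- noisy_curve_trials(6, 15, seed = 6)
  fit <- lrhmm(tr, max_iter = 10, seed = 1)
  sim <- simulate(fit, nsim = 5, seed = 4)
  expect_equal(n_trials(sim), 5)
  expect_equal(n_steps(sim), 15)
  for (q in attr(sim, "paths")) expect_true(all(diff(q) >= 0))
  expect_identical(simulate(fit, nsim = 5, seed = 4)$trials, sim$trials)
})

test_that("model methods expose the fit coherently", {
  tr <- noisy_curve_trials(6, 10, seed = 7)
  fit <- lrhmm(tr, max_iter = 10, seed = 1)
  cf <- coef(fit)
  expect_equal(rowSums(cf$trans), rep(1, 10), tolerance = 1e-12)
  expect_equal(sum(cf$pi), 1, tolerance = 1e-12)
  expect_s3_class(logLik(fit), "logLik")
  expect_equal(as.numeric(logLik(fit)), fit$fit$loglik)
  lls <- predict(fit, tr)
  expect_length(lls, 6)
  expect_equal(lls[1L], forward_loglik(fit, tr[[1L]]))
  paths <- predict(fit, tr[1:2], type = "states")
  expect_true(all(vapply(paths, function(q) all(diff(q) >= 0), logical(1))))
  res <- residuals(fit, tr[1:2])
  expect_equal(dim(res[[1L]]), c(10L, 2L))
  expect_output(print(fit), "left-to-right")
  expect_output(print(summary(fit)), "state means")
})
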