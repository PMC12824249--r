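test_that("harmonic generator reproduces the crank kinematics", {
  cfg <- harmonic_config(omega = pi, radius = 10, sample_rate = 40,
                         duration = 5, phase_mode = "fixed", phase = 0,
                         n_trials = 2, seed = 1)
  s <- gen_harmonic(cfg)
  y <- s$trials[[1L]]
  expect_equal(nrow(y), 200)              # 40 Hz x 5 s
  expect_equal(unname(y[1L, "pos_x"]), 10)        # cos(0) = 1
  expect_equal(unname(y[41L, "pos_x"]), -10)      # t = 1 s, cos(pi) = -1
  # circle invariant: x^2/r^2 + (xdot/(w r))^2 = 1 before noise
  tt <- (0:199) / 40
  xdot <- -10 * pi * sin(pi * tt)
  expect_equal(y[, "pos_x"]^2 / 100 + xdot^2 / (pi * 10)^2,
               rep(1, 200), tolerance = 1e-12)
})

test_that("harmonic generator is reproducible and respects phase mode", {
  cfg <- harmonic_config(omega = 0.8 * pi, duration = 1, n_trials = 5,
                         noise_sd = 0.5, seed = 42)
  a <- gen_harmonic(cfg)
  b <- gen_harmonic(cfg)
  expect_identical(a$trials, b$trials)
  expect_true(all(attr(a, "phases") >= 0 & attr(a, "phases") < 2 * pi))
  expect_gt(stats::sd(attr(a, "phases")), 0)
  fx <- gen_harmonic(harmonic_config(duration = 1, phase_mode = "fixed",
                                     phase = 0.3, n_trials = 3, seed = 1))
  expect_equal(attr(fx, "phases"), rep(0.3, 3))
})

test_that("invalid generator configs name the offending field", {
  expect_error(harmonic_config(omega = -1), "omega")
  expect_error(harmonic_config(n_trials = 0), "n_trials")
  expect_error(pattern_config(delta_theta = 120), "delta_theta")
  expect_error(pattern_config(shape = "zigzag"), "shape")
  expect_error(fabric_chain_config(tap_positions = 9, n_links = 3),
               "tap_positions")
  expect_error(reach_config(delta_theta = 7), "delta_theta")
  expect_error(inject_gaps(noisy_curve_set(2, 10), gap_rate = 0.7),
               "gap_rate")
})

test_that("fabric chain is quiescent for a motionless driver", {
  drv <- trajectory_set(list(cbind(x = rep(0, 80))), sample_rate = 40)
  f <- gen_fabric_chain(drv, fabric_chain_config(n_links = 2,
                                                 tap_positions = 1:2))
  expect_lt(max(abs(f$trials[[1L]])), 1e-9)
})

test_that("a very stiff, damped chain follows the driver (rigid limit)", {
  tt <- (0:159) / 40
  drv <- trajectory_set(list(cbind(x = 3 * sin(1.5 * tt))), sample_rate = 40)
  ch <- fabric_chain_config(n_links = 2, stiffness = 4e4, damping = 400,
                            tap_positions = 2, gain = 1)
  f <- gen_fabric_chain(drv, ch)
  expect_lt(max(abs(f$trials[[1L]][, 1L] - drv$trials[[1L]][, 1L])), 0.01)
})

test_that("steady-state tap amplitudes match the analytic frequency response", {
  # independent oracle: the complex transfer function of the linear chain
  ch <- fabric_chain_config(n_links = 2, stiffness = 40, damping = 4,
                            tap_positions = 1:2, gain = 1.7)
  fs <- 50
  tt <- (0:(fs * 40 - 1)) / fs
  for (om in c(2, 3.5)) {
    drv <- trajectory_set(list(cbind(x = 3 * cos(om * tt))), sample_rate = fs)
    f <- gen_fabric_chain(drv, ch)
    h <- chain_frequency_response(ch, om)
    sel <- tt > 30                        # past the damped transient
    for (j in 1:2) {
      fit <- stats::lm(f$trials[[1L]][sel, j] ~ cos(om * tt[sel]) +
                         sin(om * tt[sel]))
      amp <- sqrt(sum(stats::coef(fit)[2:3]^2))
      expect_equal(amp, 3 * Mod(h[1, j]), tolerance = 0.01)
    }
  }
})

test_that("amplifying chain widens the class-mean separation at small delta-omega", {
  om1 <- 0.63 * pi
  om2 <- 0.75 * pi
  mk <- function(om) gen_harmonic(harmonic_config(
    omega = om, duration = 2.5, phase_mode = "fixed", n_trials = 1, seed = 1))
  r1 <- mk(om1); r2 <- mk(om2)
  ch <- fabric_chain_config()             # gain 3 > 1
  f1 <- gen_fabric_chain(r1, ch); f2 <- gen_fabric_chain(r2, ch)
  isd <- function(a, b) mean((a$trials[[1L]][, 1L] - b$trials[[1L]][, 1L])^2)
  expect_gt(isd(f1, f2), isd(r1, r2))
})

test_that("pattern classes are exact rotations about the shared start", {
  cfg <- pattern_config(shape = "curved_ptp", delta_theta = 25, speed = 25,
                        duration = 4, noise_sd = 0, n_trials = 2, seed = 1)
  p <- gen_pattern(cfg)
  m1 <- attr(p$class1, "mean_path")
  m2 <- attr(p$class2, "mean_path")
  # shared start point
  expect_equal(m2[1L, 1:2], m1[1L, 1:2], tolerance = 1e-12)
  # rotating class 2 back recovers class 1 exactly (noise off)
  back <- fabmotion:::rotate_about_start(m2, -25, origin = m1[1L, 1:2])
  expect_equal(back, m1, tolerance = 1e-9)
  # zero rotation: identical mean paths
  p0 <- gen_pattern(pattern_config(delta_theta = 0, duration = 4,
                                   noise_sd = 0, n_trials = 1, seed = 1))
  expect_equal(attr(p0$class2, "mean_path"), attr(p0$class1, "mean_path"),
               tolerance = 1e-12)
})

test_that("pattern traversal time scales inversely with peak speed", {
  t25 <- attr(gen_pattern(pattern_config(speed = 25, duration = 5,
                                         n_trials = 1))$class1,
              "move_duration")
  t15 <- attr(gen_pattern(pattern_config(speed = 15, duration = 5,
                                         n_trials = 1))$class1,
              "move_duration")
  expect_equal(t25 / t15, 15 / 25, tolerance = 1e-9)
})

test_that("reaching targets sit on the 45 cm arc, 5 degrees apart", {
  cfg <- reach_config(noise_sd = 0, start_jitter_sd = 0, n_trials = 1,
                      seed = 1)
  r <- gen_reaching(cfg, chain = fabric_chain_config(n_links = 1))
  tg <- attr(r, "targets")
  expect_equal(sqrt(colSums(tg^2)), c(a = 45, b = 45))
  # adjacent configured targets subtend 5 degrees at the start
  ang <- acos(sum(tg[, 1] * tg[, 2]) / (45 * 45)) * 180 / pi
  expect_equal(ang, 5, tolerance = 1e-9)
  # minimum-jerk: speed ~ 0 at both ends of the mean wrist path
  y <- r$target_a$trials[[1L]][, 1:2]
  speed <- sqrt(rowSums(diff(y)^2)) * cfg$sample_rate
  expect_lt(speed[1L], 1e-6)
  expect_lt(speed[length(speed)], 1e-6)
  expect_gt(max(speed), 40)   # but the reach itself is fast
})

test_that("gap injection marks interior samples only, within the gap cap", {
  s <- noisy_curve_set(6, 60, seed = 2)
  expect_identical(inject_gaps(s, 0), s)
  g <- inject_gaps(s, gap_rate = 0.1, max_gap = 3, seed = 7)
  for (y in g$trials) {
    miss <- is.na(y[, 1L])
    expect_identical(is.na(y[, 2L]), miss)   # whole rows drop out
    expect_false(miss[1L] || miss[length(miss)])
    runs <- rle(miss)
    expect_lte(max(runs$lengths[runs$values]), 3)
  }
  expect_identical(inject_gaps(s, 0.1, 3, seed = 7), g)
})

test_that("expected missing count follows the sampling rate", {
  kk <- 30; vlen <- 100; rate <- 0.05
  s <- noisy_curve_set(kk, vlen, seed = 3)
  n_miss <- sum(vapply(inject_gaps(s, rate, max_gap = 6, seed = 11)$trials,
                       function(y) sum(is.na(y[, 1L])), numeric(1)))
  n_int <- kk * (vlen - 2)
  expect_lt(abs(n_miss - rate * n_int), 3 * sqrt(n_int * rate * (1 - rate)))
})
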