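test_that("spline gap filling restores polynomial signals exactly", {
  tt <- 1:50
  cubic <- cbind(a = 0.02 * tt^3 - tt^2 + 3 * tt - 5, b = 2 * tt + 1)
  s <- trajectory_set(list(cubic), 40)
  expect_identical(fill_gaps(s), s)        # no gaps: identity
  g <- inject_gaps(s, 0.25, max_gap = 4, seed = 5)
  expect_gt(sum(is.na(g$trials[[1L]])), 0)
  filled <- fill_gaps(g)
  # cubic splines reproduce cubics (and lines) exactly
  expect_equal(filled$trials[[1L]], cubic, tolerance = 1e-9)
  # present samples untouched
  keep <- !is.na(g$trials[[1L]][, 1L])
  expect_identical(filled$trials[[1L]][keep, ], cubic[keep, ])
})

test_that("gap filling refuses missing endpoints", {
  y <- cbind(a = as.numeric(1:10))
  y[1L, 1L] <- NA
  expect_error(fill_gaps(y), "unrecoverable gap")
})

test_that("onset detection finds the first suprathreshold step", {
  x <- c(rep(5, 10), 7, rep(7, 9))         # 2 mm step at sample 11
  expect_equal(detect_start(cbind(x), threshold = 1), 11)
  expect_error(detect_start(cbind(rep(5, 20)), threshold = 1), "no onset")
  expect_error(detect_start(cbind(x), threshold = -1), "threshold")
})

test_that("onset detection matches a brute-force scan on a planted reach", {
  # plant the first > 10 mm inter-sample displacement at sample 12
  x <- c(rep(0, 10), 2, 14, 30, 47, 58, rep(60, 10))
  onset <- detect_start(cbind(x), threshold = 10)
  brute <- min(which(abs(diff(x)) > 10)) + 1L
  expect_equal(onset, brute)
  expect_equal(onset, 12L)
})

test_that("alignment removes a pure time shift and crops", {
  base <- cbind(pos = c(rep(0, 15), cumsum(rep(2, 45))),
                yaw = sin(1:60))
  shifted <- rbind(matrix(0, 7, 2), base)[1:60, ]
  colnames(shifted) <- colnames(base)
  s <- trajectory_set(list(base, shifted), 40)
  al <- align_trials(s, channel = 1L, threshold = 1, length = 30)
  expect_equal(al$trials[[1L]], al$trials[[2L]])
  expect_equal(attr(al, "start_indices"), c(16L, 23L))
  expect_equal(nrow(al$trials[[1L]]), 30)
  # content is preserved: alignment is a pure crop
  expect_equal(al$trials[[1L]], base[16:45, ])
  expect_error(align_trials(s, channel = 1L, threshold = 1, length = 59),
               "trial 1")
})

test_that("alignment shrinks across-trial onset variance on offset trials", {
  mk <- function(off) {
    x <- c(rep(0, off), 10 * sin(0.3 * (1:80)))[1:80]
    cbind(pos = x)
  }
  s <- trajectory_set(lapply(c(3, 9, 15, 6, 12), mk), 40)
  al <- align_trials(s, channel = 1L, threshold = 1, length = 40)
  v_raw <- stats::var(vapply(s$trials, function(y) y[20L, 1L], numeric(1)))
  v_al <- stats::var(vapply(al$trials, function(y) y[20L, 1L], numeric(1)))
  expect_lt(v_al, v_raw)
})

test_that("fabric channels can inherit the rigid channel's start indices", {
  s <- noisy_curve_set(3, 40, seed = 4)
  starts <- c(2L, 5L, 3L)
  al <- align_trials(s, length = 30, starts = starts)
  expect_equal(al$trials[[2L]], s$trials[[2L]][5:34, ])
  expect_error(align_trials(s, length = 30, starts = c(1L, 2L)), "one index")
})

test_that("initial-orientation standardisation shares one constant", {
  c1 <- noisy_curve_set(8, 20, seed = 1)
  c2 <- noisy_curve_set(8, 20, shift = 2, seed = 2)
  out <- standardize_initial(c1, c2, channels = 1:2)
  first1 <- t(vapply(out$class1$trials, function(y) y[1L, ], numeric(2)))
  expect_equal(unname(colMeans(first1)), c(0, 0), tolerance = 1e-12)
  # within-series differences unchanged
  expect_equal(diff(out$class1$trials[[3L]]), diff(c1$trials[[3L]]))
  # class 2 shifted by class 1's offset
  expect_equal(out$class2$trials[[1L]][1L, ],
               c2$trials[[1L]][1L, ] - out$offsets)
})

test_that("baseline correction zeroes each trial's first sample, idempotently", {
  s <- noisy_curve_set(5, 15, seed = 6)
  b <- baseline_correct(s, channels = 2L)
  for (y in b$trials) expect_equal(unname(y[1L, 2L]), 0)
  expect_equal(baseline_correct(b, channels = 2L), b)
  # unselected (position) channels unchanged
  expect_identical(b$trials[[1L]][, 1L], s$trials[[1L]][, 1L])
})

test_that("angle unwrapping removes wrap discontinuities", {
  a <- fabmotion:::wrap_deg(seq(0, 720, by = 10))
  s <- trajectory_set(list(cbind(a = a)), 40)
  u <- unwrap_angles(s, 1L)$trials[[1L]][, 1L]
  expect_equal(u, seq(0, 720, by = 10))
})

test_that("linear resampling hits the printed reaching length", {
  tt <- 1:50
  y <- cbind(a = 2 * tt + 1, b = -tt)
  expect_equal(resample_trajectory(y, 50), y)              # identity grid
  r <- resample_trajectory(y, 23)
  grid <- seq(1, 50, length.out = 23)
  expect_equal(r[, "a"], 2 * grid + 1, tolerance = 1e-12)  # exact on a line
  # a 1.25 s reaching trial at 40 Hz resamples to 50 samples
  trial <- matrix(stats::rnorm(50), 50, 1)
  expect_equal(nrow(resample_trajectory(trial, round(40 * 1.25))), 50)
  expect_error(resample_trajectory(y, 1), "v_target")
})
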