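test_that("trajectory models order emissions by the Viterbi path", {
  vlen <- 12
  base <- noisy_curve_trials(1, vlen, sd = 0, seed = 1)[[1L]]
  model <- lrhmm_init(list(base), seed = 1, self_prob = 0.05)
  model$variances[] <- 0.01
  tm <- build_trajectory_model(model, base, label = 1L)
  expect_equal(tm$path, 1:vlen)                 # identity decode
  expect_equal(tm$means, unname(model$means))   # mean at step v is mu_{s_v}
  expect_equal(tm$n_steps, vlen)
  expect_true(all(diff(tm$path) >= 0))
  expect_true(all(tm$sds > 0))
  # modal decoding over several trials agrees on near-deterministic data
  tr <- noisy_curve_set(6, vlen, sd = 0.05, seed = 2)
  fit <- lrhmm(tr, max_iter = 10, seed = 1)
  tm2 <- build_trajectory_model(fit, tr)
  expect_true(all(diff(tm2$path) >= 0))
})

test_that("future prediction follows the recognised class and band width", {
  s1 <- noisy_curve_set(8, 15, sd = 0.3, seed = 3, label = 1L)
  s2 <- noisy_curve_set(8, 15, sd = 0.3, shift = 4, seed = 4, label = 2L)
  mr1 <- lrhmm(s1, max_iter = 8, seed = 1)
  mr2 <- lrhmm(s2, max_iter = 8, seed = 1)
  tm1 <- build_trajectory_model(mr1, s1, label = 1L)
  tm2 <- build_trajectory_model(mr2, s2, label = 2L)
  # a strongly class-1 prefix at v_now = 1 returns the full class-1 tail
  pred <- predict_future(tm1, tm2, s1$trials[[1L]], list(mr1, mr2),
                         v_now = 1L, band_k = 5)
  expect_equal(pred$label, 1L)
  expect_equal(nrow(pred$prediction), 14)
  expect_equal(pred$prediction$mean_ch1, tm1$means[2:15, 1L])
  # band_k = 0 collapses the envelope onto the mean
  p0 <- predict_future(tm1, tm2, s1$trials[[1L]], list(mr1, mr2),
                       v_now = 5L, band_k = 0)
  expect_equal(p0$prediction$lo_ch1, p0$prediction$mean_ch1)
  expect_equal(p0$prediction$hi_ch1, p0$prediction$mean_ch1)
  # deterministic in its inputs
  p1 <- predict_future(tm1, tm2, s1$trials[[1L]], list(mr1, mr2), 5L, 3)
  p2 <- predict_future(tm1, tm2, s1$trials[[1L]], list(mr1, mr2), 5L, 3)
  expect_identical(p1, p2)
  expect_error(predict_future(tm1, tm2, s1$trials[[1L]], list(mr1, mr2),
                              v_now = 15L), "v_now")
})

test_that("right-class predictions beat wrong-class predictions on held-out trials", {
  vlen <- 15
  tr1 <- noisy_curve_set(20, vlen, sd = 0.3, seed = 5, label = 1L)
  tr2 <- noisy_curve_set(20, vlen, sd = 0.3, shift = 3, seed = 6, label = 2L)
  m1 <- lrhmm(tr1[1:12], max_iter = 8, seed = 1)
  m2 <- lrhmm(tr2[1:12], max_iter = 8, seed = 1)
  tm1 <- build_trajectory_model(m1, tr1[1:12], label = 1L)
  tm2 <- build_trajectory_model(m2, tr2[1:12], label = 2L)
  held <- tr1[13:20]
  rmse <- function(y, tm) sqrt(mean((y[6:vlen, ] - tm$means[6:vlen, ])^2))
  wins <- vapply(held$trials, function(y)
    rmse(y, tm1) < rmse(y, tm2), logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("envelope coverage grows with the band multiplier", {
  vlen <- 15
  tr <- noisy_curve_set(20, vlen, sd = 0.4, seed = 7)
  m <- lrhmm(tr[1:15], max_iter = 8, seed = 1)
  tm <- build_trajectory_model(m, tr[1:15], label = 1L)
  cover <- function(k) {
    inside <- vapply(tr$trials[16:20], function(y)
      mean(abs(y - tm$means) <= k * tm$sds), numeric(1))
    mean(inside)
  }
  expect_gt(cover(3), cover(1))
})
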