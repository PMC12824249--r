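fit_quick <- function(set, seed = 1)
  lrhmm(set, max_iter = 10, rel_tol = 1e-5, seed = seed)

test_that("the likelihood rule classifies, ties to class 1, swaps symmetrically", {
  s1 <- noisy_curve_set(6, 12, seed = 1)
  s2 <- noisy_curve_set(6, 12, shift = 5, seed = 2)
  m1 <- fit_quick(s1)
  m2 <- fit_quick(s2)
  # identical models: exact tie -> class 1
  tie <- classify_motion(s1$trials[[1L]], m1, m1)
  expect_equal(tie$label, 1L)
  expect_equal(tie$margin, 0)
  # prefix at model 1's state means -> class 1
  atmu <- classify_motion(m1$means[1:6, ], m1, m2)
  expect_equal(atmu$label, 1L)
  # swapping the model arguments swaps the label on a non-tie input
  sw <- classify_motion(m1$means[1:6, ], m2, m1)
  expect_equal(sw$label, 2L)
  expect_equal(sw$margin, -atmu$margin, tolerance = 1e-9)
  expect_error(classify_motion(s1$trials[[1L]][, 1, drop = FALSE], m1, m2),
               "channels")
})

test_that("the split protocol counts hold-outs as the printed arithmetic", {
  s1 <- noisy_curve_set(12, 10, seed = 3, label = 1L)
  s2 <- noisy_curve_set(12, 10, shift = 6, seed = 4, label = 2L)
  pr <- split_protocol(n_train = 11, n_repeats = 10, seed = 5)
  out <- evaluate_accuracy(s1, s2, pr, prefix_len = 10,
                           hmm_options(max_iter = 6))
  # 1 held-out trial per class per repeat -> 2 recognitions x 10 repeats
  expect_equal(out$n_recognitions, 20)
  expect_equal(unique(out$per_repeat$n_total), 2)
  # fully separable classes classify perfectly
  expect_equal(out$accuracy, 1.0)
  expect_error(evaluate_accuracy(s1, s2, split_protocol(12, 2), 10),
               "infeasible")
})

test_that("accuracy is invariant to class relabelling and reproducible", {
  s1 <- noisy_curve_set(8, 10, sd = 1.5, seed = 6)
  s2 <- noisy_curve_set(8, 10, sd = 1.5, shift = 1, seed = 7)
  pr <- split_protocol(n_train = 6, n_repeats = 6, seed = 8)
  a <- evaluate_accuracy(s1, s2, pr, 10, hmm_options(max_iter = 6))
  b <- evaluate_accuracy(s2, s1, pr, 10, hmm_options(max_iter = 6))
  expect_equal(a$accuracy, b$accuracy)
  a2 <- evaluate_accuracy(s1, s2, pr, 10, hmm_options(max_iter = 6))
  expect_identical(a$per_repeat, a2$per_repeat)
})

test_that("accuracy-vs-history shares splits and accrues information", {
  s1 <- noisy_curve_set(10, 16, sd = 2, seed = 9)
  s2 <- noisy_curve_set(10, 16, sd = 2, shift = 3, seed = 10)
  pr <- split_protocol(n_train = 8, n_repeats = 6, seed = 11)
  opts <- hmm_options(max_iter = 6)
  curve <- accuracy_vs_history(s1, s2, pr, c(2L, 8L, 16L), opts)
  expect_s3_class(curve, "accuracy_curve")
  expect_true(all(curve$summary$mean_accuracy >= 0 &
                    curve$summary$mean_accuracy <= 1))
  # full-length point reproduces evaluate_accuracy under the same protocol
  full <- evaluate_accuracy(s1, s2, pr, 16L, opts)
  expect_equal(curve$summary$mean_accuracy[3L],
               mean(full$per_repeat$accuracy))
  # on separable data the curve ends at least as high as it starts
  expect_gte(curve$summary$mean_accuracy[3L], curve$summary$mean_accuracy[1L])
  expect_error(accuracy_vs_history(s1, s2, pr, c(8L, 2L), opts),
               "strictly increasing")
  expect_equal(history_to_accuracy(curve, target = 2), NA_integer_)
})
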