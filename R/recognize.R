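#' Split protocol for accuracy and distance experiments
#'
#' The resampling protocol: per repetition, `n_train` trials per class are
#' drawn at random to fit the two class models and every remaining trial is
#' classified. The defaults (49 training trials, 100 repetitions) give
#' 100 x 2 = 200 recognitions when each class holds 50 trials.
#'
#' @param n_train trials per class used for fitting.
#' @param n_repeats number of random-split repetitions.
#' @param seed integer seed; splits and model initialisations derive from
#'   it, so paired comparisons across channels reuse identical splits.
#' @return A `split_protocol` object.
#' @export
split_protocol <- function(n_train = 49L, n_repeats = 100L, seed = 1L) {
  if (n_train < 1L) stop("'n_train' must be >= 1", call. = FALSE)
  if (n_repeats < 1L) stop("'n_repeats' must be >= 1", call. = FALSE)
  structure(list(n_train = as.integer(n_train),
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)),
            class = "split_protocol")
}

#' Baum-Welch fitting options for the experiment protocols
#'
#' @inheritParams lrhmm
#' @return A plain list of options consumed by the protocol functions.
#' @export
hmm_options <- function(max_iter = 50L, rel_tol = 1e-6, variance_floor = 1e-6,
                        self_prob = 0.1, band_width = 1L,
                        update_trans = FALSE) {
  list(max_iter = max_iter, rel_tol = rel_tol,
       variance_floor = variance_floor, self_prob = self_prob,
       band_width = band_width, update_trans = update_trans)
}

fit_with_opts <- function(trials, opts, seed) {
  lrhmm(trials, max_iter = opts$max_iter, rel_tol = opts$rel_tol,
        variance_floor = opts$variance_floor, self_prob = opts$self_prob,
        band_width = opts$band_width, update_trans = opts$update_trans,
        seed = seed)
}

#' Classify a trajectory prefix between two movement models
#'
#' The likelihood-comparison rule: the prefix is scored by the forward
#' algorithm under both class models and assigned to the class with the
#' larger log-likelihood; an exact tie goes to class 1.
#'
#' @param prefix a v x M matrix of the first v observations.
#' @param model_c1,model_c2 fitted `lrhmm` models for classes 1 and 2.
#' @return A list with `label` (1 or 2), `loglik1`, `loglik2` and `margin`
#'   (`loglik1 - loglik2`).
#' @export
classify_motion <- function(prefix, model_c1, model_c2) {
  prefix <- as.matrix(prefix)
  if (nrow(prefix) < 1L) stop("prefix must have at least one sample",
                              call. = FALSE)
  if (model_c1$n_channels != model_c2$n_channels ||
      ncol(prefix) != model_c1$n_channels)
    stop("models and prefix must share the same number of channels",
         call. = FALSE)
  ll1 <- forward_loglik(model_c1, prefix)
  ll2 <- forward_loglik(model_c2, prefix)
  list(label = if (ll2 > ll1) 2L else 1L, loglik1 = ll1, loglik2 = ll2,
       margin = ll1 - ll2)
}

# Shared split-refit-score machinery. For each repetition: draw n_train
# trials per class (seeded from the protocol), fit both class models on the
# full-length training trials, then score every held-out trial's prefix
# log-likelihood under both models at every requested length in one forward
# sweep. Returns per-repeat matrices ll11, ll12, ll21, ll22 (held-out
# trials x lengths; first index = true class, second = scoring model).
split_eval <- function(set_c1, set_c2, protocol, prefix_lengths, hmm_opts) {
  stopifnot(inherits(protocol, "split_protocol"))
  k1 <- n_trials(set_c1); k2 <- n_trials(set_c2)
  if (protocol$n_train >= k1 || protocol$n_train >= k2)
    stop("infeasible protocol: n_train must leave at least one test trial per class",
         call. = FALSE)
  vlen <- n_steps(set_c1)
  if (n_steps(set_c2) != vlen)
    stop("the two classes must share the trial length V", call. = FALSE)
  prefix_lengths <- as.integer(prefix_lengths)
  if (any(prefix_lengths < 1L) || any(prefix_lengths > vlen))
    stop("prefix lengths must lie in 1..V", call. = FALSE)
  if (is.unsorted(prefix_lengths, strictly = TRUE))
    stop("prefix lengths must be strictly increasing", call. = FALSE)
  lapply(seq_len(protocol$n_repeats), function(r) {
    idx <- with_seed(derive_seed(protocol$seed, "split", r), {
      list(tr1 = sample.int(k1, protocol$n_train),
           tr2 = sample.int(k2, protocol$n_train))
    })
    m1 <- fit_with_opts(set_c1[idx$tr1], hmm_opts,
                        derive_seed(protocol$seed, "init1", r))
    m2 <- fit_with_opts(set_c2[idx$tr2], hmm_opts,
                        derive_seed(protocol$seed, "init2", r))
    te1 <- set_c1$trials[setdiff(seq_len(k1), idx$tr1)]
    te2 <- set_c2$trials[setdiff(seq_len(k2), idx$tr2)]
    score <- function(trials, model)
      t(vapply(trials,
               function(y) forward_cumloglik(model, y)[prefix_lengths],
               numeric(length(prefix_lengths))))
    list(ll11 = score(te1, m1), ll12 = score(te1, m2),
         ll21 = score(te2, m1), ll22 = score(te2, m2))
  })
}

acc_from_scores <- function(scores, prefix_lengths) {
  rows <- lapply(seq_along(scores), function(r) {
    s <- scores[[r]]
    n1 <- nrow(s$ll11); n2 <- nrow(s$ll22)
    correct <- colSums(s$ll11 >= s$ll12) + colSums(s$ll22 > s$ll21)
    data.frame(repeat_id = r, prefix_len = prefix_lengths,
               n_correct = as.integer(correct),
               n_total = n1 + n2,
               accuracy = correct / (n1 + n2))
  })
  do.call(rbind, rows)
}

#' Motion recognition accuracy under the split protocol
#'
#' Per repetition, fits the two class models on `n_train` randomly chosen
#' trials each and classifies every held-out trial's prefix of
#' `prefix_len` samples from both classes; accuracy is the number of
#' correct recognitions over the total.
#'
#' @param set_c1,set_c2 equal-length `trajectory_set`s for the two classes.
#' @param protocol a [split_protocol()].
#' @param prefix_len history length in samples.
#' @param hmm_opts fitting options from [hmm_options()].
#' @return A list with `accuracy` (pooled over all recognitions),
#'   `n_recognitions`, and `per_repeat` (a data frame of repeat-level
#'   outcomes).
#' @export
evaluate_accuracy <- function(set_c1, set_c2, protocol, prefix_len,
                              hmm_opts = hmm_options()) {
  scores <- split_eval(set_c1, set_c2, protocol, prefix_len, hmm_opts)
  df <- acc_from_scores(scores, as.integer(prefix_len))
  list(accuracy = sum(df$n_correct) / sum(df$n_total),
       n_recognitions = sum(df$n_total),
       per_repeat = df)
}

#' Accuracy as a function of movement-history length
#'
#' Evaluates recognition accuracy at each prefix length with splits and
#' model fits shared across lengths (each repetition fits once and scores
#' all prefixes in a single forward sweep), so the curve is a paired
#' comparison across history lengths. Running two channels with the same
#' protocol seed pairs the curves across channels as well.
#'
#' @inheritParams evaluate_accuracy
#' @param prefix_lengths strictly increasing history lengths (samples).
#' @return An `accuracy_curve`: list with `summary` (prefix_len,
#'   mean_accuracy, sd_accuracy), `per_repeat`, `prefix_lengths`,
#'   `sample_rate`.
#' @export
accuracy_vs_history <- function(set_c1, set_c2, protocol, prefix_lengths,
                                hmm_opts = hmm_options()) {
  scores <- split_eval(set_c1, set_c2, protocol, prefix_lengths, hmm_opts)
  df <- acc_from_scores(scores, as.integer(prefix_lengths))
  agg_m <- tapply(df$accuracy, df$prefix_len, mean)
  agg_s <- tapply(df$accuracy, df$prefix_len, stats::sd)
  lens <- as.integer(names(agg_m))
  o <- order(lens)
  structure(
    list(summary = data.frame(prefix_len = lens[o],
                              mean_accuracy = as.numeric(agg_m)[o],
                              sd_accuracy = as.numeric(agg_s)[o]),
         per_repeat = df,
         prefix_lengths = as.integer(prefix_lengths),
         sample_rate = set_c1$sample_rate),
    class = "accuracy_curve")
}

#' @export
print.accuracy_curve <- function(x, ...) {
  cat("<accuracy_curve> recognition accuracy vs history length\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
plot.accuracy_curve <- function(x, add = FALSE, col = "black", ...) {
  t_axis <- x$summary$prefix_len / x$sample_rate
  m <- x$summary$mean_accuracy
  s <- x$summary$sd_accuracy
  if (!add)
    graphics::plot(t_axis, m, type = "n", ylim = c(0, 1),
                   xlab = "history length (s)", ylab = "recognition accuracy",
                   ...)
  graphics::polygon(c(t_axis, rev(t_axis)),
                    c(pmin(m + s, 1), rev(pmax(m - s, 0))),
                    border = NA, col = grDevices::adjustcolor(col, 0.2))
  graphics::lines(t_axis, m, col = col, lwd = 2)
  invisible(x)
}

#' Shortest history reaching a target accuracy
#'
#' @param curve an `accuracy_curve`.
#' @param target accuracy threshold (default 0.95).
#' @return The smallest prefix length whose mean accuracy meets `target`,
#'   or `NA` if none does.
#' @export
history_to_accuracy <- function(curve, target = 0.95) {
  hit <- which(curve$summary$mean_accuracy >= target)
  if (length(hit) == 0L) return(NA_integer_)
  curve$summary$prefix_len[min(hit)]
}
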