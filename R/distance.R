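#' Cross-fitness distance between two fitted movement models
#'
#' The four-term log-likelihood contrast measuring how much better each
#' class's held-out data fit their own model than the rival model:
#' `D = logP(Y1|m1) + logP(Y2|m2) - logP(Y1|m2) - logP(Y2|m1)`, with each
#' term the mean forward log-likelihood over the corresponding held-out
#' prefixes. Identical models give exactly 0 for any data; well-separated
#' classes give large positive values, and larger D indicates more
#' discriminative information in the channel.
#'
#' @param model_c1,model_c2 fitted `lrhmm` models.
#' @param test_c1,test_c2 held-out trials per class: a `trajectory_set`,
#'   list of matrices, or single matrix.
#' @param prefix_len history length in samples (default: full trials).
#' @return The distance D (scalar).
#' @export
cross_fitness <- function(model_c1, model_c2, test_c1, test_c2,
                          prefix_len = NULL) {
  tr1 <- if (inherits(test_c1, "trajectory_set")) test_c1$trials
         else if (is.list(test_c1)) test_c1 else list(as.matrix(test_c1))
  tr2 <- if (inherits(test_c2, "trajectory_set")) test_c2$trials
         else if (is.list(test_c2)) test_c2 else list(as.matrix(test_c2))
  if (length(tr1) == 0L || length(tr2) == 0L)
    stop("empty test set", call. = FALSE)
  if (model_c1$n_channels != model_c2$n_channels)
    stop("models must share the same number of channels", call. = FALSE)
  mean_ll <- function(trials, model)
    mean(vapply(trials, function(y) {
      y <- as.matrix(y)
      v <- if (is.null(prefix_len)) nrow(y) else prefix_len
      forward_loglik(model, y, v)
    }, numeric(1)))
  mean_ll(tr1, model_c1) + mean_ll(tr2, model_c2) -
    mean_ll(tr1, model_c2) - mean_ll(tr2, model_c1)
}

#' Cross-fitness distance as a function of history length
#'
#' Per split, fits the two class models on the training trials and
#' computes the cross-fitness distance of the held-out prefixes at every
#' history length (one forward sweep per trial and model). Reported as
#' mean +/- sd over splits, matching the accuracy protocol so the two
#' curves are paired.
#'
#' @inheritParams accuracy_vs_history
#' @return A `distance_curve`: list with `summary` (prefix_len, mean_D,
#'   sd_D), `per_split`, `prefix_lengths`, `sample_rate`.
#' @export
distance_vs_history <- function(set_c1, set_c2, protocol, prefix_lengths,
                                hmm_opts = hmm_options()) {
  scores <- split_eval(set_c1, set_c2, protocol, prefix_lengths, hmm_opts)
  prefix_lengths <- as.integer(prefix_lengths)
  rows <- lapply(seq_along(scores), function(r) {
    s <- scores[[r]]
    d <- colMeans(s$ll11) + colMeans(s$ll22) -
      colMeans(s$ll12) - colMeans(s$ll21)
    data.frame(split = r, prefix_len = prefix_lengths, D = d)
  })
  df <- do.call(rbind, rows)
  agg_m <- tapply(df$D, df$prefix_len, mean)
  agg_s <- tapply(df$D, df$prefix_len, stats::sd)
  lens <- as.integer(names(agg_m))
  o <- order(lens)
  structure(
    list(summary = data.frame(prefix_len = lens[o],
                              mean_D = as.numeric(agg_m)[o],
                              sd_D = as.numeric(agg_s)[o]),
         per_split = df,
         prefix_lengths = prefix_lengths,
         sample_rate = set_c1$sample_rate),
    class = "distance_curve")
}

#' @export
print.distance_curve <- function(x, ...) {
  cat("<distance_curve> cross-fitness distance vs history length\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
plot.distance_curve <- function(x, add = FALSE, col = "black", ...) {
  t_axis <- x$summary$prefix_len / x$sample_rate
  m <- x$summary$mean_D
  s <- x$summary$sd_D
  if (!add)
    graphics::plot(t_axis, m, type = "n",
                   ylim = range(c(m - s, m + s), finite = TRUE),
                   xlab = "history length (s)",
                   ylab = "cross-fitness distance", ...)
  graphics::polygon(c(t_axis, rev(t_axis)), c(m + s, rev(m - s)),
                    border = NA, col = grDevices::adjustcolor(col, 0.2))
  graphics::lines(t_axis, m, col = col, lwd = 2)
  invisible(x)
}
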