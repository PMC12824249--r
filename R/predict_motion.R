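#' Probabilistic trajectory model of the rigid channel
#'
#' Orders the fitted model's emission Gaussians by the most likely state
#' sequence: the Viterbi path assigns a state to every time step, and step
#' v's predictive density is that state's emission Gaussian. By default
#' every supplied trial is decoded and step v takes the modal state across
#' trials (ties toward the smaller state index); with
#' `method = "single"` the first trial alone is decoded.
#'
#' @param model a fitted `lrhmm` for the rigid channel.
#' @param reference trials to decode: a `trajectory_set`, list of matrices,
#'   or one matrix of length V.
#' @param label class label carried by the model (1 or 2).
#' @param method `"modal"` (default) or `"single"`.
#' @return A `trajectory_model`: per-step `means` and `sds` (V x M
#'   matrices), `path` (the state sequence used), `label`, `channels`.
#' @export
build_trajectory_model <- function(model, reference, label = NA_integer_,
                                   method = c("modal", "single")) {
  method <- match.arg(method)
  trials <- if (inherits(reference, "trajectory_set")) reference$trials
            else if (is.list(reference)) reference else list(as.matrix(reference))
  if (method == "single") trials <- trials[1L]
  paths <- vapply(trials, function(y) viterbi(model, as.matrix(y))$path,
                  integer(model$n_states))
  paths <- matrix(paths, nrow = model$n_states)
  q <- apply(paths, 1, function(states) {
    tab <- tabulate(states, nbins = model$n_states)
    which.max(tab)            # first max = smallest state on ties
  })
  sds <- sqrt(pmax(model$variances, model$variance_floor))
  structure(
    list(means = model$means[q, , drop = FALSE],
         sds = sds[q, , drop = FALSE],
         path = as.integer(q),
         label = label,
         channels = model$channels,
         n_steps = model$n_states),
    class = "trajectory_model")
}

#' @export
print.trajectory_model <- function(x, ...) {
  cat(sprintf("<trajectory_model> %d steps x %d channels%s\n",
              x$n_steps, length(x$channels),
              if (is.na(x$label)) "" else sprintf(", class %d", x$label)))
  invisible(x)
}

#' @export
plot.trajectory_model <- function(x, band_k = 5, channel = 1L, ...) {
  v <- seq_len(x$n_steps)
  m <- x$means[, channel]
  s <- x$sds[, channel]
  graphics::plot(v, m, type = "l", lwd = 2,
                 ylim = range(c(m - band_k * s, m + band_k * s)),
                 xlab = "time step", ylab = x$channels[channel], ...)
  graphics::polygon(c(v, rev(v)), c(m + band_k * s, rev(m - band_k * s)),
                    border = NA, col = grDevices::adjustcolor("grey40", 0.25))
  graphics::lines(v, m, lwd = 2)
  invisible(x)
}

#' Predict future rigid motion from a fabric-channel prefix
#'
#' The deployment step: the movement class is recognised from the fabric
#' prefix by the likelihood rule, then the recognised class's trajectory
#' model supplies the future rigid-channel course as per-step Gaussian
#' envelopes `mean +/- band_k * sd` for steps `v_now + 1 .. V`. The figures
#' of the physical-rig experiments shade `band_k = 5`; the human-reaching
#' figure uses `band_k = 3`.
#'
#' @param tm_c1,tm_c2 `trajectory_model`s of the rigid channel for the two
#'   classes.
#' @param fabric_prefix the observed fabric-channel prefix (at least
#'   `v_now` samples; rows beyond `v_now` are ignored).
#' @param fabric_models list of the two fabric-channel `lrhmm` models.
#' @param v_now current time step (1 <= v_now < V).
#' @param band_k envelope half-width in emission sds.
#' @return A list with `label`, `margin` (log-likelihood margin for class
#'   1), and `prediction`: a data frame with `step` and, per channel,
#'   `mean_*`, `lo_*`, `hi_*`.
#' @export
predict_future <- function(tm_c1, tm_c2, fabric_prefix, fabric_models,
                           v_now, band_k = 5) {
  stopifnot(inherits(tm_c1, "trajectory_model"),
            inherits(tm_c2, "trajectory_model"))
  vlen <- tm_c1$n_steps
  if (tm_c2$n_steps != vlen)
    stop("the two trajectory models must share the length V", call. = FALSE)
  if (v_now < 1L || v_now >= vlen)
    stop("'v_now' must satisfy 1 <= v_now < V", call. = FALSE)
  fabric_prefix <- as.matrix(fabric_prefix)
  cl <- classify_motion(trial_prefix(fabric_prefix, v_now),
                        fabric_models[[1L]], fabric_models[[2L]])
  tm <- if (cl$label == 1L) tm_c1 else tm_c2
  steps <- (v_now + 1L):vlen
  out <- data.frame(step = steps)
  for (m in seq_along(tm$channels)) {
    mu <- tm$means[steps, m]
    hw <- band_k * tm$sds[steps, m]
    out[[paste0("mean_", tm$channels[m])]] <- mu
    out[[paste0("lo_", tm$channels[m])]] <- mu - hw
    out[[paste0("hi_", tm$channels[m])]] <- mu + hw
  }
  list(label = cl$label, margin = cl$margin, prediction = out)
}
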