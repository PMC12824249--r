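#' Fill missing samples by piecewise cubic spline interpolation
#'
#' Each channel of each trial is interpolated through its present samples
#' with a cubic spline (Forsythe-Malcolm-Moler end conditions, which
#' reproduce cubic polynomials exactly); present samples are left untouched.
#' The first and last sample of every channel must be present.
#'
#' @param trajs a `trajectory_set` (or a single trial matrix) with `NA`
#'   marking missing samples.
#' @return The input with all missing samples filled.
#' @export
fill_gaps <- function(trajs) {
  fill_one <- function(y) {
    if (!anyNA(y)) return(y)
    vlen <- nrow(y)
    for (m in seq_len(ncol(y))) {
      miss <- is.na(y[, m])
      if (!any(miss)) next
      if (miss[1L] || miss[vlen])
        stop("unrecoverable gap: first or last sample missing in a channel",
             call. = FALSE)
      ok <- which(!miss)
      y[miss, m] <- stats::spline(ok, y[ok, m], xout = which(miss),
                                  method = "fmm")$y
    }
    y
  }
  if (inherits(trajs, "trajectory_set")) {
    trajs$trials <- lapply(trajs$trials, fill_one)
    trajs
  } else fill_one(as.matrix(trajs))
}

#' Detect the movement-onset sample of a trial
#'
#' Returns the smallest index `v` inside the search window for which the
#' inter-sample displacement `|x[v] - x[v-1]|` on the designated channel
#' exceeds the threshold. The thresholds used by the three study scenarios
#' are 1 mm (frequency task), 0.5 mm (pattern task) and 10 mm (reaching);
#' they are passed in the channel's own units.
#'
#' @param trial a V x M trial matrix.
#' @param channel index of the horizontal-position channel.
#' @param threshold onset threshold in channel units.
#' @param window integer range of candidate onset indices (default: the
#'   whole trial).
#' @return The onset index.
#' @export
detect_start <- function(trial, channel = 1L, threshold, window = NULL) {
  trial <- as.matrix(trial)
  vlen <- nrow(trial)
  if (channel < 1L || channel > ncol(trial))
    stop("channel index out of range", call. = FALSE)
  if (!is.numeric(threshold) || threshold <= 0)
    stop("invalid configuration: field 'threshold' must be > 0", call. = FALSE)
  if (is.null(window)) window <- 2:vlen
  window <- window[window >= 2L & window <= vlen]
  if (length(window) == 0L)
    stop("search window outside the trial", call. = FALSE)
  x <- trial[, channel]
  hit <- window[abs(x[window] - x[window - 1L]) > threshold]
  if (length(hit) == 0L)
    stop("no onset: no inter-sample displacement exceeds the threshold",
         call. = FALSE)
  min(hit)
}

#' Time-align every trial of a set at its movement onset
#'
#' Finds each trial's onset on the designated rigid channel (or uses
#' `starts` supplied from a paired rigid set, as fabric channels inherit the
#' rigid channel's start) and crops the trial to `length` samples from the
#' onset.
#'
#' @param set a `trajectory_set`.
#' @param channel onset-detection channel (ignored when `starts` given).
#' @param threshold onset threshold in channel units.
#' @param length number of samples to retain from the onset.
#' @param window optional search window of candidate onset indices.
#' @param starts optional integer vector of start indices, one per trial,
#'   e.g. taken from the rigid set's alignment.
#' @return The aligned set, with attribute `"start_indices"`.
#' @export
align_trials <- function(set, channel = 1L, threshold = NULL, length,
                         window = NULL, starts = NULL) {
  stopifnot(inherits(set, "trajectory_set"))
  k <- n_trials(set)
  if (is.null(starts)) {
    starts <- vapply(set$trials, detect_start, 1L,
                     channel = channel, threshold = threshold, window = window)
  }
  if (base::length(starts) != k)
    stop("'starts' must give one index per trial", call. = FALSE)
  out <- set
  out$trials <- lapply(seq_len(k), function(i) {
    y <- set$trials[[i]]
    if (starts[i] + length - 1L > nrow(y))
      stop(sprintf("trial %d too short after its onset (needs %d samples, has %d)",
                   i, length, nrow(y) - starts[i] + 1L), call. = FALSE)
    y[starts[i]:(starts[i] + length - 1L), , drop = FALSE]
  })
  attr(out, "start_indices") <- as.integer(starts)
  out
}

#' Detect the first crest of a periodic position channel
#'
#' Phase alignment for periodic motion: returns the index of the maximum
#' of a moving-average-smoothed position channel within the search window,
#' i.e. the first crest, so that cropping every trial at its crest leaves
#' all trials at a common phase reference (up to the detection jitter that
#' sensor noise and sampling impose).
#'
#' @param trial a V x M trial matrix.
#' @param channel position channel index.
#' @param window integer range of candidate crest indices.
#' @param smooth moving-average half-window in samples.
#' @return The crest index.
#' @export
detect_crest <- function(trial, channel = 1L, window, smooth = 2L) {
  trial <- as.matrix(trial)
  x <- trial[, channel]
  vlen <- length(x)
  window <- window[window >= 1L & window <= vlen]
  if (length(window) == 0L)
    stop("search window outside the trial", call. = FALSE)
  xs <- stats::filter(x, rep(1 / (2 * smooth + 1), 2 * smooth + 1),
                      sides = 2)
  xs[is.na(xs)] <- -Inf
  window[which.max(xs[window])]
}

# Unwrap a degree series so no step jumps by more than 180.
unwrap_deg_vec <- function(a) {
  d <- diff(a)
  d <- d - 360 * round(d / 360)
  c(a[1L], a[1L] + cumsum(d))
}

#' Unwrap orientation channels
#'
#' Removes +/-180-degree wrap discontinuities from the selected channels of
#' every trial, so that offsets and differences are meaningful.
#'
#' @param set a `trajectory_set`.
#' @param channels indices of the orientation channels.
#' @return The set with unwrapped angles.
#' @export
unwrap_angles <- function(set, channels) {
  stopifnot(inherits(set, "trajectory_set"))
  set$trials <- lapply(set$trials, function(y) {
    for (m in channels) y[, m] <- unwrap_deg_vec(y[, m])
    y
  })
  set
}

#' Standardise initial orientation across two movement classes
#'
#' Computes one constant offset per selected channel — the mean initial
#' (first-sample) value over the class-1 trials — and subtracts it from
#' BOTH classes, so class 1's mean initial orientation becomes 0 on every
#' axis while all within-series differences and the between-class contrast
#' are preserved.
#'
#' @param class1,class2 aligned `trajectory_set`s with the same channels.
#' @param channels indices of the orientation channels to standardise.
#' @return A list with `class1`, `class2` and the applied `offsets`.
#' @export
standardize_initial <- function(class1, class2, channels) {
  stopifnot(inherits(class1, "trajectory_set"),
            inherits(class2, "trajectory_set"))
  if (n_trials(class1) == 0L || n_trials(class2) == 0L)
    stop("empty trajectory set", call. = FALSE)
  first_vals <- t(vapply(class1$trials,
                         function(y) y[1L, channels, drop = TRUE],
                         numeric(length(channels))))
  if (length(channels) == 1L) first_vals <- matrix(first_vals, ncol = 1L)
  offsets <- colMeans(first_vals)
  shift <- function(set) {
    set$trials <- lapply(set$trials, function(y) {
      y[, channels] <- sweep(y[, channels, drop = FALSE], 2, offsets)
      y
    })
    set
  }
  list(class1 = shift(class1), class2 = shift(class2), offsets = offsets)
}

#' Per-trial baseline correction of orientation channels
#'
#' Shifts each trial's selected channels so that its own first sample is 0,
#' removing slow drift of the mechanism between repetitions (unlike
#' [standardize_initial()], which subtracts one shared constant).
#'
#' @param set a `trajectory_set`.
#' @param channels indices of the orientation channels.
#' @return The baseline-corrected set.
#' @export
baseline_correct <- function(set, channels) {
  stopifnot(inherits(set, "trajectory_set"))
  set$trials <- lapply(set$trials, function(y) {
    y[, channels] <- sweep(y[, channels, drop = FALSE], 2,
                           y[1L, channels, drop = TRUE])
    y
  })
  set
}

#' Resample a trial to a fixed number of samples by linear interpolation
#'
#' Interpolates each channel linearly onto a uniform grid of `v_target`
#' points spanning the trial's original time range.
#'
#' @param traj a single trial matrix, or a `trajectory_set` (every trial is
#'   resampled; the set's sample rate is rescaled per the common original
#'   length when trials share one length).
#' @param v_target desired number of samples (>= 2).
#' @return The resampled trial or set.
#' @export
resample_trajectory <- function(traj, v_target) {
  if (v_target < 2L)
    stop("invalid configuration: field 'v_target' must be >= 2", call. = FALSE)
  res_one <- function(y) {
    vlen <- nrow(y)
    if (vlen < 2L) stop("trial needs at least 2 samples", call. = FALSE)
    grid <- seq(1, vlen, length.out = v_target)
    out <- apply(y, 2, function(ch) stats::approx(seq_len(vlen), ch,
                                                  xout = grid)$y)
    colnames(out) <- colnames(y)
    out
  }
  if (inherits(traj, "trajectory_set")) {
    v0 <- unique(vapply(traj$trials, nrow, 1L))
    traj$trials <- lapply(traj$trials, res_one)
    if (length(v0) == 1L)
      traj$sample_rate <- traj$sample_rate * (v_target - 1) / (v0 - 1)
    traj
  } else res_one(as.matrix(traj))
}
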