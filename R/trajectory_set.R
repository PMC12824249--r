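#' Labelled set of multichannel motion trajectories
#'
#' A `trajectory_set` holds K repetitions (trials) of a movement, each a
#' numeric matrix with V rows (time steps) and M columns (sensor channels),
#' together with the sampling rate, channel names, channel roles
#' (`"rigid"` or `"fabric"`) and an optional class label. Trials may have
#' different lengths before alignment; most model-fitting functions require
#' equal lengths. Missing samples are stored as `NA`.
#'
#' @param trials list of numeric matrices, one per trial, each V x M with the
#'   same number of columns.
#' @param sample_rate sampling frequency in Hz.
#' @param channels character vector of channel names (defaults to column
#'   names of the first trial, or `ch1..chM`).
#' @param roles character vector, one of `"rigid"`/`"fabric"` per channel.
#' @param label optional class label (1 or 2, or `NA`).
#' @param units optional character vector of channel units.
#'
#' @return An object of class `trajectory_set`.
#' @export
trajectory_set <- function(trials, sample_rate, channels = NULL,
                           roles = NULL, label = NA_integer_, units = NULL) {
  if (!is.list(trials) || length(trials) == 0L)
    stop("'trials' must be a non-empty list of matrices", call. = FALSE)
  trials <- lapply(trials, function(y) {
    y <- as.matrix(y)
    storage.mode(y) <- "double"
    y
  })
  m <- ncol(trials[[1L]])
  if (any(vapply(trials, ncol, 1L) != m))
    stop("all trials must have the same number of channels", call. = FALSE)
  if (any(vapply(trials, nrow, 1L) < 1L))
    stop("trials must have at least one sample", call. = FALSE)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("'sample_rate' must be a positive scalar", call. = FALSE)
  if (is.null(channels)) {
    channels <- colnames(trials[[1L]])
    if (is.null(channels)) channels <- paste0("ch", seq_len(m))
  }
  if (length(channels) != m)
    stop("'channels' must name every column", call. = FALSE)
  if (is.null(roles)) roles <- rep("rigid", m)
  roles <- match.arg(roles, c("rigid", "fabric"), several.ok = TRUE)
  if (length(roles) == 1L) roles <- rep(roles, m)
  if (length(roles) != m)
    stop("'roles' must have one entry per channel", call. = FALSE)
  trials <- lapply(trials, function(y) { colnames(y) <- channels; y })
  structure(
    list(trials = trials, sample_rate = sample_rate, channels = channels,
         roles = roles, label = label, units = units),
    class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  v <- vapply(x$trials, nrow, 1L)
  cat(sprintf("<trajectory_set> %d trials x %d channels @ %g Hz\n",
              length(x$trials), length(x$channels), x$sample_rate))
  cat(sprintf("  steps per trial: %s\n",
              if (length(unique(v)) == 1L) as.character(v[1L])
              else paste0(min(v), "-", max(v))))
  cat(sprintf("  channels: %s\n",
              paste0(x$channels, " (", x$roles, ")", collapse = ", ")))
  if (!is.na(x$label)) cat(sprintf("  class label: %d\n", x$label))
  invisible(x)
}

#' @export
length.trajectory_set <- function(x) length(x$trials)

#' Subset the trials of a trajectory set
#'
#' @param x a `trajectory_set`.
#' @param i trial indices.
#' @param ... unused.
#' @return A `trajectory_set` with the selected trials.
#' @export
`[.trajectory_set` <- function(x, i, ...) {
  out <- x
  out$trials <- x$trials[i]
  if (length(out$trials) == 0L)
    stop("empty trial subset", call. = FALSE)
  out
}

#' Number of trials, time steps and channels
#'
#' @param x a `trajectory_set`.
#' @return `n_trials()` the number of trials K; `n_steps()` the common trial
#'   length V (error if trials differ); `n_channels()` the channel count M.
#' @export
n_trials <- function(x) length(x$trials)

#' @rdname n_trials
#' @export
n_steps <- function(x) {
  v <- unique(vapply(x$trials, nrow, 1L))
  if (length(v) != 1L)
    stop("trials have unequal lengths; align or resample first", call. = FALSE)
  v
}

#' @rdname n_trials
#' @export
n_channels <- function(x) length(x$channels)

#' Select channels of a trajectory set
#'
#' @param x a `trajectory_set`.
#' @param channels channel indices, names, or a role (`"rigid"`/`"fabric"`)
#'   when `by_role = TRUE`.
#' @param by_role interpret `channels` as a role.
#' @return A `trajectory_set` restricted to those channels.
#' @export
select_channels <- function(x, channels, by_role = FALSE) {
  if (by_role) {
    idx <- which(x$roles == match.arg(channels, c("rigid", "fabric")))
  } else if (is.character(channels)) {
    idx <- match(channels, x$channels)
    if (anyNA(idx)) stop("unknown channel name", call. = FALSE)
  } else idx <- as.integer(channels)
  if (length(idx) == 0L || any(idx < 1L) || any(idx > length(x$channels)))
    stop("channel selection out of range", call. = FALSE)
  out <- x
  out$trials <- lapply(x$trials, function(y) y[, idx, drop = FALSE])
  out$channels <- x$channels[idx]
  out$roles <- x$roles[idx]
  if (!is.null(x$units)) out$units <- x$units[idx]
  out
}

#' First-v-samples prefix of a trial
#'
#' @param trial a V x M trial matrix.
#' @param v prefix length in samples (1..V).
#' @return The first `v` rows of `trial`.
#' @export
trial_prefix <- function(trial, v) {
  trial <- as.matrix(trial)
  if (v < 1L || v > nrow(trial))
    stop("prefix length out of range", call. = FALSE)
  trial[seq_len(v), , drop = FALSE]
}

# Missing-sample mask: list of logical matrices (TRUE = missing)
#' Missing-sample flags of a trajectory set
#'
#' @param x a `trajectory_set`.
#' @return A list of logical matrices, TRUE where a sample is missing.
#' @export
missing_mask <- function(x) lapply(x$trials, is.na)

# Run a block with a private, seeded RNG stream, restoring global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a reproducible child seed
#'
#' Child seeds are a pure function of the master seed, a stage name and a
#' repeat index, so every stage of an experiment draws from its own stream
#' and whole runs replay bit-for-bit from the master seed alone.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @param index non-negative repeat index.
#' @return An integer seed in 1..2^31-2.
#' @export
derive_seed <- function(master, stage, index = 0L) {
  h <- 0
  for (ch in utf8ToInt(as.character(stage))) h <- (h * 31 + ch) %% 2147483647
  s <- (abs(as.numeric(master)) %% 2147483647)
  val <- (s * 48271 + h * 16807 + as.numeric(index) * 69621) %% 2147483646
  as.integer(val + 1)
}
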