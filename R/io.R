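#' Write a trajectory set as delimited-text trial files plus a manifest
#'
#' One CSV per trial (columns `time_s, ch1..chM`, header row, 17
#' significant digits so the round trip is bit-exact) and a YAML manifest
#' recording trial file names, class label, channel names/roles/units,
#' sample rate, seed and an optional generator-config echo.
#'
#' @param set a `trajectory_set`.
#' @param dir output directory (created if needed).
#' @param name stem for the trial file names.
#' @param seed seed recorded in the manifest (provenance).
#' @param provenance free-text or config list echoed into the manifest.
#' @return The manifest path, invisibly.
#' @export
write_trajectory_set <- function(set, dir, name = "trial", seed = NA_integer_,
                                 provenance = "generated") {
  stopifnot(inherits(set, "trajectory_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(n_trials(set))
  for (k in seq_len(n_trials(set))) {
    y <- set$trials[[k]]
    tt <- (seq_len(nrow(y)) - 1) / set$sample_rate
    txt <- cbind(sprintf("%.17g", tt),
                 matrix(sprintf("%.17g", y), nrow(y)))
    files[k] <- sprintf("%s_%03d.csv", name, k)
    con <- file.path(dir, files[k])
    writeLines(c(paste(c("time_s", set$channels), collapse = ","),
                 apply(txt, 1, paste, collapse = ",")), con)
  }
  manifest <- list(
    format = "fabmotion_dataset",
    version = 1L,
    sample_rate = set$sample_rate,
    channels = as.list(set$channels),
    roles = as.list(set$roles),
    units = if (is.null(set$units)) NULL else as.list(set$units),
    label = if (is.na(set$label)) NULL else as.integer(set$label),
    seed = if (is.na(seed)) NULL else as.integer(seed),
    provenance = provenance,
    trials = as.list(files))
  mpath <- file.path(dir, paste0(name, "_manifest.yaml"))
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}

#' Read a trajectory set from a manifest
#'
#' Validates the manifest and every referenced trial file at load:
#' missing files, malformed rows and inconsistent column counts raise a
#' parse error naming the file (and line).
#'
#' @param manifest_path path to a manifest written by
#'   [write_trajectory_set()].
#' @return The restored `trajectory_set`.
#' @export
read_trajectory_set <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop(sprintf("parse error: manifest '%s' does not exist", manifest_path),
         call. = FALSE)
  man <- yaml::read_yaml(manifest_path)
  if (!identical(man$format, "fabmotion_dataset"))
    stop(sprintf("parse error: '%s' is not a fabmotion dataset manifest",
                 manifest_path), call. = FALSE)
  dir <- dirname(manifest_path)
  channels <- unlist(man$channels)
  m <- length(channels)
  trials <- lapply(unlist(man$trials), function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path))
      stop(sprintf("parse error: trial file '%s' referenced by the manifest is missing", f),
           call. = FALSE)
    lines <- readLines(path)
    nf <- lengths(strsplit(lines, ",", fixed = TRUE))
    bad <- which(nf != m + 1L)
    if (length(bad))
      stop(sprintf("parse error in '%s' line %d: expected %d columns, found %d",
                   f, bad[1L], m + 1L, nf[bad[1L]]), call. = FALSE)
    vals <- utils::read.csv(path, header = TRUE)
    if (anyNA(suppressWarnings(as.numeric(as.matrix(vals)))))
      stop(sprintf("parse error in '%s': non-numeric value", f),
           call. = FALSE)
    y <- as.matrix(vals[, -1L, drop = FALSE])
    colnames(y) <- channels
    y
  })
  trajectory_set(trials,
                 sample_rate = man$sample_rate,
                 channels = channels,
                 roles = unlist(man$roles),
                 label = if (is.null(man$label)) NA_integer_
                         else as.integer(man$label),
                 units = if (is.null(man$units)) NULL else unlist(man$units))
}

#' Write an accuracy or distance curve as tidy delimited text
#'
#' Accuracy rows: `channel, prefix_len, repeat, n_correct, n_total,
#' accuracy`; distance rows: `channel, prefix_len, split, D`.
#'
#' @param curve an `accuracy_curve` or `distance_curve`.
#' @param path output file.
#' @param channel channel-role tag recorded in the first column.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, channel = "rigid") {
  if (inherits(curve, "accuracy_curve")) {
    df <- cbind(channel = channel, curve$per_repeat)
    names(df)[names(df) == "repeat_id"] <- "repeat"
  } else if (inherits(curve, "distance_curve")) {
    df <- cbind(channel = channel, curve$per_split)
  } else stop("not a curve object", call. = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
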