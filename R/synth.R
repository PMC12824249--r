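#' Configuration objects for the synthetic movement generators
#'
#' Constructors that validate the parameters of the three synthetic
#' scenarios (scotch-yoke harmonics, rotated point-to-point patterns,
#' minimum-jerk reaching) and of the driven fabric chain. Each returns a
#' classed list; invalid values raise an error naming the offending field.
#'
#' @param omega angular frequency of the crank (rad/s).
#' @param radius crank (disk) radius in cm.
#' @param sample_rate sampling frequency in Hz.
#' @param duration trial duration in seconds (excludes `lead_in`).
#' @param phase_mode `"random"` draws the starting phase per trial from
#'   Uniform\[0, 2*pi); `"fixed"` uses `phase`.
#' @param phase fixed starting phase (rad), used when `phase_mode = "fixed"`.
#' @param lead_in seconds of rest (crank held at its start position) recorded
#'   before motion begins; gives onset detection something to find.
#' @param noise_sd standard deviation of additive Gaussian sensor noise, in
#'   channel units (cm for positions, degrees for angles).
#' @param n_trials number of trials K.
#' @param seed integer RNG seed.
#'
#' @return A config object (`harmonic_config`, `fabric_chain_config`,
#'   `pattern_config` or `reach_config`).
#' @name synth_config
NULL

cfg_check <- function(ok, field, what) {
  if (!isTRUE(ok))
    stop(sprintf("invalid configuration: field '%s' %s", field, what),
         call. = FALSE)
}

#' @rdname synth_config
#' @export
harmonic_config <- function(omega = 0.63 * pi, radius = 10, sample_rate = 40,
                            duration = 5, phase_mode = c("random", "fixed"),
                            phase = 0, lead_in = 0, noise_sd = 0,
                            n_trials = 50, seed = 1L) {
  phase_mode <- match.arg(phase_mode)
  cfg_check(is.numeric(omega) && omega > 0, "omega", "must be > 0")
  cfg_check(is.numeric(radius) && radius > 0, "radius", "must be > 0")
  cfg_check(is.numeric(sample_rate) && sample_rate > 0, "sample_rate", "must be > 0")
  cfg_check(is.numeric(duration) && duration > 0, "duration", "must be > 0")
  cfg_check(is.numeric(lead_in) && lead_in >= 0, "lead_in", "must be >= 0")
  cfg_check(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd", "must be >= 0")
  cfg_check(is.numeric(n_trials) && n_trials >= 1, "n_trials", "must be >= 1")
  structure(list(omega = omega, radius = radius, sample_rate = sample_rate,
                 duration = duration, phase_mode = phase_mode, phase = phase,
                 lead_in = lead_in, noise_sd = noise_sd,
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "harmonic_config")
}

#' @rdname synth_config
#' @param n_links number of lumped fabric segments in the chain.
#' @param stiffness per-link restoring constant (s^-2, unit link masses).
#' @param damping per-link damping constant (s^-1).
#' @param link_length nominal link length in cm (metadata only; the chain is
#'   expressed in displacements relative to rest).
#' @param tap_positions link indices carrying virtual sensors.
#' @param gain scale applied to the driving (rigid) signal at the chain root.
#' @export
fabric_chain_config <- function(n_links = 3, stiffness = 12, damping = 4,
                                link_length = 10, tap_positions = n_links,
                                gain = 3) {
  cfg_check(is.numeric(n_links) && n_links >= 1, "n_links", "must be >= 1")
  cfg_check(is.numeric(stiffness) && stiffness > 0, "stiffness", "must be > 0")
  cfg_check(is.numeric(damping) && damping >= 0, "damping", "must be >= 0")
  cfg_check(is.numeric(link_length) && link_length > 0, "link_length", "must be > 0")
  tap_positions <- as.integer(tap_positions)
  cfg_check(length(tap_positions) >= 1 && all(tap_positions >= 1) &&
              all(tap_positions <= n_links),
            "tap_positions", "must be indices within 1..n_links")
  cfg_check(is.numeric(gain) && gain > 0, "gain", "must be > 0")
  structure(list(n_links = as.integer(n_links), stiffness = stiffness,
                 damping = damping, link_length = link_length,
                 tap_positions = tap_positions, gain = gain),
            class = "fabric_chain_config")
}

#' @rdname synth_config
#' @param shape `"linear_ptp"`, `"curved_ptp"` or `"circular"`.
#' @param delta_theta rotation of the class-2 path about the shared start
#'   point, in degrees (0..90).
#' @param speed peak moving velocity along the path, cm/s.
#' @param path_scale characteristic path extent in cm (point-to-point
#'   distance, or circle diameter for `"circular"`).
#' @export
pattern_config <- function(shape = c("linear_ptp", "curved_ptp", "circular"),
                           delta_theta = 10, speed = 25, path_scale = 20,
                           sample_rate = 40, duration = 5, noise_sd = 0,
                           n_trials = 50, seed = 1L) {
  if (is.character(shape) && length(shape) == 1L &&
      !shape %in% c("linear_ptp", "curved_ptp", "circular"))
    stop(sprintf("invalid configuration: field 'shape' unknown shape '%s'", shape),
         call. = FALSE)
  shape <- match.arg(shape)
  cfg_check(is.numeric(delta_theta) && delta_theta >= 0 && delta_theta <= 90,
            "delta_theta", "must lie in [0, 90] degrees")
  cfg_check(is.numeric(speed) && speed > 0, "speed", "must be > 0")
  cfg_check(is.numeric(path_scale) && path_scale > 0, "path_scale", "must be > 0")
  cfg_check(is.numeric(sample_rate) && sample_rate > 0, "sample_rate", "must be > 0")
  cfg_check(is.numeric(duration) && duration > 0, "duration", "must be > 0")
  cfg_check(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd", "must be >= 0")
  cfg_check(is.numeric(n_trials) && n_trials >= 1, "n_trials", "must be >= 1")
  structure(list(shape = shape, delta_theta = delta_theta, speed = speed,
                 path_scale = path_scale, sample_rate = sample_rate,
                 duration = duration, noise_sd = noise_sd,
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "pattern_config")
}

#' @rdname synth_config
#' @param arc_radius start-to-target distance in cm (all targets lie on this
#'   arc).
#' @param target_angles angular positions of the configured target buttons,
#'   degrees from straight ahead; adjacent targets are 5 degrees apart by
#'   default.
#' @param delta_theta angular separation between the two compared targets
#'   (degrees); must be representable as a difference of `target_angles`.
#' @param move_duration duration of the reach itself (s).
#' @param start_jitter_sd per-trial start-position jitter (cm).
#' @export
reach_config <- function(arc_radius = 45, target_angles = c(0, 5, 10, 15),
                         delta_theta = 5, duration = 2, move_duration = 1,
                         lead_in = 0.3, sample_rate = 40, noise_sd = 0.2,
                         start_jitter_sd = 0.2, n_trials = 50, seed = 1L) {
  cfg_check(is.numeric(arc_radius) && arc_radius > 0, "arc_radius", "must be > 0")
  cfg_check(is.numeric(duration) && duration > 0, "duration", "must be > 0")
  cfg_check(is.numeric(move_duration) && move_duration > 0 &&
              move_duration + lead_in <= duration,
            "move_duration", "must be > 0 with lead_in + move_duration <= duration")
  cfg_check(is.numeric(sample_rate) && sample_rate > 0, "sample_rate", "must be > 0")
  cfg_check(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd", "must be >= 0")
  cfg_check(is.numeric(n_trials) && n_trials >= 1, "n_trials", "must be >= 1")
  d <- outer(target_angles, target_angles, "-")
  if (!any(abs(abs(d) - delta_theta) < 1e-9))
    stop("invalid configuration: field 'delta_theta' is not a difference of 'target_angles'",
         call. = FALSE)
  structure(list(arc_radius = arc_radius, target_angles = target_angles,
                 delta_theta = delta_theta, duration = duration,
                 move_duration = move_duration, lead_in = lead_in,
                 sample_rate = sample_rate, noise_sd = noise_sd,
                 start_jitter_sd = start_jitter_sd,
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "reach_config")
}

wrap_deg <- function(a) ((a + 180) %% 360) - 180

#' Generate scotch-yoke harmonic trajectories
#'
#' Emulates the crank-and-yoke rig: the horizontal position of the yoke is
#' simple harmonic motion `radius * cos(omega * t + phi0)` and the yaw
#' channel is the crank angle (atan2 of the crank position, degrees,
#' wrapped to (-180, 180]). An optional rest period of `lead_in` seconds is
#' prepended (yoke held at its starting position) so that onset detection
#' has a quiet baseline. I.i.d. Gaussian noise of `noise_sd` is added to
#' every channel.
#'
#' @param cfg a [harmonic_config()].
#' @return A `trajectory_set` with channels `pos_x` (cm) and `yaw` (deg) and
#'   attribute `"phases"` holding the per-trial starting phase phi0.
#' @export
gen_harmonic <- function(cfg) {
  stopifnot(inherits(cfg, "harmonic_config"))
  v_move <- round(cfg$sample_rate * cfg$duration)
  v_lead <- round(cfg$sample_rate * cfg$lead_in)
  with_seed(cfg$seed, {
    phases <- if (cfg$phase_mode == "random")
      stats::runif(cfg$n_trials, 0, 2 * pi) else rep(cfg$phase, cfg$n_trials)
    trials <- vector("list", cfg$n_trials)
    for (k in seq_len(cfg$n_trials)) {
      t_move <- (seq_len(v_move) - 1) / cfg$sample_rate
      theta <- cfg$omega * t_move + phases[k]
      x <- cfg$radius * cos(theta)
      yaw <- wrap_deg(atan2(sin(theta), cos(theta)) * 180 / pi)
      if (v_lead > 0) {
        x <- c(rep(x[1L], v_lead), x)
        yaw <- c(rep(yaw[1L], v_lead), yaw)
      }
      y <- cbind(pos_x = x, yaw = yaw)
      trials[[k]] <- y
    }
    clean <- trials
    if (cfg$noise_sd > 0)
      trials <- lapply(trials, function(y)
        y + matrix(stats::rnorm(length(y), 0, cfg$noise_sd), nrow(y)))
    out <- trajectory_set(trials, cfg$sample_rate,
                          channels = c("pos_x", "yaw"),
                          roles = c("rigid", "rigid"),
                          units = c("cm", "deg"))
    attr(out, "phases") <- phases
    attr(out, "clean") <- clean
    attr(out, "config") <- cfg
    out
  })
}

# Chain coupling matrices for n unit-mass links hung off a driven root:
# x''_j = k (x_{j-1} - 2 x_j + x_{j+1}) + c (same in velocities), free end.
chain_laplacian <- function(n) {
  L <- diag(2, n)
  if (n >= 2) {
    for (j in seq_len(n - 1)) { L[j, j + 1] <- -1; L[j + 1, j] <- -1 }
    L[n, n] <- 1
  } else L[1, 1] <- 1
  L
}

#' Steady-state frequency response of the fabric chain
#'
#' Closed-form transfer function of the linear mass-spring-damper chain from
#' the root displacement to each tap displacement at angular frequency
#' `omega`: solves `(-omega^2 I + i omega c L + k L) X = (k + i omega c) e1 U`.
#' The `gain` of the config multiplies the root drive and therefore the
#' response.
#'
#' @param chain a [fabric_chain_config()].
#' @param omega angular frequency (rad/s), vectorised.
#' @return A matrix of complex amplitude ratios, `length(omega)` rows by
#'   `length(tap_positions)` columns.
#' @export
chain_frequency_response <- function(chain, omega) {
  stopifnot(inherits(chain, "fabric_chain_config"))
  n <- chain$n_links
  L <- chain_laplacian(n)
  out <- matrix(NA_complex_, length(omega), length(chain$tap_positions))
  for (w in seq_along(omega)) {
    om <- omega[w]
    A <- -om^2 * diag(n) + (1i * om * chain$damping + chain$stiffness) * L
    f <- numeric(n)
    f[1] <- 1
    x <- solve(A, (chain$stiffness + 1i * om * chain$damping) * f)
    out[w, ] <- chain$gain * x[chain$tap_positions]
  }
  out
}

#' Drive the fabric chain with a rigid trajectory set
#'
#' The fabric proxy: a chain of lumped unit masses joined by springs
#' (`stiffness`) and dampers (`damping`), its root prescribed to follow
#' `gain` times a rigid channel. Integrated with `deSolve::lsoda` at the
#' rigid set's sample times; each tap position yields one output channel.
#' The chain starts at rest at the driver's initial value, so a motionless
#' driver produces identically zero deviation.
#'
#' @param rigid a `trajectory_set`; `channel` selects the driving channel.
#' @param chain a [fabric_chain_config()].
#' @param channel index of the driving channel in `rigid`.
#' @param noise_sd additive Gaussian sensor noise on the fabric channels.
#' @param seed RNG seed for the noise.
#' @return A `trajectory_set` with one `fabric` channel per tap position.
#' @export
gen_fabric_chain <- function(rigid, chain, channel = 1L, noise_sd = 0,
                             seed = 1L) {
  stopifnot(inherits(rigid, "trajectory_set"),
            inherits(chain, "fabric_chain_config"))
  if (length(rigid$trials) == 0L)
    stop("'rigid' must contain at least one trial", call. = FALSE)
  n <- chain$n_links
  L <- chain_laplacian(n)
  K_mat <- chain$stiffness * L
  C_mat <- chain$damping * L
  e1 <- c(1, numeric(n - 1))
  deriv <- function(t, state, parms) {
    x <- state[seq_len(n)]
    v <- state[n + seq_len(n)]
    u <- parms$u(t)
    du <- parms$du(t)
    acc <- -as.vector(K_mat %*% x) - as.vector(C_mat %*% v) +
      (chain$stiffness * u + chain$damping * du) * e1
    list(c(v, acc))
  }
  fs <- rigid$sample_rate
  # the chain is driven by the physical motion: use the pre-noise signal
  # when the generator provides it (sensor noise belongs at each sensor,
  # not in the mechanics)
  driver <- attr(rigid, "clean")
  if (is.null(driver)) driver <- rigid$trials
  trials <- lapply(driver, function(y) {
    vlen <- nrow(y)
    if (vlen < 2L) stop("trials too short to drive the chain", call. = FALSE)
    tt <- (seq_len(vlen) - 1) / fs
    drv <- chain$gain * y[, channel]
    uf <- stats::splinefun(tt, drv, method = "fmm")
    parms <- list(u = uf, du = function(t) uf(t, deriv = 1))
    init <- c(rep(drv[1L], n), numeric(n))
    sol <- deSolve::lsoda(init, tt, deriv, parms, rtol = 1e-9, atol = 1e-9)
    taps <- sol[, 1 + chain$tap_positions, drop = FALSE]
    colnames(taps) <- paste0("fab", chain$tap_positions)
    taps
  })
  out <- trajectory_set(trials, fs,
                        channels = paste0("fab", chain$tap_positions),
                        roles = rep("fabric", length(chain$tap_positions)),
                        label = rigid$label)
  attr(out, "clean") <- out$trials
  if (noise_sd > 0) {
    out$trials <- with_seed(seed, lapply(out$trials, function(y)
      y + matrix(stats::rnorm(length(y), 0, noise_sd), nrow(y))))
  }
  attr(out, "chain") <- chain
  out
}

# Minimum-jerk normalised position profile s(tau) on [0,1].
min_jerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

# Mean path of a pattern shape: T x 2 positions for arclength fractions s.
pattern_path <- function(shape, s, scale) {
  switch(shape,
    linear_ptp = cbind(x = numeric(length(s)), y = scale * s),
    curved_ptp = {
      # quadratic Bezier start (0,0) -> (0,scale) bowed sideways
      p0 <- c(0, 0); p1 <- c(0.4 * scale, 0.5 * scale); p2 <- c(0, scale)
      cbind(x = (1 - s)^2 * p0[1] + 2 * (1 - s) * s * p1[1] + s^2 * p2[1],
            y = (1 - s)^2 * p0[2] + 2 * (1 - s) * s * p1[2] + s^2 * p2[2])
    },
    circular = {
      r <- scale / 2
      ang <- 2 * pi * s
      cbind(x = r * sin(ang), y = r * (1 - cos(ang)))
    },
    stop(sprintf("invalid configuration: field 'shape' unknown shape '%s'", shape),
         call. = FALSE))
}

# Rotate xy channels about 'origin' by theta degrees; add theta to yaw.
rotate_about_start <- function(y, theta_deg, origin = c(0, 0),
                               xy = c(1L, 2L), yaw = 3L) {
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xy0 <- sweep(y[, xy, drop = FALSE], 2, origin)
  y[, xy] <- sweep(xy0 %*% t(R), 2, origin, "+")
  if (!is.na(yaw) && yaw <= ncol(y)) y[, yaw] <- y[, yaw] + theta_deg
  y
}

#' Generate a pair of rotated point-to-point movement classes
#'
#' Class 1 traces the configured shape with a minimum-jerk arclength profile
#' at the given peak speed, then holds at the endpoint for the rest of the
#' trial. Class 2 is exactly class 1's path rotated by `delta_theta` about
#' the shared start point (noise is added after rotation). Channels are the
#' planar position (cm) and the path tangent angle (deg, unwrapped).
#'
#' @param cfg a [pattern_config()].
#' @return A list with elements `class1` and `class2`, each a
#'   `trajectory_set` labelled 1 and 2; attribute `"move_duration"` holds
#'   the traversal time in seconds.
#' @export
gen_pattern <- function(cfg) {
  stopifnot(inherits(cfg, "pattern_config"))
  vlen <- round(cfg$sample_rate * cfg$duration)
  tt <- (seq_len(vlen) - 1) / cfg$sample_rate
  # path length by fine quadrature of the mean path
  sf <- seq(0, 1, length.out = 2001)
  pf <- pattern_path(cfg$shape, sf, cfg$path_scale)
  seg <- sqrt(diff(pf[, 1])^2 + diff(pf[, 2])^2)
  plen <- sum(seg)
  # minimum-jerk peak speed is 15/8 * L / T  =>  T from the configured peak
  t_move <- (15 / 8) * plen / cfg$speed
  if (t_move > cfg$duration)
    stop("invalid configuration: field 'speed' too low for 'duration'",
         call. = FALSE)
  arc <- c(0, cumsum(seg)) / plen
  s_of_arc <- stats::approxfun(arc, sf, rule = 2)
  s_traj <- s_of_arc(min_jerk(tt / t_move))
  base <- pattern_path(cfg$shape, s_traj, cfg$path_scale)
  # tangent angle along the path, unwrapped
  dx <- c(diff(base[, 1]), 0); dy <- c(diff(base[, 2]), 0)
  yaw <- atan2(dy, dx) * 180 / pi
  still <- sqrt(dx^2 + dy^2) < 1e-9
  for (i in seq_along(yaw)) if (still[i] && i > 1) yaw[i] <- yaw[i - 1]
  yaw <- unwrap_deg_vec(yaw)
  mean_path <- cbind(pos_x = base[, 1], pos_y = base[, 2], yaw = yaw)
  mk_set <- function(theta, label, seed) {
    path <- if (theta != 0) rotate_about_start(mean_path, theta) else mean_path
    with_seed(seed, {
      trials <- lapply(seq_len(cfg$n_trials), function(k) {
        y <- path
        if (cfg$noise_sd > 0)
          y <- y + matrix(stats::rnorm(length(y), 0, cfg$noise_sd), nrow(y))
        y
      })
      out <- trajectory_set(trials, cfg$sample_rate,
                            channels = c("pos_x", "pos_y", "yaw"),
                            roles = rep("rigid", 3), label = label,
                            units = c("cm", "cm", "deg"))
      attr(out, "move_duration") <- t_move
      attr(out, "mean_path") <- path
      attr(out, "clean") <- rep(list(path), cfg$n_trials)
      out
    })
  }
  list(class1 = mk_set(0, 1L, cfg$seed),
       class2 = mk_set(cfg$delta_theta, 2L, cfg$seed + 1L))
}

#' Generate minimum-jerk reaching movements to two arc targets
#'
#' Targets sit on an arc of `arc_radius` cm centred on the start point, with
#' adjacent configured targets 5 degrees apart by default. The two compared
#' targets are the pair of `target_angles` separated by `delta_theta`. Each
#' trial rests at the (jittered) start for `lead_in` seconds, reaches the
#' target along a straight minimum-jerk profile in `move_duration` seconds,
#' and holds there. Wrist channels are the smooth path plus noise; sleeve
#' channels are the fabric chain driven by the wrist channels.
#'
#' @param cfg a [reach_config()].
#' @param chain a [fabric_chain_config()] for the sleeve proxy.
#' @return A list with `target_a` and `target_b`, each a `trajectory_set`
#'   with channels `wrist_x`, `wrist_y` (rigid) and `sleeve_x`, `sleeve_y`
#'   (fabric); attribute `"targets"` holds the two target coordinates.
#' @export
gen_reaching <- function(cfg, chain = fabric_chain_config()) {
  stopifnot(inherits(cfg, "reach_config"))
  pair <- NULL
  for (i in seq_along(cfg$target_angles))
    for (j in seq_along(cfg$target_angles))
      if (is.null(pair) &&
          abs(abs(cfg$target_angles[j] - cfg$target_angles[i]) -
              cfg$delta_theta) < 1e-9)
        pair <- c(cfg$target_angles[i], cfg$target_angles[j])
  if (is.null(pair))
    stop("invalid configuration: field 'delta_theta' is not a difference of 'target_angles'",
         call. = FALSE)
  vlen <- round(cfg$sample_rate * cfg$duration)
  tt <- (seq_len(vlen) - 1) / cfg$sample_rate
  prof <- min_jerk((tt - cfg$lead_in) / cfg$move_duration)
  target_xy <- function(ang_deg)
    cfg$arc_radius * c(sin(ang_deg * pi / 180), cos(ang_deg * pi / 180))
  mk <- function(ang, label, seed) {
    tgt <- target_xy(ang)
    with_seed(seed, {
      clean <- lapply(seq_len(cfg$n_trials), function(k) {
        start <- stats::rnorm(2, 0, cfg$start_jitter_sd)
        cbind(wrist_x = start[1] + (tgt[1] - start[1]) * prof,
              wrist_y = start[2] + (tgt[2] - start[2]) * prof)
      })
      trials <- if (cfg$noise_sd > 0)
        lapply(clean, function(y)
          y + matrix(stats::rnorm(length(y), 0, cfg$noise_sd), nrow(y)))
      else clean
      out <- trajectory_set(trials, cfg$sample_rate,
                            channels = c("wrist_x", "wrist_y"),
                            roles = c("rigid", "rigid"), label = label,
                            units = c("cm", "cm"))
      attr(out, "clean") <- clean
      out
    })
  }
  sets <- list(target_a = mk(pair[1], 1L, cfg$seed),
               target_b = mk(pair[2], 2L, cfg$seed + 1L))
  out <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    fx <- gen_fabric_chain(s, chain, channel = 1L,
                           noise_sd = cfg$noise_sd,
                           seed = cfg$seed + 10L + i)
    fy <- gen_fabric_chain(s, chain, channel = 2L,
                           noise_sd = cfg$noise_sd,
                           seed = cfg$seed + 20L + i)
    trials <- Map(function(w, a, b)
      cbind(w, sleeve_x = a[, 1], sleeve_y = b[, 1]),
      s$trials, fx$trials, fy$trials)
    ts <- trajectory_set(trials, cfg$sample_rate,
                         channels = c("wrist_x", "wrist_y", "sleeve_x", "sleeve_y"),
                         roles = c("rigid", "rigid", "fabric", "fabric"),
                         label = s$label,
                         units = rep("cm", 4))
    ts
  })
  names(out) <- c("target_a", "target_b")
  attr(out, "targets") <- cbind(a = target_xy(pair[1]), b = target_xy(pair[2]))
  attr(out, "config") <- cfg
  out
}

#' Inject missing-sample gaps into a trajectory set
#'
#' Marks interior samples missing (`NA`) to emulate tracking dropouts: each
#' interior sample is flagged independently with probability `gap_rate`, and
#' runs of flagged samples longer than `max_gap` are truncated to `max_gap`.
#' The first and last samples of a trial are never removed, so spline gap
#' filling always has anchored endpoints.
#'
#' @param trajs a `trajectory_set`.
#' @param gap_rate per-sample missingness probability, in \[0, 0.5).
#' @param max_gap longest permitted run of consecutive missing samples.
#' @param seed RNG seed.
#' @return The set with `NA` in flagged samples (whole rows are dropped
#'   across channels, as when a tracker loses the sensor).
#' @export
inject_gaps <- function(trajs, gap_rate, max_gap = 5L, seed = 1L) {
  stopifnot(inherits(trajs, "trajectory_set"))
  if (!is.numeric(gap_rate) || gap_rate < 0 || gap_rate >= 0.5)
    stop("invalid configuration: field 'gap_rate' must lie in [0, 0.5)",
         call. = FALSE)
  if (max_gap < 1L)
    stop("invalid configuration: field 'max_gap' must be >= 1", call. = FALSE)
  if (gap_rate == 0) return(trajs)
  out <- trajs
  out$trials <- with_seed(seed, lapply(trajs$trials, function(y) {
    vlen <- nrow(y)
    if (vlen <= 2L) return(y)
    flag <- c(FALSE, stats::runif(vlen - 2L) < gap_rate, FALSE)
    r <- rle(flag)
    over <- which(r$values & r$lengths > max_gap)
    if (length(over)) {
      ends <- cumsum(r$lengths)
      for (i in over) {
        run_start <- ends[i] - r$lengths[i] + 1L
        flag[(run_start + max_gap):ends[i]] <- FALSE
      }
    }
    y[flag, ] <- NA_real_
    y
  }))
  out
}
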