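#' Fit a left-to-right hidden Markov model by Baum-Welch
#'
#' Fits the time-indexed movement model: a left-to-right HMM with one state
#' per time step (N = V), diagonal-Gaussian emissions over the M sensor
#' channels, and a banded transition matrix in which advancing to the next
#' state is far more probable than remaining (states represent successive
#' time steps). Estimation alternates the forward-backward E-step with
#' closed-form M-step updates of the initial distribution, emission means
#' and per-dimension variances until the total training log-likelihood
#' converges. All recursions run in scaled/log arithmetic, so models with
#' hundreds of states do not underflow.
#'
#' By default the transition band is left at its initial values and only
#' pi, means and variances are re-estimated; set `update_trans = TRUE` to
#' re-estimate the band from the pair posteriors as well.
#'
#' @param x training data: a `trajectory_set` or a list of equal-length
#'   V x M trial matrices.
#' @param max_iter maximum EM iterations; `0` returns the initial model.
#' @param rel_tol relative log-likelihood change declaring convergence.
#' @param variance_floor smallest admissible emission variance (squared
#'   channel units).
#' @param self_prob initial self-transition probability; the remaining mass
#'   advances along the band (progression dominates in a time-indexed
#'   model).
#' @param band_width number of forward states reachable in one step (1 =
#'   self + successor; larger values allow skips).
#' @param update_trans re-estimate the transition band in the M-step.
#' @param seed RNG seed for the initialisation (which training trial seeds
#'   the state means).
#' @param init optional model from [lrhmm_init()] to start from.
#'
#' @return An object of class `lrhmm` with components `n_states`,
#'   `n_channels`, `pi`, `trans_band` (N x (band_width+1); column d+1 holds
#'   a\[i, i+d\]), `means`, `variances` (both N x M), `variance_floor`,
#'   `band_width`, `channels`, and `fit` (log-likelihood trace, iteration
#'   count, stop reason, zero-occupancy states, seed).
#' @seealso [forward_loglik()], [viterbi()], [classify_motion()],
#'   [cross_fitness()]
#' @export
lrhmm <- function(x, max_iter = 50L, rel_tol = 1e-6, variance_floor = 1e-6,
                  self_prob = 0.1, band_width = 1L, update_trans = FALSE,
                  seed = 1L, init = NULL) {
  trials <- as_trial_list(x)
  if (is.null(init))
    init <- lrhmm_init(x, seed = seed, variance_floor = variance_floor,
                       self_prob = self_prob, band_width = band_width)
  model <- init
  model$update_trans <- isTRUE(update_trans)
  kk <- length(trials)
  trace <- numeric(0)
  stop_reason <- "max_iter"
  zero_states <- integer(0)
  iter <- 0L
  yslices <- make_yslices(trials)
  while (iter < max_iter) {
    iter <- iter + 1L
    es <- lr_estep_all(model, trials, yslices)
    if (!is.finite(es$loglik))
      stop(sprintf("numerical failure: non-finite likelihood at iteration %d",
                   iter), call. = FALSE)
    trace <- c(trace, es$loglik)
    if (length(trace) >= 2L) {
      prev <- trace[length(trace) - 1L]
      if (abs(es$loglik - prev) < rel_tol * (abs(prev) + rel_tol)) {
        stop_reason <- "converged"
        break
      }
    }
    up <- lr_mstep(model, es, kk)
    model <- up$model
    zero_states <- union(zero_states, up$zero_states)
  }
  # on convergence the loop breaks before the M-step, so the last traced
  # log-likelihood already belongs to the returned parameters
  final_ll <- if (stop_reason == "converged") trace[length(trace)]
              else sum(vapply(trials, function(y) forward_loglik(model, y),
                              numeric(1)))
  model$fit <- list(loglik = final_ll,
                    trace = if (stop_reason == "converged") trace
                            else c(trace, final_ll),
                    iterations = iter, stop_reason = stop_reason,
                    zero_occupancy_states = sort(zero_states),
                    n_trials = kk, seed = as.integer(seed))
  model
}

as_trial_list <- function(x) {
  trials <- if (inherits(x, "trajectory_set")) x$trials
            else if (is.list(x)) lapply(x, as.matrix)
            else list(as.matrix(x))
  if (length(trials) == 0L) stop("no training trials", call. = FALSE)
  v <- unique(vapply(trials, nrow, 1L))
  if (length(v) != 1L)
    stop("training trials must all have the same length V", call. = FALSE)
  if (anyNA(unlist(trials, use.names = FALSE)))
    stop("training data contain missing samples; run fill_gaps() first",
         call. = FALSE)
  trials
}

#' Initialise left-to-right HMM parameters from training data
#'
#' One state per time step (N = V). The state means are copied from one
#' randomly chosen training trial (state i takes that trial's sample i);
#' variances are the per-step across-trial empirical variances, floored;
#' the initial distribution concentrates `1 - self_prob` mass on state 1;
#' the transition band gives each state `self_prob` of remaining and splits
#' the rest over its successors, with the last state absorbing.
#'
#' @inheritParams lrhmm
#' @return An unfitted `lrhmm` object.
#' @export
lrhmm_init <- function(x, seed = 1L, variance_floor = 1e-6, self_prob = 0.1,
                       band_width = 1L) {
  trials <- as_trial_list(x)
  kk <- length(trials)
  n <- nrow(trials[[1L]])
  m <- ncol(trials[[1L]])
  band_width <- as.integer(band_width)
  if (band_width < 1L) stop("'band_width' must be >= 1", call. = FALSE)
  ref <- with_seed(seed, sample.int(kk, 1L))
  means <- trials[[ref]]
  dimnames(means) <- NULL
  if (kk >= 2L) {
    arr <- array(unlist(trials, use.names = FALSE), dim = c(n, m, kk))
    vars <- apply(arr, c(1, 2), stats::var)
  } else {
    vars <- matrix(0, n, m)
  }
  vars <- pmax(vars, variance_floor)
  eps <- self_prob
  pi0 <- if (n == 1L) 1 else c(1 - eps, rep(eps / (n - 1), n - 1))
  band <- matrix(0, n, band_width + 1L)
  for (i in seq_len(n)) {
    succ <- seq.int(i + 1L, length.out = band_width)
    succ <- succ[succ <= n]
    if (length(succ) == 0L) {
      band[i, 1L] <- 1            # absorbing final state
    } else {
      band[i, 1L] <- eps
      band[i, 1L + (succ - i)] <- (1 - eps) / length(succ)
    }
  }
  ch <- colnames(trials[[1L]])
  if (is.null(ch)) ch <- paste0("ch", seq_len(m))
  structure(
    list(n_states = n, n_channels = m, pi = pi0, trans_band = band,
         band_width = band_width, means = means, variances = vars,
         variance_floor = variance_floor, update_trans = FALSE,
         channels = ch, fit = NULL),
    class = "lrhmm")
}

# Per-step observation slices: yslices[[v]] is the K x M matrix of every
# trial's sample v (precomputed once per fit).
make_yslices <- function(trials) {
  kk <- length(trials)
  m <- ncol(trials[[1L]])
  vlen <- nrow(trials[[1L]])
  arr <- array(unlist(trials, use.names = FALSE), dim = c(vlen, m, kk))
  out <- lapply(seq_len(vlen), function(v) matrix(aperm(arr[v, , , drop = FALSE],
                                                        c(3L, 2L, 1L)), kk, m))
  attr(out, "yall") <- do.call(rbind, trials)
  out
}

# Exact column maxima of a matrix.
colmax_mat <- function(x) apply(x, 2L, max)

# N x V matrix of per-state diagonal-Gaussian log-densities for a trial.
emission_logmat <- function(model, y) {
  y <- as.matrix(y)
  if (ncol(y) != model$n_channels)
    stop("observation has wrong number of channels", call. = FALSE)
  if (!all(is.finite(y)))
    stop("non-finite observation values", call. = FALSE)
  vars <- pmax(model$variances, model$variance_floor)
  p <- 1 / vars
  a1 <- p %*% t(y * y)
  a2 <- (model$means * p) %*% t(y)
  const <- rowSums(log(2 * pi * vars)) + rowSums(model$means^2 * p)
  -0.5 * (a1 - 2 * a2 + const)
}

#' Per-state Gaussian emission log-density
#'
#' The log-density of an M-channel observation under state `i`'s diagonal
#' Gaussian: the sum over channels of univariate normal log-densities, with
#' variances clamped at the model's floor.
#'
#' @param model an `lrhmm` object.
#' @param state state index (1..N).
#' @param y numeric observation vector of length M.
#' @return The log-density (scalar).
#' @export
emission_logdensity <- function(model, state, y) {
  if (state < 1L || state > model$n_states)
    stop("state index out of range", call. = FALSE)
  y <- as.numeric(y)
  if (length(y) != model$n_channels || !all(is.finite(y)))
    stop("observation must be a finite vector of length M", call. = FALSE)
  v <- pmax(model$variances[state, ], model$variance_floor)
  sum(stats::dnorm(y, model$means[state, ], sqrt(v), log = TRUE))
}

# Log-domain forward pass for scoring: returns the cumulative prefix
# log-likelihoods (length V). Pure log-sum-exp arithmetic, so even a
# grossly mismatched model yields its (very negative) finite likelihood
# instead of underflowing.
forward_pass_log <- function(model, y) {
  logB <- emission_logmat(model, y)
  n <- model$n_states
  vlen <- ncol(logB)
  lband <- log(model$trans_band)
  w <- model$band_width
  cum <- numeric(vlen)
  la <- log(model$pi) + logB[, 1L]
  cum[1L] <- logsumexp_vec(la)
  if (!is.finite(cum[1L]))
    stop("degenerate posterior: zero likelihood at time step 1", call. = FALSE)
  if (vlen >= 2L) for (v in 2:vlen) {
    lanew <- la + lband[, 1L]
    if (n >= 2L) for (d in seq_len(w)) {
      if (d >= n) break
      idx <- seq_len(n - d)
      lanew[idx + d] <- logaddexp(lanew[idx + d], la[idx] + lband[idx, d + 1L])
    }
    la <- lanew + logB[, v]
    cum[v] <- logsumexp_vec(la)
    if (!is.finite(cum[v]))
      stop(sprintf("degenerate posterior: zero likelihood at time step %d", v),
           call. = FALSE)
  }
  cum
}

logaddexp <- function(x, y) {
  m <- pmax(x, y)
  d <- -abs(x - y)
  out <- m + log1p(exp(d))
  out[m == -Inf] <- -Inf
  out
}

logsumexp_vec <- function(x) {
  m <- max(x)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(x - m)))
}

# Scaled forward pass. Returns cumulative prefix log-likelihoods (length V)
# and, if want_alpha, the per-step normalised alpha-hat (N x V).
forward_pass <- function(model, y, want_alpha = FALSE) {
  logB <- emission_logmat(model, y)
  n <- model$n_states
  vlen <- ncol(logB)
  band <- model$trans_band
  w <- model$band_width
  cum <- numeric(vlen)
  alpha_hat <- if (want_alpha) matrix(0, n, vlen) else NULL
  mx <- max(logB[, 1L])
  a <- model$pi * exp(logB[, 1L] - mx)
  s <- sum(a)
  if (s <= 0 || !is.finite(s))
    stop("degenerate posterior: all forward mass vanished at time step 1",
         call. = FALSE)
  cum[1L] <- log(s) + mx
  a <- a / s
  if (want_alpha) alpha_hat[, 1L] <- a
  if (vlen >= 2L) for (v in 2:vlen) {
    anew <- a * band[, 1L]
    if (n >= 2L) for (d in seq_len(w)) {
      if (d >= n) break
      idx <- seq_len(n - d)
      anew[idx + d] <- anew[idx + d] + a[idx] * band[idx, d + 1L]
    }
    mx <- max(logB[, v])
    anew <- anew * exp(logB[, v] - mx)
    s <- sum(anew)
    if (s <= 0 || !is.finite(s))
      stop(sprintf("degenerate posterior: all forward mass vanished at time step %d", v),
           call. = FALSE)
    cum[v] <- cum[v - 1L] + log(s) + mx
    a <- anew / s
    if (want_alpha) alpha_hat[, v] <- a
  }
  list(cumloglik = cum, alpha_hat = alpha_hat, logB = logB)
}

#' Forward-algorithm log-likelihood of a trajectory prefix
#'
#' Computes `log P(y[1..v] | model)` by the scaled forward recursion,
#' summing the forward variables over all states at step `v`. The full
#' N-state model scores a prefix by terminating the forward sum at `v`; the
#' model is never truncated. The banded transition structure makes the cost
#' O(N v), not O(N^2 v).
#'
#' @param model an `lrhmm` object.
#' @param y a V x M trial matrix (or longer; only the prefix is used).
#' @param v prefix length in samples (default: all rows of `y`).
#' @return The prefix log-likelihood (scalar).
#' @export
forward_loglik <- function(model, y, v = NULL) {
  y <- as.matrix(y)
  if (is.null(v)) v <- nrow(y)
  if (v < 1L || v > nrow(y))
    stop("prefix length 'v' out of range", call. = FALSE)
  forward_pass_log(model, y[seq_len(v), , drop = FALSE])[v]
}

#' Cumulative prefix log-likelihoods for all prefix lengths
#'
#' One forward sweep returning `log P(y[1..v] | model)` for every
#' `v = 1..V`, so accuracy- and distance-versus-history curves need a
#' single pass per trial.
#'
#' @inheritParams forward_loglik
#' @return Numeric vector of length V.
#' @export
forward_cumloglik <- function(model, y) {
  forward_pass_log(model, as.matrix(y))
}

# Scaled backward pass; per-column scaling only (gamma/xi normalise it out).
backward_pass <- function(model, logB) {
  n <- model$n_states
  vlen <- ncol(logB)
  band <- model$trans_band
  w <- model$band_width
  beta_hat <- matrix(0, n, vlen)
  bshift <- apply(logB, 2, max)
  beta_hat[, vlen] <- 1
  if (vlen >= 2L) for (v in (vlen - 1L):1L) {
    bb <- exp(logB[, v + 1L] - bshift[v + 1L]) * beta_hat[, v + 1L]
    bnew <- band[, 1L] * bb
    if (n >= 2L) for (d in seq_len(w)) {
      if (d >= n) break
      idx <- seq_len(n - d)
      bnew[idx] <- bnew[idx] + band[idx, d + 1L] * bb[idx + d]
    }
    s <- sum(bnew)
    if (s <= 0 || !is.finite(s))
      stop(sprintf("degenerate posterior: all backward mass vanished at time step %d", v),
           call. = FALSE)
    beta_hat[, v] <- bnew / s
  }
  beta_hat
}

#' Forward-backward posterior tables for one trial
#'
#' The E-step quantities for a single trial: state posteriors `gamma`
#' (N x V, columns sum to 1), banded pair posteriors `xi` (N x (band_width
#' + 1) x (V - 1); `xi[i, d+1, v]` is the posterior of being in state i at
#' v and state i+d at v+1), and the trial log-likelihood.
#'
#' @param model an `lrhmm` object.
#' @param y a V x M trial matrix.
#' @return A list with `gamma`, `xi`, `loglik`.
#' @export
hmm_posteriors <- function(model, y) {
  y <- as.matrix(y)
  fw <- forward_pass(model, y, want_alpha = TRUE)
  beta_hat <- backward_pass(model, fw$logB)
  n <- model$n_states
  vlen <- ncol(fw$logB)
  w <- model$band_width
  band <- model$trans_band
  g_num <- fw$alpha_hat * beta_hat
  gsum <- colSums(g_num)
  if (any(gsum <= 0) || any(!is.finite(gsum))) {
    bad <- which(gsum <= 0 | !is.finite(gsum))[1L]
    stop(sprintf("degenerate posterior at time step %d", bad), call. = FALSE)
  }
  gamma <- sweep(g_num, 2, gsum, "/")
  xi <- array(0, dim = c(n, w + 1L, max(vlen - 1L, 0L)))
  if (vlen >= 2L) {
    bshift <- apply(fw$logB, 2, max)
    for (v in seq_len(vlen - 1L)) {
      bb <- exp(fw$logB[, v + 1L] - bshift[v + 1L]) * beta_hat[, v + 1L]
      sl <- matrix(0, n, w + 1L)
      sl[, 1L] <- fw$alpha_hat[, v] * band[, 1L] * bb
      if (n >= 2L) for (d in seq_len(w)) {
        if (d >= n) break
        idx <- seq_len(n - d)
        sl[idx, d + 1L] <- fw$alpha_hat[idx, v] * band[idx, d + 1L] * bb[idx + d]
      }
      tot <- sum(sl)
      if (tot <= 0 || !is.finite(tot))
        stop(sprintf("degenerate posterior at time step %d", v), call. = FALSE)
      xi[, , v] <- sl / tot
    }
  }
  list(gamma = gamma, xi = xi, loglik = fw$cumloglik[vlen])
}

# E-step over all trials, batched: the forward/backward recursions run on
# N x K matrices (states x trials) so the per-step work is a handful of
# vectorised operations regardless of the number of trials.
lr_estep_all <- function(model, trials, yslices = NULL) {
  n <- model$n_states
  m <- model$n_channels
  w <- model$band_width
  kk <- length(trials)
  vlen <- nrow(trials[[1L]])
  if (is.null(yslices)) yslices <- make_yslices(trials)
  yall <- attr(yslices, "yall")
  band <- model$trans_band
  # emission log-densities, dims (N, V, K), in one stacked matmul;
  # per-step scaled slices esc[[v]]
  logB <- array(emission_logmat(model, yall), dim = c(n, vlen, kk))
  esc <- vector("list", vlen)   # exp(logB - colmax), N x K, per step
  for (v in seq_len(vlen)) {
    sl <- matrix(logB[, v, ], n, kk)
    mx <- colmax_mat(sl)        # exact column maxima (max.col's tolerance
                                # mis-scales when log-densities span 1e9)
    esc[[v]] <- list(e = exp(sl - rep(mx, each = n)), mx = mx)
  }
  # scaled forward
  alpha <- array(0, dim = c(n, kk, vlen))
  cum <- matrix(0, kk, vlen)
  a <- model$pi * esc[[1L]]$e
  s <- colSums(a)
  if (any(s <= 0) || any(!is.finite(s)))
    stop("degenerate posterior: all forward mass vanished at time step 1",
         call. = FALSE)
  cum[, 1L] <- log(s) + esc[[1L]]$mx
  a <- a / rep(s, each = n)
  alpha[, , 1L] <- a
  if (vlen >= 2L) for (v in 2:vlen) {
    anew <- a * band[, 1L]
    if (n >= 2L) for (d in seq_len(w)) {
      if (d >= n) break
      idx <- seq_len(n - d)
      anew[idx + d, ] <- anew[idx + d, , drop = FALSE] +
        a[idx, , drop = FALSE] * band[idx, d + 1L]
    }
    anew <- anew * esc[[v]]$e
    s <- colSums(anew)
    if (any(s <= 0) || any(!is.finite(s)))
      stop(sprintf("degenerate posterior: all forward mass vanished at time step %d", v),
           call. = FALSE)
    cum[, v] <- cum[, v - 1L] + log(s) + esc[[v]]$mx
    a <- anew / rep(s, each = n)
    alpha[, , v] <- a
  }
  # scaled backward (per-step column scaling; cancels in gamma/xi)
  beta <- matrix(1, n, kk)
  occ <- numeric(n)
  mom1 <- matrix(0, n, m)
  mom2 <- matrix(0, n, m)
  pi1 <- numeric(n)
  xi_sum <- matrix(0, n, w + 1L)
  occ_head <- numeric(n)
  gam <- function(v, b) {
    gn <- matrix(alpha[, , v], n, kk) * b
    gs <- colSums(gn)
    if (any(gs <= 0) || any(!is.finite(gs)))
      stop(sprintf("degenerate posterior at time step %d", v), call. = FALSE)
    gn / rep(gs, each = n)
  }
  yv <- function(v) yslices[[v]]
  g <- gam(vlen, beta)
  occ <- occ + rowSums(g)
  y <- yv(vlen)
  mom1 <- mom1 + g %*% y
  mom2 <- mom2 + g %*% (y * y)
  if (vlen >= 2L) for (v in (vlen - 1L):1L) {
    bb <- esc[[v + 1L]]$e * beta           # b_{v+1} * beta_{v+1}, scaled
    bnew <- band[, 1L] * bb
    if (n >= 2L) for (d in seq_len(w)) {
      if (d >= n) break
      idx <- seq_len(n - d)
      bnew[idx, ] <- bnew[idx, , drop = FALSE] +
        band[idx, d + 1L] * bb[idx + d, , drop = FALSE]
    }
    s <- colSums(bnew)
    if (any(s <= 0) || any(!is.finite(s)))
      stop(sprintf("degenerate posterior: all backward mass vanished at time step %d", v),
           call. = FALSE)
    if (model$update_trans) {
      av <- matrix(alpha[, , v], n, kk)
      sl <- array(0, dim = c(n, w + 1L, kk))
      sl[, 1L, ] <- av * band[, 1L] * bb
      for (d in seq_len(w)) {
        if (d >= n) break
        idx <- seq_len(n - d)
        sl[idx, d + 1L, ] <- av[idx, , drop = FALSE] * band[idx, d + 1L] *
          bb[idx + d, , drop = FALSE]
      }
      tot <- apply(sl, 3L, sum)
      xi_sum <- xi_sum + rowSums(sweep(sl, 3L, tot, "/"), dims = 2L)
    }
    beta <- bnew / rep(s, each = n)
    g <- gam(v, beta)
    occ <- occ + rowSums(g)
    if (model$update_trans) occ_head <- occ_head + rowSums(g)
    y <- yv(v)
    mom1 <- mom1 + g %*% y
    mom2 <- mom2 + g %*% (y * y)
    if (v == 1L) pi1 <- rowSums(g)
  }
  if (vlen == 1L) pi1 <- rowSums(g)
  list(occ = occ, mom1 = mom1, mom2 = mom2, pi1 = pi1, xi_sum = xi_sum,
       occ_head = occ_head, loglik = sum(cum[, vlen]))
}

# M-step: closed-form updates of pi, means, variances (and optionally the
# transition band). States with zero occupancy keep their previous
# emission parameters.
lr_mstep <- function(model, es, kk) {
  ok <- es$occ > .Machine$double.xmin
  zero_states <- which(!ok)
  means <- model$means
  vars <- model$variances
  means[ok, ] <- es$mom1[ok, , drop = FALSE] / es$occ[ok]
  vars[ok, ] <- es$mom2[ok, , drop = FALSE] / es$occ[ok] -
    means[ok, , drop = FALSE]^2
  vars <- pmax(vars, model$variance_floor)
  model$means <- means
  model$variances <- vars
  model$pi <- es$pi1 / kk
  if (model$update_trans) {
    band <- model$trans_band
    upd <- es$occ_head > .Machine$double.xmin
    band[upd, ] <- es$xi_sum[upd, , drop = FALSE] / es$occ_head[upd]
    rs <- rowSums(band)
    band[rs > 0, ] <- band[rs > 0, , drop = FALSE] / rs[rs > 0]
    # structural zeros beyond the last state stay zero
    n <- model$n_states
    for (d in seq_len(model$band_width))
      if (d < n) band[(n - d + 1L):n, d + 1L] <- band[(n - d + 1L):n, d + 1L] * 0
    model$trans_band <- band
  }
  list(model = model, zero_states = zero_states)
}

#' Most likely state path by the Viterbi algorithm
#'
#' Log-domain dynamic program over the banded left-to-right transition
#' structure, with backtracking. Ties are broken toward the smaller state
#' index. Under the left-to-right topology the returned path is
#' non-decreasing, and its log-probability never exceeds the forward
#' log-likelihood of the same trial.
#'
#' @param model an `lrhmm` object.
#' @param y a V x M trial matrix.
#' @return A list with `path` (integer state sequence of length V),
#'   `log_prob` (log-probability of the best path) and `backpointers`.
#' @export
viterbi <- function(model, y) {
  y <- as.matrix(y)
  logB <- emission_logmat(model, y)
  n <- model$n_states
  vlen <- ncol(logB)
  w <- model$band_width
  lband <- log(model$trans_band)
  delta <- log(model$pi) + logB[, 1L]
  psi <- matrix(0L, n, vlen)
  if (vlen >= 2L) for (v in 2:vlen) {
    # candidate predecessors i = j - d, compared exactly (strict > keeps
    # the earlier candidate on ties); scanning d from w down to 0 visits
    # smaller i first, giving the smallest-index tie-break
    cand <- matrix(-Inf, w + 1L, n)
    for (d in w:0) {
      if (d >= n) next
      j <- (d + 1L):n
      cand[w - d + 1L, j] <- delta[j - d] + lband[cbind(j - d, d + 1L)]
    }
    best <- rep(1L, n)
    bestval <- cand[1L, ]
    if (w >= 1L) for (r in 2:(w + 1L)) {
      upd <- cand[r, ] > bestval
      bestval[upd] <- cand[r, upd]
      best[upd] <- r
    }
    j <- seq_len(n)
    delta <- bestval + logB[, v]
    psi[, v] <- j - (w + 1L - best)   # predecessor index i = j - d
  }
  q <- integer(vlen)
  q[vlen] <- which.max(delta)
  log_prob <- delta[q[vlen]]
  if (vlen >= 2L) for (v in (vlen - 1L):1L) q[v] <- psi[q[v + 1L], v + 1L]
  list(path = q, log_prob = log_prob, backpointers = psi)
}

dense_trans <- function(model) {
  n <- model$n_states
  a <- matrix(0, n, n)
  for (d in 0:model$band_width) {
    i <- seq_len(n - d)
    a[cbind(i, i + d)] <- model$trans_band[i, d + 1L]
  }
  a
}

#' @export
print.lrhmm <- function(x, ...) {
  cat(sprintf("<lrhmm> left-to-right HMM: %d states, %d channels (%s)\n",
              x$n_states, x$n_channels, paste(x$channels, collapse = ", ")))
  if (is.null(x$fit)) {
    cat("  unfitted (initial parameters)\n")
  } else {
    cat(sprintf("  Baum-Welch: %d iterations (%s), log-likelihood %.4f\n",
                x$fit$iterations, x$fit$stop_reason, x$fit$loglik))
  }
  invisible(x)
}

#' @export
summary.lrhmm <- function(object, ...) {
  s <- list(
    n_states = object$n_states,
    n_channels = object$n_channels,
    channels = object$channels,
    band_width = object$band_width,
    variance_floor = object$variance_floor,
    mean_range = apply(object$means, 2, range),
    sd_range = apply(sqrt(object$variances), 2, range),
    floored = sum(object$variances <= object$variance_floor),
    fit = object$fit)
  class(s) <- "summary.lrhmm"
  s
}

#' @export
print.summary.lrhmm <- function(x, ...) {
  cat(sprintf("Left-to-right HMM: %d states x %d channels, band width %d\n",
              x$n_states, x$n_channels, x$band_width))
  for (m in seq_along(x$channels))
    cat(sprintf("  %s: state means in [%.3g, %.3g], sds in [%.3g, %.3g]\n",
                x$channels[m], x$mean_range[1, m], x$mean_range[2, m],
                x$sd_range[1, m], x$sd_range[2, m]))
  cat(sprintf("  %d variance entries at the floor (%g)\n",
              x$floored, x$variance_floor))
  if (!is.null(x$fit))
    cat(sprintf("  fit: %d iterations, %s, final log-likelihood %.4f\n",
                x$fit$iterations, x$fit$stop_reason, x$fit$loglik))
  invisible(x)
}

#' @export
coef.lrhmm <- function(object, ...) {
  list(pi = object$pi, trans = dense_trans(object),
       means = object$means, variances = object$variances)
}

#' @export
logLik.lrhmm <- function(object, ...) {
  if (is.null(object$fit)) stop("model has not been fitted", call. = FALSE)
  df <- (object$n_states - 1) + 2 * object$n_states * object$n_channels +
    if (object$update_trans) sum(object$trans_band > 0) - object$n_states else 0
  structure(object$fit$loglik, df = df,
            nobs = object$fit$n_trials * object$n_states, class = "logLik")
}

#' Predict from a fitted left-to-right HMM
#'
#' `type = "loglik"` returns the forward log-likelihood of each trial's
#' prefix; `type = "states"` the Viterbi state path per trial.
#'
#' @param object an `lrhmm` object.
#' @param newdata a trial matrix, list of trials, or `trajectory_set`.
#' @param type `"loglik"` or `"states"`.
#' @param prefix optional prefix length (samples) for `"loglik"`.
#' @param ... unused.
#' @return Numeric vector of log-likelihoods, or a list of integer paths.
#' @export
predict.lrhmm <- function(object, newdata, type = c("loglik", "states"),
                          prefix = NULL, ...) {
  type <- match.arg(type)
  trials <- if (inherits(newdata, "trajectory_set")) newdata$trials
            else if (is.list(newdata)) newdata else list(as.matrix(newdata))
  if (type == "loglik") {
    vapply(trials, function(y) {
      y <- as.matrix(y)
      forward_loglik(object, y, v = if (is.null(prefix)) nrow(y) else prefix)
    }, numeric(1))
  } else {
    lapply(trials, function(y) viterbi(object, as.matrix(y))$path)
  }
}

#' Simulate trajectories from a fitted left-to-right HMM
#'
#' Samples a state path from the initial distribution and transition band,
#' then Gaussian observations from each visited state's emission density.
#' The path length equals the number of states (one state per time step).
#'
#' @param object an `lrhmm` object.
#' @param nsim number of trials to simulate.
#' @param seed RNG seed.
#' @param sample_rate sampling rate recorded on the returned set.
#' @param ... unused.
#' @return A `trajectory_set` of `nsim` simulated trials, with the state
#'   paths in attribute `"paths"`.
#' @export
simulate.lrhmm <- function(object, nsim = 1L, seed = 1L, sample_rate = 40, ...) {
  n <- object$n_states
  w <- object$band_width
  sds <- sqrt(pmax(object$variances, object$variance_floor))
  with_seed(seed, {
    paths <- vector("list", nsim)
    trials <- vector("list", nsim)
    for (k in seq_len(nsim)) {
      q <- integer(n)
      q[1L] <- sample.int(n, 1L, prob = object$pi)
      if (n >= 2L) for (v in 2:n) {
        i <- q[v - 1L]
        p <- object$trans_band[i, ]
        d <- sample.int(w + 1L, 1L, prob = p) - 1L
        q[v] <- min(i + d, n)
      }
      y <- object$means[q, , drop = FALSE] +
        matrix(stats::rnorm(n * object$n_channels), n) * sds[q, , drop = FALSE]
      colnames(y) <- object$channels
      trials[[k]] <- y
      paths[[k]] <- q
    }
    out <- trajectory_set(trials, sample_rate, channels = object$channels)
    attr(out, "paths") <- paths
    out
  })
}

#' Standardised residuals of trials against the model's state means
#'
#' Decodes each trial with Viterbi and returns `(y - mu[q])/sd[q]`, the
#' observation residuals standardised by the assigned state's emission
#' parameters.
#'
#' @param object an `lrhmm` object.
#' @param newdata trial matrix, list, or `trajectory_set`.
#' @param ... unused.
#' @return A list of V x M residual matrices.
#' @export
residuals.lrhmm <- function(object, newdata, ...) {
  trials <- if (inherits(newdata, "trajectory_set")) newdata$trials
            else if (is.list(newdata)) newdata else list(as.matrix(newdata))
  sds <- sqrt(pmax(object$variances, object$variance_floor))
  lapply(trials, function(y) {
    y <- as.matrix(y)
    q <- viterbi(object, y)$path
    (y - object$means[q, , drop = FALSE]) / sds[q, , drop = FALSE]
  })
}

#' Plot a fitted left-to-right HMM's emission profile
#'
#' State means with a +/- k sd band per channel, against state index (which
#' is also the time-step index in this time-indexed model).
#'
#' @param x an `lrhmm` object.
#' @param band_k half-width of the shaded band in emission sds.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.lrhmm <- function(x, band_k = 3, ...) {
  n <- x$n_states
  sds <- sqrt(pmax(x$variances, x$variance_floor))
  op <- graphics::par(mfrow = c(x$n_channels, 1), mar = c(3.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  for (m in seq_len(x$n_channels)) {
    lo <- x$means[, m] - band_k * sds[, m]
    hi <- x$means[, m] + band_k * sds[, m]
    graphics::matplot(seq_len(n), cbind(lo, x$means[, m], hi), type = "l",
                      lty = c(2, 1, 2), col = c("grey60", "black", "grey60"),
                      xlab = "state (time step)", ylab = x$channels[m], ...)
  }
  invisible(x)
}

#' Write and read a fitted model as structured text
#'
#' Serialises every parameter (with 17 significant digits, so the
#' round-trip is bit-exact), the band specification, the variance floor and
#' the fit report to a plain-text model file.
#'
#' @param model an `lrhmm` object.
#' @param path file path.
#' @return `write_lrhmm()` returns `path` invisibly; `read_lrhmm()` the
#'   restored `lrhmm` object.
#' @export
write_lrhmm <- function(model, path) {
  num <- function(x) sprintf("%.17g", x)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste(...), con)
  wl("fabmotion_lrhmm", "1")
  wl("n_states", model$n_states)
  wl("n_channels", model$n_channels)
  wl("band_width", model$band_width)
  wl("variance_floor", num(model$variance_floor))
  wl("update_trans", model$update_trans)
  wl("channels", paste(model$channels, collapse = ","))
  wl("pi", paste(num(model$pi), collapse = " "))
  for (d in 0:model$band_width)
    wl(paste0("trans_band_", d), paste(num(model$trans_band[, d + 1L]),
                                       collapse = " "))
  for (m in seq_len(model$n_channels)) {
    wl(paste0("means_", m), paste(num(model$means[, m]), collapse = " "))
    wl(paste0("variances_", m), paste(num(model$variances[, m]),
                                      collapse = " "))
  }
  if (!is.null(model$fit)) {
    wl("fit_loglik", num(model$fit$loglik))
    wl("fit_trace", paste(num(model$fit$trace), collapse = " "))
    wl("fit_iterations", model$fit$iterations)
    wl("fit_stop_reason", model$fit$stop_reason)
    wl("fit_zero_occupancy", paste(model$fit$zero_occupancy_states,
                                   collapse = " "))
    wl("fit_n_trials", model$fit$n_trials)
    wl("fit_seed", model$fit$seed)
  }
  invisible(path)
}

#' @rdname write_lrhmm
#' @export
read_lrhmm <- function(path) {
  lines <- readLines(path)
  kv <- regmatches(lines, regexpr(" ", lines), invert = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) if (length(x) > 1L) x[2L] else "", "")
  get1 <- function(k) vals[match(k, keys)]
  nums <- function(k) as.numeric(strsplit(get1(k), " ", fixed = TRUE)[[1L]])
  if (is.na(get1("fabmotion_lrhmm")))
    stop("not a fabmotion model file", call. = FALSE)
  n <- as.integer(get1("n_states"))
  m <- as.integer(get1("n_channels"))
  w <- as.integer(get1("band_width"))
  band <- sapply(0:w, function(d) nums(paste0("trans_band_", d)))
  if (n == 1L) band <- matrix(band, nrow = 1L)
  means <- sapply(seq_len(m), function(j) nums(paste0("means_", j)))
  vars <- sapply(seq_len(m), function(j) nums(paste0("variances_", j)))
  if (n == 1L) { means <- matrix(means, 1L); vars <- matrix(vars, 1L) }
  model <- structure(
    list(n_states = n, n_channels = m, pi = nums("pi"),
         trans_band = band, band_width = w,
         means = means, variances = vars,
         variance_floor = as.numeric(get1("variance_floor")),
         update_trans = as.logical(get1("update_trans")),
         channels = strsplit(get1("channels"), ",", fixed = TRUE)[[1L]],
         fit = NULL),
    class = "lrhmm")
  if ("fit_loglik" %in% keys) {
    zo <- get1("fit_zero_occupancy")
    model$fit <- list(
      loglik = as.numeric(get1("fit_loglik")),
      trace = nums("fit_trace"),
      iterations = as.integer(get1("fit_iterations")),
      stop_reason = get1("fit_stop_reason"),
      zero_occupancy_states = if (is.na(zo) || zo == "") integer(0)
                              else as.integer(strsplit(zo, " ")[[1L]]),
      n_trials = as.integer(get1("fit_n_trials")),
      seed = as.integer(get1("fit_seed")))
  }
  model
}
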