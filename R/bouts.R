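#' Bout observable: log RMS amplitude in moving windows
#'
#' The dominant signature of an inhibitory bout is the collapse of the heart
#' PPG envelope, so the HMM observes the log of the root-mean-square
#' amplitude about the local (within-window) mean — i.e. the windowed
#' standard deviation — in short windows (default 2 s stepped by 1 s) of the
#' conditioned heart trace. Removing the within-window mean keeps slow
#' baseline shifts from masking the amplitude collapse. The RMS is floored at
#' machine precision so silent stretches stay finite.
#'
#' @param ts Conditioned heart [ppg_ts()].
#' @param feature_window_s Window length, s.
#' @param step_s Window step, s.
#' @return Data frame with columns `time_s` (window centres) and `feature`
#'   (log RMS); the step is kept in `attr(, "step_s")`.
#' @export
bout_feature <- function(ts, feature_window_s = 2, step_s = 1) {
  stopifnot(inherits(ts, "ppg_ts"), feature_window_s > 0, step_s > 0)
  nwin <- round(feature_window_s * ts$rate)
  step <- max(1L, round(step_s * ts$rate))
  n <- length(ts$samples)
  if (nwin > n) stop("feature window longer than the record")
  starts <- seq.int(1L, n - nwin + 1L, by = step)
  cs1 <- cumsum(c(0, ts$samples))
  cs2 <- cumsum(c(0, ts$samples^2))
  mu <- (cs1[starts + nwin] - cs1[starts]) / nwin
  msq <- (cs2[starts + nwin] - cs2[starts]) / nwin
  rms <- sqrt(pmax(msq - mu^2, 0))
  feat <- log(pmax(rms, .Machine$double.eps))
  out <- data.frame(
    time_s = ts$t0 + (starts - 1L + (nwin - 1L) / 2) / ts$rate,
    feature = feat
  )
  attr(out, "step_s") <- step / ts$rate
  out
}

#' Two-state HMM parameter container
#'
#' @param transition 2x2 row-stochastic transition matrix; rows/columns are
#'   ordered (state 1, state 2) with no label attached — labelling as
#'   active/inhibitory happens at decoding, by emission mean.
#' @param means,vars Gaussian emission mean and variance per state.
#' @param initial Initial state distribution (sums to 1).
#' @return List of class `hmm_params`.
#' @export
hmm_params <- function(transition, means, vars, initial = c(0.5, 0.5)) {
  transition <- matrix(as.numeric(transition), 2L, 2L)
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-8))
    stop("'transition' rows must be nonnegative and sum to 1")
  if (length(means) != 2L || length(vars) != 2L || any(vars <= 0))
    stop("need 2 emission means and 2 positive variances")
  if (abs(sum(initial) - 1) > 1e-8 || any(initial < 0))
    stop("'initial' must be a distribution over 2 states")
  structure(list(transition = transition, means = as.numeric(means),
                 vars = as.numeric(vars), initial = as.numeric(initial)),
            class = "hmm_params")
}

#' Default initial HMM parameters for bout detection
#'
#' The initial transition matrix uses the classical fast-switching starting
#' values P(switch) = 0.9, P(stay) = 0.1; Baum-Welch re-estimates them.
#' Emission parameters start from a deterministic two-means split of the
#' feature (initial centres at the 10th and 90th percentiles, Lloyd
#' iterations to convergence), which finds a minority low-amplitude mode that
#' plain percentile inits can miss.
#'
#' @param features Numeric feature vector (or the data frame from
#'   [bout_feature()]).
#' @return An [hmm_params()] object.
#' @export
default_hmm_init <- function(features) {
  f <- if (is.data.frame(features)) features$feature else as.numeric(features)
  ctr <- stats::quantile(f, c(0.1, 0.9), names = FALSE)
  if (diff(ctr) <= 0) ctr <- range(f)
  for (i in seq_len(50)) {
    assign1 <- abs(f - ctr[1L]) <= abs(f - ctr[2L])
    new_ctr <- c(mean(f[assign1]), mean(f[!assign1]))
    if (any(!is.finite(new_ctr))) break
    if (max(abs(new_ctr - ctr)) < 1e-10) { ctr <- new_ctr; break }
    ctr <- new_ctr
  }
  assign1 <- abs(f - ctr[1L]) <= abs(f - ctr[2L])
  v <- c(stats::var(f[assign1]), stats::var(f[!assign1]))
  v[!is.finite(v) | v < 1e-6] <- max(stats::var(f), 1e-6)
  hmm_params(transition = matrix(c(0.1, 0.9, 0.9, 0.1), 2L, 2L, byrow = TRUE),
             means = ctr, vars = v, initial = c(0.5, 0.5))
}

# Scaled forward-backward pass. Returns log-likelihood, smoothed posteriors
# (gamma, T x 2) and expected transition counts (xi_sum, 2 x 2).
forward_backward <- function(f, par) {
  T_ <- length(f)
  B <- cbind(stats::dnorm(f, par$means[1L], sqrt(par$vars[1L])),
             stats::dnorm(f, par$means[2L], sqrt(par$vars[2L])))
  B <- pmax(B, .Machine$double.xmin)
  A <- par$transition
  alpha <- matrix(0, T_, 2L)
  scale <- numeric(T_)
  a <- par$initial * B[1L, ]
  scale[1L] <- sum(a)
  alpha[1L, ] <- a / scale[1L]
  for (t in 2L:T_) {
    a <- (alpha[t - 1L, ] %*% A) * B[t, ]
    scale[t] <- sum(a)
    alpha[t, ] <- a / scale[t]
  }
  beta <- matrix(0, T_, 2L)
  beta[T_, ] <- 1
  xi_sum <- matrix(0, 2L, 2L)
  for (t in (T_ - 1L):1L) {
    bb <- B[t + 1L, ] * beta[t + 1L, ]
    beta[t, ] <- (A %*% bb) / scale[t + 1L]
    xi <- (alpha[t, ] %o% bb) * A / scale[t + 1L]
    xi_sum <- xi_sum + xi
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(loglik = sum(log(scale)), gamma = gamma, xi_sum = xi_sum)
}

#' Fit the two-state Gaussian HMM by Baum-Welch
#'
#' Expectation-maximization with a scaled forward-backward E step. The
#' log-likelihood is non-decreasing across iterations (asserted to numerical
#' tolerance); iteration stops when its relative change falls below `tol` or
#' after `max_iter` iterations.
#'
#' @param features Numeric feature vector or the data frame from
#'   [bout_feature()].
#' @param init Initial [hmm_params()]; defaults to [default_hmm_init()].
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @return An [hmm_params()] with attributes `loglik` (final value),
#'   `loglik_trace` and `iterations`.
#' @export
baum_welch <- function(features, init = NULL, max_iter = 500, tol = 1e-6) {
  f <- if (is.data.frame(features)) features$feature else as.numeric(features)
  if (length(f) < 10L) stop("need at least 10 feature steps")
  if (!all(is.finite(f))) stop("non-finite features")
  if (stats::var(f) <= .Machine$double.xmin)
    stop("degenerate (zero-variance) feature")
  par <- if (is.null(init)) default_hmm_init(f) else init
  stopifnot(inherits(par, "hmm_params"))
  trace <- numeric(0)
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    fb <- forward_backward(f, par)
    if (fb$loglik < prev - 1e-8 * max(1, abs(prev)))
      stop("EM log-likelihood decreased; numerical failure")
    trace <- c(trace, fb$loglik)
    if (is.finite(prev) &&
        abs(fb$loglik - prev) <= tol * max(1, abs(prev))) break
    prev <- fb$loglik
    g <- fb$gamma
    A <- fb$xi_sum / pmax(rowSums(fb$xi_sum), .Machine$double.xmin)
    occ <- colSums(g)
    means <- colSums(g * f) / occ
    vars <- pmax(colSums(g * (outer(f, means, "-")^2)) / occ, 1e-10)
    par <- hmm_params(A, means, vars, initial = pmax(g[1L, ], 1e-12) /
                        sum(pmax(g[1L, ], 1e-12)))
  }
  attr(par, "loglik") <- trace[length(trace)]
  attr(par, "loglik_trace") <- trace
  attr(par, "iterations") <- length(trace)
  par
}

#' Decode the active/inhibitory state path
#'
#' Viterbi decoding of the most probable state path, plus forward-backward
#' posteriors. States are labelled by emission mean, not index: the state with
#' the lower mean (collapsed amplitude) is "inhibitory" (0), the other
#' "active" (1), so results are permutation-stable.
#'
#' Before decoding, the two-state fit is compared by BIC with a single
#' Gaussian: when one state already explains the feature (no second regime),
#' the whole record is labelled active instead of letting two overlapping
#' components split the noise. Disable with `check_one_state = FALSE`.
#'
#' @param model Fitted [hmm_params()].
#' @param features Numeric feature vector or data frame from [bout_feature()].
#' @param check_one_state Compare against a one-state model first (default
#'   TRUE).
#' @return Data frame of class `ppg_statepath` with columns `time_s` (if
#'   available), `state` (1 active / 0 inhibitory) and `posterior_inhib`;
#'   step size carried in `attr(, "step_s")`.
#' @export
decode_states <- function(model, features, check_one_state = TRUE) {
  stopifnot(inherits(model, "hmm_params"))
  f <- if (is.data.frame(features)) features$feature else as.numeric(features)
  tt <- if (is.data.frame(features)) features$time_s else
    seq_along(f) - 1
  step_s <- attr(features, "step_s")
  if (is.null(step_s)) step_s <- if (length(tt) > 1L) tt[2L] - tt[1L] else 1
  T_ <- length(f)
  if (check_one_state) {
    ll1 <- sum(stats::dnorm(f, mean(f), stats::sd(f), log = TRUE))
    ll2 <- forward_backward(f, model)$loglik
    bic1 <- -2 * ll1 + 2 * log(T_)
    bic2 <- -2 * ll2 + 7 * log(T_)
    if (bic1 <= bic2) {
      out <- data.frame(time_s = tt, state = 1L, posterior_inhib = 0)
      attr(out, "step_s") <- step_s
      class(out) <- c("ppg_statepath", "data.frame")
      return(out)
    }
  }
  logB <- cbind(stats::dnorm(f, model$means[1L], sqrt(model$vars[1L]),
                             log = TRUE),
                stats::dnorm(f, model$means[2L], sqrt(model$vars[2L]),
                             log = TRUE))
  logA <- log(pmax(model$transition, .Machine$double.xmin))
  delta <- matrix(-Inf, T_, 2L)
  psi <- matrix(1L, T_, 2L)
  delta[1L, ] <- log(pmax(model$initial, .Machine$double.xmin)) + logB[1L, ]
  for (t in 2L:T_) {
    for (s in 1:2) {
      cand <- delta[t - 1L, ] + logA[, s]
      psi[t, s] <- which.max(cand)
      delta[t, s] <- cand[psi[t, s]] + logB[t, s]
    }
  }
  path <- integer(T_)
  path[T_] <- which.max(delta[T_, ])
  for (t in (T_ - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  inhib_state <- which.min(model$means)
  fb <- forward_backward(f, model)
  out <- data.frame(
    time_s = tt,
    state = ifelse(path == inhib_state, 0L, 1L),
    posterior_inhib = fb$gamma[, inhib_state]
  )
  attr(out, "step_s") <- step_s
  class(out) <- c("ppg_statepath", "data.frame")
  out
}

#' Run-length encode the state path into a bout table
#'
#' Consecutive equal states become one bout of duration (run length x step).
#' Bouts tile the record without overlap and adjacent rows alternate state;
#' per-state duration summaries and empirical cumulative distributions are
#' attached.
#'
#' @param states A `ppg_statepath` from [decode_states()].
#' @param min_duration_s Optional minimum bout duration; shorter runs are
#'   merged into the enclosing state (default `0` = no filter).
#' @return List with `bouts` (data frame of class `ppg_bouttable`: `state`,
#'   `start_s`, `duration_s`) and `summary` (per-state mean/median/count).
#' @export
bout_durations <- function(states, min_duration_s = 0) {
  stopifnot(is.data.frame(states), nrow(states) >= 1L)
  step_s <- attr(states, "step_s")
  if (is.null(step_s)) step_s <- 1
  s <- states$state
  if (min_duration_s > 0) {
    repeat {
      r <- rle(s)
      short <- which(r$lengths * step_s < min_duration_s)
      short <- short[!(short %in% c(1L, length(r$lengths)))]
      if (length(short) == 0L) break
      k <- short[1L]
      r$values[k] <- r$values[k - 1L]
      s <- inverse.rle(r)
    }
  }
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  bouts <- data.frame(
    state = r$values,
    start_s = states$time_s[1L] + starts * step_s,
    duration_s = r$lengths * step_s
  )
  class(bouts) <- c("ppg_bouttable", "data.frame")
  summarize <- function(st) {
    d <- bouts$duration_s[bouts$state == st]
    data.frame(state = st, n = length(d),
               mean_s = if (length(d)) mean(d) else NA_real_,
               median_s = if (length(d)) stats::median(d) else NA_real_)
  }
  list(bouts = bouts, summary = rbind(summarize(1L), summarize(0L)))
}
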