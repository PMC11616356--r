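#' Duration-weighted exponential velocity fit
#'
#' Maximum-likelihood exponential fit on `[0, Inf)` to absolute segment
#' velocities, time-weighted by repeating each velocity `N_R` times with
#' `N_R = floor(duration / basis)`. The weighted MLE is the closed-form
#' weighted mean `sum(N_R * v) / sum(N_R)`; no optimiser is involved. The
#' 95% CI comes from the exponential (chi-square) likelihood on the weighted
#' sample with `n_effective = sum(N_R)`; the reported `n_obs` excludes the
#' weight replication.
#'
#' @param values Absolute velocities (nm/s) or other non-negative
#'   exponential variates, one per segment.
#' @param durations Segment durations, s; all at least `basis`. `NULL` gives
#'   unit weights.
#' @param basis Weight basis, s (`N_R = floor(duration / basis)`).
#' @return A `dist_fit` (family `"exp"`): parameter `mean`, 95% CI,
#'   `n_obs`, `n_effective`, log-likelihood.
#' @examples
#' fit_exponential_weighted(c(1, 4), durations = c(30, 10)) # mean 1.75
#' @export
fit_exponential_weighted <- function(values, durations = NULL, basis = 10) {
  if (length(values) == 0) stopf("empty sample")
  if (any(values < 0)) stopf("values must be non-negative (pass |v| per direction class)")
  if (is.null(durations)) {
    w <- rep(1, length(values))
  } else {
    if (length(durations) != length(values)) stopf("values/durations length mismatch")
    if (any(durations < basis)) stopf("all durations must be >= the weight basis (%g s)", basis)
    w <- floor(durations / basis)
  }
  S <- sum(w * values)
  n_eff <- sum(w)
  mu <- S / n_eff
  ci <- exp_mean_ci(S, n_eff)
  ll <- if (mu > 0) sum(w * stats::dexp(values, rate = 1 / mu, log = TRUE)) else -Inf
  new_dist_fit(
    family = "exp",
    params = list(mean = mu),
    ci95 = list(mean = unname(ci)),
    n_obs = length(values), n_effective = n_eff, loglik = ll,
    data = list(values = values, weights = w)
  )
}

#' Left-truncated exponential dwell-time fit
#'
#' Two-parameter exponential in which the total probability on
#' `[t0, Inf)` equals 1: density `f(t) = (1/tau) exp(-(t - t0)/tau)`. The
#' MLE is the closed form `tau = mean(durations) - t0`. Both `tau` and the
#' distribution mean `t0 + tau` are reported.
#'
#' @param durations Dwell times, s; all at least `t0`.
#' @param t0 Truncation point, s (the minimum segment duration).
#' @return A `dist_fit` (family `"trunc_exp"`): parameters `tau`, `t0`,
#'   `mean`, with a degenerate-fit warning when all durations equal `t0`.
#' @examples
#' fit_truncated_exponential(c(20, 30)) # tau 15, mean 25
#' @export
fit_truncated_exponential <- function(durations, t0 = 10) {
  if (length(durations) == 0) stopf("empty sample")
  if (any(durations < t0)) stopf("all durations must be >= t0 = %g s", t0)
  y <- durations - t0
  tau <- mean(y)
  n <- length(y)
  if (tau <= 0) {
    warnf("degenerate fit: all durations equal t0, tau = 0")
    ci <- c(0, 0)
    ll <- Inf
  } else {
    ci <- unname(exp_mean_ci(sum(y), n))
    ll <- sum(stats::dexp(y, rate = 1 / tau, log = TRUE))
  }
  new_dist_fit(
    family = "trunc_exp",
    params = list(tau = tau, t0 = t0, mean = t0 + tau),
    ci95 = list(tau = ci, mean = t0 + ci),
    n_obs = n, n_effective = n, loglik = ll,
    data = list(values = durations)
  )
}

#' Two-component truncated-exponential mixture fit by EM
#'
#' Fits `f(t) = A1/t1 exp(-(t - t0)/t1) + A2/t2 exp(-(t - t0)/t2)` on
#' `[t0, Inf)` with `A1 + A2 = 1` by expectation-maximization. Iterations
#' stop when both component-mean updates change by less than `tol`; the
#' log-likelihood is non-decreasing by construction and is retained per
#' iteration for inspection. Components are reported with `t1 <= t2`.
#' Collapse onto a single component (vanishing amplitude or equal means) is
#' flagged degenerate. 95% CIs come from the observed information
#' (numerical Hessian of the log-likelihood).
#'
#' @param durations Dwell times, s; all at least `t0`, at least 4 values.
#' @param t0 Truncation point, s.
#' @param tol Convergence tolerance on the component means, s.
#' @param max_iter Iteration cap; hitting it flags the fit non-converged.
#' @return A `dist_fit` (family `"trunc_2exp"`): parameters `A1`, `t1`,
#'   `A2`, `t2`, `t0`, plus `n_iter`, `converged`, `degenerate` and the
#'   iteration log-likelihood trace in `loglik_trace`.
#' @export
fit_double_exponential_em <- function(durations, t0 = 10, tol = 1e-5,
                                      max_iter = 5000) {
  if (length(durations) < 4) stopf("need at least 4 durations")
  if (any(durations < t0)) stopf("all durations must be >= t0 = %g s", t0)
  y <- durations - t0
  n <- length(y)
  qs <- stats::quantile(y, c(0.25, 0.75), names = FALSE)
  t1 <- max(qs[1], 1e-3)
  t2 <- max(qs[2], t1 * 1.5)
  A1 <- 0.5
  mix_ll <- function(A1, t1, t2) {
    sum(log(A1 / t1 * exp(-y / t1) + (1 - A1) / t2 * exp(-y / t2)))
  }
  ll_trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    d1 <- A1 / t1 * exp(-y / t1)
    d2 <- (1 - A1) / t2 * exp(-y / t2)
    r1 <- d1 / (d1 + d2)
    A1_new <- mean(r1)
    s1 <- sum(r1)
    s2 <- n - s1
    t1_new <- if (s1 > 1e-12) sum(r1 * y) / s1 else t1
    t2_new <- if (s2 > 1e-12) sum((1 - r1) * y) / s2 else t2
    t1_new <- max(t1_new, 1e-9)
    t2_new <- max(t2_new, 1e-9)
    A1_new <- min(max(A1_new, 1e-12), 1 - 1e-12)
    ll_trace <- c(ll_trace, mix_ll(A1_new, t1_new, t2_new))
    done <- abs(t1_new - t1) < tol && abs(t2_new - t2) < tol
    A1 <- A1_new
    t1 <- t1_new
    t2 <- t2_new
    if (done) {
      converged <- TRUE
      break
    }
  }
  if (t1 > t2) { # ordering convention t1 <= t2
    tmp <- t1; t1 <- t2; t2 <- tmp
    A1 <- 1 - A1
  }
  A2 <- 1 - A1
  degenerate <- A1 < 1e-6 || A2 < 1e-6 || abs(t2 - t1) < 1e-6 * max(t2, 1e-12)
  ci95 <- list(A1 = c(NA_real_, NA_real_), t1 = c(NA_real_, NA_real_),
               t2 = c(NA_real_, NA_real_))
  if (!degenerate) {
    se <- tryCatch({
      H <- stats::optimHess(c(A1, t1, t2), function(p) {
        if (p[1] <= 0 || p[1] >= 1 || p[2] <= 0 || p[3] <= 0) return(1e10)
        -mix_ll(p[1], p[2], p[3])
      })
      sqrt(diag(solve(H)))
    }, error = function(e) rep(NA_real_, 3))
    ci95 <- list(
      A1 = A1 + c(-1, 1) * 1.96 * se[1],
      t1 = t1 + c(-1, 1) * 1.96 * se[2],
      t2 = t2 + c(-1, 1) * 1.96 * se[3]
    )
  }
  if (!converged) warnf("EM did not converge in %d iterations", max_iter)
  fit <- new_dist_fit(
    family = "trunc_2exp",
    params = list(A1 = A1, t1 = t1, A2 = A2, t2 = t2, t0 = t0,
                  mean1 = t0 + t1, mean2 = t0 + t2),
    ci95 = ci95,
    n_obs = n, n_effective = n,
    loglik = mix_ll(A1, t1, t2),
    data = list(values = durations)
  )
  fit$n_iter <- it
  fit$converged <- converged
  fit$degenerate <- degenerate
  fit$loglik_trace <- ll_trace
  fit
}

#' Derive the pause-velocity threshold from a control fit
#'
#' The quantile of the exponential control-speed distribution:
#' `mu * log(1 / (1 - quantile))`. At the default 0.90 quantile a control
#' mean of 0.037 nm/s gives 0.0852 nm/s -- the conservative cutoff below
#' which motion is indistinguishable from residual drift.
#'
#' @param control_fit A `dist_fit` of family `"exp"` to control segment
#'   speeds, or a numeric exponential mean.
#' @param quantile Quantile in (0, 1).
#' @return Threshold in nm/s.
#' @examples
#' derive_pause_threshold(0.037) # 0.0852
#' @export
derive_pause_threshold <- function(control_fit, quantile = 0.90) {
  if (quantile <= 0 || quantile >= 1) stopf("quantile must be in (0, 1)")
  mu <- if (inherits(control_fit, "dist_fit")) {
    if (control_fit$family != "exp") stopf("control fit must be an exponential fit")
    control_fit$params$mean
  } else {
    as.numeric(control_fit)
  }
  mu * log(1 / (1 - quantile))
}

#' Detect abrupt positional displacements
#'
#' Finds plateau-to-plateau position changes of at least `min_amplitude`
#' completing within `max_transition`, on a full-rate (pre-downsample)
#' record. The detection statistic is the difference of boxcar plateau means
#' on either side of a transition gap; events are localised at the
#' maximum-slope sample, amplitudes measured plateau-to-plateau, and
#' opposite-sign events of similar amplitude (within `pair_tol`, default
#' 20%) within `pair_window` are paired as reversible partners.
#'
#' @param trace A full-rate `mot_trace` (smoothed is fine).
#' @param min_amplitude Detection floor, nm.
#' @param max_transition Maximum transition time, s.
#' @param plateau_window Plateau averaging window, s.
#' @param pair_window Reversible-partner search window, s.
#' @param pair_tol Relative amplitude tolerance for partner pairing.
#' @return A `jump_events` tibble: `t`, `amplitude` (signed, nm),
#'   `transition_time` (s), `partner` (row index of the reversible partner
#'   or NA). An empty tibble is a valid result.
#' @export
detect_jumps <- function(trace, min_amplitude = 5, max_transition = 0.01,
                         plateau_window = 0.03, pair_window = 10,
                         pair_tol = 0.2) {
  assert_trace(trace)
  rate <- sample_rate(trace)
  x <- trace$x
  n <- length(x)
  w <- max(3L, round(plateau_window * rate))
  g <- max(1L, ceiling(max_transition * rate))
  empty <- structure(
    tibble::tibble(t = numeric(0), amplitude = numeric(0),
                   transition_time = numeric(0), partner = integer(0)),
    class = c("jump_events", class(tibble::tibble()))
  )
  if (n < 2 * (w + g) + 1) return(empty)
  cs <- cumsum(c(0, x))
  idx <- (w + g + 1):(n - w - g)
  after <- (cs[idx + g + w + 1] - cs[idx + g + 1]) / w
  before <- (cs[idx - g] - cs[idx - g - w]) / w
  stat <- after - before
  hot <- which(abs(stat) >= min_amplitude)
  if (length(hot) == 0) return(empty)
  # cluster candidate centres separated by less than one plateau window
  cl <- cumsum(c(TRUE, diff(hot) > w))
  events <- lapply(split(hot, cl), function(h) {
    centre <- h[which.max(abs(stat[h]))]
    i <- idx[centre]
    # refine to the steepest sample: short boxcar difference, robust to
    # single-sample noise spikes
    m <- max(3L, ceiling(g / 3))
    span <- max(i - g, m + 1):min(i + g, n - m)
    d <- (cs[span + m + 1] - cs[span + 1]) - (cs[span] - cs[span - m])
    i <- span[which.max(abs(d))]
    lo <- max(1, i - g - w)
    hi <- min(n, i + g + w)
    before_m <- mean(x[lo:(i - g)])
    after_m <- mean(x[(i + g):hi])
    amp <- after_m - before_m
    # 10-90% transition time between the plateaus, on a lightly smoothed
    # signal: last sample still at the 10% level before the max-slope
    # sample, first sample reaching the 90% level after it
    lv10 <- before_m + 0.1 * amp
    lv90 <- before_m + 0.9 * amp
    win <- max(1, i - 2 * g - w):min(n, i + 2 * g + w)
    xs <- moving_average(x[win], 3L)
    rel <- which(win == i)
    if (amp > 0) {
      below <- which(xs[seq_len(rel)] <= lv10)
      above <- which(xs[rel:length(xs)] >= lv90)
    } else {
      below <- which(xs[seq_len(rel)] >= lv10)
      above <- which(xs[rel:length(xs)] <= lv90)
    }
    tt <- if (length(below) == 0 || length(above) == 0) {
      NA_real_
    } else {
      max((rel + above[1] - 1) - below[length(below)], 1) / rate
    }
    tibble::tibble(t = trace$t[i], amplitude = amp, transition_time = tt)
  })
  ev <- dplyr::bind_rows(events)
  ev <- ev[abs(ev$amplitude) >= min_amplitude, ]
  ev <- ev[is.na(ev$transition_time) | ev$transition_time <= 1.5 * max_transition, ]
  if (nrow(ev) == 0) return(empty)
  ev <- ev[order(ev$t), ]
  ev$partner <- NA_integer_
  for (i in seq_len(nrow(ev))) {
    if (!is.na(ev$partner[i])) next
    j <- which(
      ev$t > ev$t[i] & ev$t <= ev$t[i] + pair_window &
        sign(ev$amplitude) == -sign(ev$amplitude[i]) &
        abs(abs(ev$amplitude) - abs(ev$amplitude[i])) <=
          pair_tol * abs(ev$amplitude[i]) &
        is.na(ev$partner)
    )
    if (length(j) > 0) {
      ev$partner[i] <- j[1]
      ev$partner[j[1]] <- i
    }
  }
  structure(ev, class = c("jump_events", class(tibble::tibble())))
}

#' Subtract detected jumps from a trace
#'
#' Removes the persistent offset of each detected event -- the amplitude
#' applied as a sigmoid with the estimated transition time (a unit step when
#' no transition time is available) -- so that a jump neither splits nor
#' biases constant-velocity segments fitted afterwards.
#'
#' @param trace A `mot_trace`.
#' @param jumps A `jump_events` tibble from [detect_jumps()].
#' @return The trace with jump offsets removed; history records the count.
#' @export
remove_jumps <- function(trace, jumps) {
  assert_trace(trace)
  if (is.null(jumps) || nrow(jumps) == 0) return(trace)
  x <- trace$x
  for (i in seq_len(nrow(jumps))) {
    tt <- jumps$transition_time[i]
    if (is.na(tt) || tt <= 0) {
      x <- x - jumps$amplitude[i] * (trace$t >= jumps$t[i])
    } else {
      s <- tt / (2 * log(9))
      x <- x - jumps$amplitude[i] * stats::plogis((trace$t - jumps$t[i]) / s)
    }
  }
  retrace(trace, trace$t, x, trace_force(trace),
          step = sprintf("jumps-removed(%d)", nrow(jumps)))
}

new_dist_fit <- function(family, params, ci95, n_obs, n_effective, loglik,
                         data = NULL) {
  structure(
    list(family = family, params = params, ci95 = ci95, n_obs = n_obs,
         n_effective = n_effective, loglik = loglik, data = data),
    class = "dist_fit"
  )
}

#' @export
print.dist_fit <- function(x, ...) {
  cat(sprintf("<dist_fit: %s> n = %d (effective %g), logLik = %.3f\n",
              x$family, x$n_obs, x$n_effective, x$loglik))
  for (p in names(x$params)) {
    ci <- x$ci95[[p]]
    if (!is.null(ci) && all(is.finite(ci))) {
      cat(sprintf("  %-6s %.4g  [%.4g, %.4g]\n", p, x$params[[p]], ci[1], ci[2]))
    } else {
      cat(sprintf("  %-6s %.4g\n", p, x$params[[p]]))
    }
  }
  if (!is.null(x$converged)) {
    cat(sprintf("  EM: %d iterations, converged = %s, degenerate = %s\n",
                x$n_iter, x$converged, x$degenerate))
  }
  invisible(x)
}
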