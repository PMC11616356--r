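# shared builders for the test suite; everything is generated in code

make_ramp_trace <- function(slope = 0.2, duration = 100, rate = 30,
                            noise_sd = 0, intercept = 0, seed = NULL) {
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  x <- intercept + slope * t
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    x <- x + rnorm(n, 0, noise_sd)
  }
  new_trace(t, x, sample_rate = rate)
}

# piecewise-linear trace from (velocity, duration) pairs, continuous
make_piecewise_trace <- function(velocities, durations, rate = 30,
                                 noise_sd = 0, seed = NULL) {
  t_breaks <- c(0, cumsum(durations))
  n <- round(sum(durations) * rate)
  t <- (seq_len(n) - 1) / rate
  starts <- c(0, cumsum(velocities * durations))
  k <- findInterval(t, t_breaks, rightmost.closed = TRUE)
  k[k > length(velocities)] <- length(velocities)
  x <- starts[k] + velocities[k] * (t - t_breaks[k])
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    x <- x + rnorm(n, 0, noise_sd)
  }
  new_trace(t, x, sample_rate = rate)
}

# inject a smooth sigmoidal step into a trace
inject_step <- function(trace, t0, amplitude, risetime) {
  s <- risetime / (2 * log(9))
  x <- trace$x + amplitude * stats::plogis((trace$t - t0) / s)
  new_trace(trace$t, x, sample_rate = sample_rate(trace))
}

quiet_pipeline <- function(...) suppressMessages(suppressWarnings(run_pipeline(...)))
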