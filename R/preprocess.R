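#' Decimate a trace to a lower sampling rate
#'
#' Applies a zero-phase anti-alias low-pass (4th-order Butterworth at 0.8x
#' the target Nyquist, run forwards and backwards) before resampling onto the
#' target time base. Never upsamples.
#'
#' @param trace A `mot_trace`.
#' @param target_rate Target sampling rate, Hz; must not exceed the trace
#'   rate.
#' @return Decimated `mot_trace` at `target_rate`.
#' @export
decimate_trace <- function(trace, target_rate) {
  assert_trace(trace)
  rate <- sample_rate(trace)
  if (target_rate > rate) stopf("cannot upsample: target %g Hz > %g Hz", target_rate, rate)
  if (abs(target_rate - rate) < 1e-9 * rate) return(trace)
  wc <- 0.8 * target_rate / rate # cutoff as a fraction of the source Nyquist
  bf <- signal::butter(4, wc, type = "low")
  xf <- as.numeric(signal::filtfilt(bf, trace$x - trace$x[1])) + trace$x[1]
  n_out <- floor((nrow(trace) - 1) * target_rate / rate) + 1
  t_out <- trace$t[1] + (seq_len(n_out) - 1) / target_rate
  x_out <- stats::approx(trace$t, xf, xout = t_out, rule = 2)$y
  f <- trace_force(trace)
  f_out <- if (!is.null(f)) stats::approx(trace$t, f, xout = t_out, rule = 2)$y
  retrace(trace, t_out, x_out, f_out, sample_rate = target_rate,
          step = sprintf("decimate(%g Hz)", target_rate))
}

#' Exponentially weighted moving average
#'
#' Causal single-pass EWMA with decay `alpha = 2 / (window + 1)`, initialised
#' at the first sample so constant traces pass through unchanged. `window = 1`
#' is the identity.
#'
#' @param trace A `mot_trace`.
#' @param window Effective span of the smoothing kernel, samples (>= 1).
#' @return Smoothed `mot_trace`, same length and rate.
#' @export
ewma_trace <- function(trace, window = 20) {
  assert_trace(trace)
  if (window < 1) stopf("window must be >= 1")
  alpha <- 2 / (window + 1)
  sm <- function(x) {
    as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive",
                             init = x[1]))
  }
  f <- trace_force(trace)
  retrace(trace, trace$t, sm(trace$x), if (!is.null(f)) sm(f),
          step = sprintf("ewma(%d)", as.integer(window)))
}

#' Downsample a trace by an integer factor
#'
#' Keeps every `factor`-th sample, dividing the sampling rate accordingly.
#'
#' @param trace A `mot_trace`.
#' @param factor Integer keep-every factor (>= 1, at most the record length).
#' @return Downsampled `mot_trace`.
#' @export
downsample_trace <- function(trace, factor = 100) {
  assert_trace(trace)
  factor <- as.integer(factor)
  if (factor < 1) stopf("factor must be >= 1")
  if (factor > nrow(trace)) stopf("factor %d exceeds record length %d", factor, nrow(trace))
  if (factor == 1L) return(trace)
  idx <- seq(1L, nrow(trace), by = factor)
  f <- trace_force(trace)
  retrace(trace, trace$t[idx], trace$x[idx], if (!is.null(f)) f[idx],
          sample_rate = sample_rate(trace) / factor,
          step = sprintf("downsample(%d)", factor))
}

#' Standard record conditioning
#'
#' Decimation (skipped when the record is already at or below the target
#' rate), EWMA smoothing, then downsampling -- the conditioning applied to
#' every record before drift correction and segmentation.
#'
#' @param trace A `mot_trace`.
#' @param target_rate Decimation target, Hz.
#' @param window EWMA window, samples.
#' @param factor Downsample factor.
#' @return List with `dec` (decimated, unsmoothed full-rate record; jump
#'   detection runs here so amplitudes and transition times are not
#'   distorted by the smoother), `full` (decimated + smoothed, full rate)
#'   and `ds` (additionally downsampled; used for segmentation).
#' @export
preprocess_trace <- function(trace, target_rate = 3000, window = 20,
                             factor = 100) {
  assert_trace(trace)
  if (sample_rate(trace) > target_rate) {
    trace <- decimate_trace(trace, target_rate)
  }
  full <- ewma_trace(trace, window)
  list(dec = trace, full = full, ds = downsample_trace(full, factor))
}
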