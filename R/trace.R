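#' Construct a bead-position trace
#'
#' A trace is a uniformly sampled record of bead position projected on the
#' motility axis, stored as a tibble with columns `t` (s), `x` (nm) and an
#' optional per-sample force channel `f` (pN, assisting load positive).
#' Sampling rate, metadata (substrate, construct, temperature, record id) and
#' an append-only processing history travel along as attributes.
#'
#' @param t Time stamps in seconds, strictly increasing and uniform.
#' @param x Bead position in nm along the motility axis.
#' @param f Optional per-sample force in pN (assisting load positive).
#' @param sample_rate Sampling rate in Hz. Inferred from `t` when missing.
#' @param meta Named list of metadata. Recognised fields: `record_id`,
#'   `substrate` (`"CI"`, `"CIII"`, `"FP"`), `construct` (`"intact"`,
#'   `"CD-only"`, `"control"`), `temperature` (deg C).
#' @param history Character vector of processing steps already applied.
#' @return A `mot_trace` tibble.
#' @export
new_trace <- function(t, x, f = NULL, sample_rate = NULL, meta = list(),
                      history = character()) {
  if (length(t) != length(x)) stopf("t and x must have equal length")
  if (!is.null(f) && length(f) != length(t)) {
    stopf("force channel must match trace length")
  }
  if (length(t) >= 2) {
    if (any(diff(t) <= 0)) stopf("t must be strictly increasing")
    dt <- (t[length(t)] - t[1]) / (length(t) - 1)
    grid <- t[1] + (seq_along(t) - 1) * dt
    # uniform within 1e-9 of the span (floating accumulation allowed)
    if (max(abs(t - grid)) > 1e-9 * max(abs(t[length(t)] - t[1]), 1)) {
      stopf("t must be uniformly spaced (relative tolerance 1e-9)")
    }
    if (is.null(sample_rate)) sample_rate <- 1 / dt
  }
  if (is.null(sample_rate)) stopf("sample_rate required for length-1 traces")
  out <- if (is.null(f)) {
    tibble::tibble(t = as.numeric(t), x = as.numeric(x))
  } else {
    tibble::tibble(t = as.numeric(t), x = as.numeric(x), f = as.numeric(f))
  }
  structure(
    out,
    sample_rate = as.numeric(sample_rate),
    meta = meta,
    history = history,
    class = c("mot_trace", class(out))
  )
}

#' @export
print.mot_trace <- function(x, ...) {
  cat(sprintf(
    "<mot_trace> %d samples @ %g Hz (%.1f s)%s\n",
    nrow(x), attr(x, "sample_rate"), nrow(x) / attr(x, "sample_rate"),
    if ("f" %in% names(x)) ", force channel" else ""
  ))
  meta <- attr(x, "meta")
  if (length(meta)) {
    cat("  meta:", paste(names(meta), unlist(meta), sep = "=", collapse = ", "), "\n")
  }
  hist <- attr(x, "history")
  if (length(hist)) cat("  history:", paste(hist, collapse = " -> "), "\n")
  NextMethod()
}

#' Sampling rate of a trace
#' @param trace A `mot_trace`.
#' @return Sampling rate in Hz.
#' @export
sample_rate <- function(trace) attr(trace, "sample_rate")

#' Trace metadata
#' @param trace A `mot_trace`.
#' @return Named list of metadata.
#' @export
trace_meta <- function(trace) attr(trace, "meta")

# rebuild a trace keeping metadata, appending a history entry
retrace <- function(trace, t, x, f = NULL, sample_rate = NULL, step = NULL) {
  hist <- attr(trace, "history")
  if (!is.null(step)) hist <- c(hist, step)
  new_trace(
    t, x, f,
    sample_rate = if (is.null(sample_rate)) attr(trace, "sample_rate") else sample_rate,
    meta = attr(trace, "meta"),
    history = hist
  )
}

trace_force <- function(trace) if ("f" %in% names(trace)) trace$f else NULL

assert_trace <- function(trace) {
  if (!inherits(trace, "mot_trace")) stopf("expected a mot_trace object")
  invisible(trace)
}
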