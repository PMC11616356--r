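#' Configuration for the synthetic trace generator
#'
#' Defines the generative model for synthetic bead-position records: a
#' continuous-time three-state Markov chain (forward / backward / paused)
#' with exponential dwell times, exponential per-visit speeds, slow
#' instrumental drift, i.i.d. Gaussian position noise at full bandwidth, and
#' rare abrupt displacements completing within milliseconds.
#'
#' Moving-state speeds are drawn as `motility_floor + Exp(mean)`, i.e. the
#' reported exponential speed law conditioned on exceeding the pause
#' classification threshold: the generator's states are the observable
#' motility categories, so a visit labelled "forward" is by construction one
#' that moves faster than the threshold. Pause-state residual speeds are
#' unconditional `Exp(pause_speed_mean)` with random sign, so the classifier
#' is exercised nontrivially in both directions.
#'
#' @param sample_rate Sampling rate, Hz.
#' @param duration Record duration, s.
#' @param state_means Mean exponential dwell times (s) for the forward,
#'   backward and pause states.
#' @param occupancy_targets Stationary fractions of time in the forward,
#'   backward and pause states; must sum to 1.
#' @param v_forward_mean,v_backward_mean Exponential mean of the speed excess
#'   above `motility_floor` for forward / backward visits, nm/s.
#' @param pause_speed_mean Mean residual speed during pauses, nm/s (random
#'   sign).
#' @param motility_floor Speed threshold defining the moving states, nm/s.
#' @param noise_sd Per-sample Gaussian position noise at full bandwidth, nm.
#' @param drift_rate_scale Residual instrumental drift scale, nm/s: the
#'   straight-line fit to the drift path over the record has this absolute
#'   slope (random sign).
#' @param drift_corr_time Correlation time of the drift increment process, s.
#'   The default makes drift nearly linear over a ~150 s record, consistent
#'   with straight-line fits describing control records well.
#' @param jump_rate Abrupt-displacement rate, events/s.
#' @param jump_amp_range Displacement amplitude range, nm.
#' @param jump_risetime_range 10--90% transition-time range, s.
#' @param jump_reversible_frac Fraction of jumps paired with an opposite-sign
#'   partner of equal magnitude.
#' @param jump_partner_gap Delay range between a jump and its reversible
#'   partner, s.
#' @param tether_contour DNA tether contour length, nm (1010 bp at 0.34
#'   nm/bp).
#' @param trap_stiffness Trap stiffness, pN/nm; when set, a force channel
#'   `f = trap_stiffness * x` is emitted.
#' @param seed Integer seed; identical seed and config give bit-identical
#'   output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(sample_rate = 3000,
                       duration = 150,
                       state_means = c(forward = 15, backward = 15, pause = 15),
                       occupancy_targets = c(forward = 0.41, backward = 0.20, pause = 0.39),
                       v_forward_mean = 0.17,
                       v_backward_mean = 0.11,
                       pause_speed_mean = 0.03,
                       motility_floor = 0.085,
                       noise_sd = 2.0,
                       drift_rate_scale = 0.037,
                       drift_corr_time = 1000,
                       jump_rate = 0.005,
                       jump_amp_range = c(5, 20),
                       jump_risetime_range = c(0.001, 0.01),
                       jump_reversible_frac = 0.3,
                       jump_partner_gap = c(1, 5),
                       tether_contour = 1010 * 0.34,
                       trap_stiffness = NULL,
                       seed = NULL) {
  cfg <- list(
    sample_rate = sample_rate, duration = duration,
    state_means = state_means, occupancy_targets = occupancy_targets,
    v_forward_mean = v_forward_mean, v_backward_mean = v_backward_mean,
    pause_speed_mean = pause_speed_mean, motility_floor = motility_floor,
    noise_sd = noise_sd, drift_rate_scale = drift_rate_scale,
    drift_corr_time = drift_corr_time, jump_rate = jump_rate,
    jump_amp_range = jump_amp_range, jump_risetime_range = jump_risetime_range,
    jump_reversible_frac = jump_reversible_frac,
    jump_partner_gap = jump_partner_gap,
    tether_contour = tether_contour, trap_stiffness = trap_stiffness,
    seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$duration <= 0) stopf("duration must be > 0")
  if (cfg$sample_rate <= 0) stopf("sample_rate must be > 0")
  occ <- cfg$occupancy_targets
  if (length(occ) != 3 || abs(sum(occ) - 1) > 1e-9) {
    stopf("occupancy_targets must be 3 fractions summing to 1 (tol 1e-9)")
  }
  if (any(occ <= 0)) stopf("occupancy_targets must be strictly positive")
  if (any(cfg$state_means <= 0)) stopf("state dwell means must be positive")
  pos <- c(cfg$v_forward_mean, cfg$v_backward_mean, cfg$pause_speed_mean)
  if (any(pos <= 0)) stopf("speed means must be strictly positive")
  if (cfg$noise_sd < 0 || cfg$drift_rate_scale < 0 || cfg$jump_rate < 0) {
    stopf("noise_sd, drift_rate_scale and jump_rate must be non-negative")
  }
  if (cfg$jump_amp_range[1] < 0) stopf("jump amplitude lower bound must be >= 0")
  if (cfg$drift_corr_time <= 0) stopf("drift_corr_time must be positive")
  # embedded-chain weights must admit non-negative symmetric flows
  nu <- occ / cfg$state_means
  nu <- nu / sum(nu)
  if (any(nu > 0.5 + 1e-12)) {
    stopf("occupancy/dwell combination not realizable by a 3-state chain")
  }
  invisible(cfg)
}

# Embedded transition matrix (zero diagonal) with stationary weights nu,
# built from symmetric pairwise flows F_ij = (nu_i + nu_j - nu_k)/2.
embedded_chain <- function(nu) {
  f12 <- (nu[1] + nu[2] - nu[3]) / 2
  f13 <- (nu[1] + nu[3] - nu[2]) / 2
  f23 <- (nu[2] + nu[3] - nu[1]) / 2
  P <- rbind(
    c(0, f12, f13) / nu[1],
    c(f12, 0, f23) / nu[2],
    c(f13, f23, 0) / nu[3]
  )
  rownames(P) <- colnames(P) <- c("forward", "backward", "pause")
  P
}

# Draw the hidden state path: states, dwell times, per-visit velocities.
draw_state_path <- function(cfg) {
  states <- c("forward", "backward", "pause")
  occ <- cfg$occupancy_targets
  means <- cfg$state_means
  nu <- occ / means
  nu <- nu / sum(nu)
  P <- embedded_chain(nu)
  t_now <- 0
  s <- sample(3L, 1L, prob = occ) # start from stationary time fractions
  rows_s <- integer(0)
  rows_d <- numeric(0)
  while (t_now < cfg$duration) {
    d <- stats::rexp(1L, rate = 1 / means[s])
    rows_s <- c(rows_s, s)
    rows_d <- c(rows_d, d)
    t_now <- t_now + d
    s <- sample(3L, 1L, prob = P[s, ])
  }
  # truncate final dwell at the record end
  t_end <- cumsum(rows_d)
  t_start <- c(0, t_end[-length(t_end)])
  t_end[length(t_end)] <- cfg$duration
  keep <- t_start < cfg$duration
  t_start <- t_start[keep]
  t_end <- pmin(t_end[keep], cfg$duration)
  st <- states[rows_s[keep]]
  v <- vapply(st, function(s) {
    switch(s,
      forward = cfg$motility_floor + stats::rexp(1L, 1 / cfg$v_forward_mean),
      backward = -(cfg$motility_floor + stats::rexp(1L, 1 / cfg$v_backward_mean)),
      pause = sample(c(-1, 1), 1L) * stats::rexp(1L, 1 / cfg$pause_speed_mean)
    )
  }, numeric(1))
  tibble::tibble(t_start = t_start, t_end = t_end, state = st, velocity = unname(v))
}

#' Generate a smooth instrumental drift path
#'
#' A straight trend of absolute slope `rate_scale` (random sign) plus a
#' smooth zero-trend fluctuation: integrated AR(1)-filtered Gaussian
#' increments, detrended, and scaled so the fluctuation's instantaneous
#' slope has RMS `fluct_frac * rate_scale`. The straight-line fit to the
#' whole path therefore has absolute slope close to `rate_scale`, while the
#' path is not exactly linear. With `rate_scale = 0` the path is
#' identically zero.
#'
#' @param duration Path duration, s.
#' @param rate_scale Target absolute straight-line slope, nm/s.
#' @param corr_time Correlation time of the increment process, s.
#' @param fluct_frac RMS instantaneous slope of the fluctuation, as a
#'   fraction of `rate_scale`.
#' @param dt Grid spacing, s.
#' @param seed Optional integer seed.
#' @return Tibble with columns `t` (s) and `d` (nm); linear interpolation
#'   between grid points reproduces the drift applied to simulated samples
#'   exactly.
#' @export
make_drift_path <- function(duration, rate_scale, corr_time = 1000,
                            fluct_frac = 0.3, dt = 1, seed = NULL) {
  with_seed(seed, {
    tc <- seq(0, duration, by = dt)
    if (tc[length(tc)] < duration) tc <- c(tc, duration)
    n <- length(tc)
    if (rate_scale <= 0 || n < 3) {
      return(tibble::tibble(t = tc, d = numeric(n)))
    }
    trend <- sample(c(-1, 1), 1L) * rate_scale * tc
    rho <- exp(-dt / corr_time)
    e <- stats::rnorm(n)
    z <- as.numeric(stats::filter(e * sqrt(1 - rho^2), rho, method = "recursive",
                                  init = stats::rnorm(1)))
    f <- cumsum(z) * dt
    f <- f - f[1] - ols_line(tc, f - f[1])$slope * tc # detrend
    slope_rms <- stats::sd(diff(f)) / dt
    if (slope_rms > 1e-12) {
      f <- f * (fluct_frac * rate_scale / slope_rms)
    }
    tibble::tibble(t = tc, d = trend + f)
  })
}

draw_jumps <- function(cfg) {
  empty <- tibble::tibble(
    t = numeric(0), amplitude = numeric(0), risetime = numeric(0),
    partner = integer(0)
  )
  margin <- 5
  span <- cfg$duration - 2 * margin
  if (cfg$jump_rate <= 0 || span <= 0) return(empty)
  n <- stats::rpois(1L, cfg$jump_rate * span)
  if (n == 0L) return(empty)
  t <- sort(stats::runif(n, margin, cfg$duration - margin))
  amp <- stats::runif(n, cfg$jump_amp_range[1], cfg$jump_amp_range[2]) *
    sample(c(-1, 1), n, replace = TRUE)
  rise <- stats::runif(n, cfg$jump_risetime_range[1], cfg$jump_risetime_range[2])
  ev <- tibble::tibble(t = t, amplitude = amp, risetime = rise,
                       partner = NA_integer_)
  # reversible toggling: pair a fraction with an opposite-sign partner
  rev <- which(stats::runif(n) < cfg$jump_reversible_frac)
  for (i in rev) {
    tp <- ev$t[i] + stats::runif(1, cfg$jump_partner_gap[1], cfg$jump_partner_gap[2])
    if (tp > cfg$duration - margin) next
    ev <- tibble::add_row(ev,
      t = tp, amplitude = -ev$amplitude[i],
      risetime = stats::runif(1, cfg$jump_risetime_range[1], cfg$jump_risetime_range[2]),
      partner = i
    )
    ev$partner[i] <- nrow(ev)
  }
  ord <- order(ev$t)
  remap <- match(seq_len(nrow(ev)), ord)
  ev <- ev[ord, ]
  ev$partner <- remap[ev$partner]
  ev
}

# smooth sigmoidal step: 10-90% width equals risetime
jump_waveform <- function(t, events) {
  x <- numeric(length(t))
  if (nrow(events) == 0) return(x)
  for (i in seq_len(nrow(events))) {
    s <- events$risetime[i] / (2 * log(9))
    x <- x + events$amplitude[i] * stats::plogis((t - events$t[i]) / s)
  }
  x
}

new_sim_truth <- function(state_path, drift_path, jump_events, duration) {
  structure(
    list(
      state_path = state_path,
      drift_path = drift_path,
      jump_events = jump_events,
      net_displacement = sum(state_path$velocity *
                               (state_path$t_end - state_path$t_start)) +
        sum(jump_events$amplitude),
      duration = duration
    ),
    class = "sim_truth"
  )
}

#' Reconstruct the noise-free position implied by a ground truth
#'
#' Sum of the piecewise-linear motility path, the linearly interpolated drift
#' path and the sigmoidal jump waveforms at the requested times.
#'
#' @param truth A `sim_truth` object.
#' @param t Times (s) at which to evaluate.
#' @return Numeric vector of positions, nm.
#' @export
truth_position <- function(truth, t) {
  sp <- truth$state_path
  dur <- sp$t_end - sp$t_start
  start_pos <- c(0, cumsum(sp$velocity * dur))[seq_len(nrow(sp))]
  k <- findInterval(t, sp$t_start, rightmost.closed = TRUE)
  k[k < 1] <- 1L
  mot <- start_pos[k] + sp$velocity[k] * (pmin(t, sp$t_end[k]) - sp$t_start[k])
  drift <- if (nrow(truth$drift_path) >= 2) {
    stats::approx(truth$drift_path$t, truth$drift_path$d, xout = t, rule = 2)$y
  } else {
    numeric(length(t))
  }
  mot + drift + jump_waveform(t, truth$jump_events)
}

#' Simulate a single-enzyme motility record
#'
#' Draws a three-state (forward / backward / paused) Markov path with
#' exponential dwells, per-visit speeds, residual instrumental drift, abrupt
#' displacements and i.i.d. Gaussian position noise, and returns both the
#' observable trace and the generating ground truth.
#'
#' @param config A [sim_config()].
#' @return A list with elements `trace` (a [new_trace()] tibble) and `truth`
#'   (a `sim_truth`: state path, drift path, jump events, net displacement).
#' @examples
#' rec <- simulate_motility_record(sim_config(duration = 60, seed = 1))
#' rec$truth$state_path
#' @export
simulate_motility_record <- function(config = sim_config()) {
  validate_sim_config(config)
  with_seed(config$seed, {
    sp <- draw_state_path(config)
    drift <- make_drift_path(config$duration, config$drift_rate_scale,
                             config$drift_corr_time)
    jumps <- draw_jumps(config)
    truth <- new_sim_truth(sp, drift, jumps, config$duration)
    n <- floor(config$duration * config$sample_rate)
    t <- (seq_len(n) - 1) / config$sample_rate
    x <- truth_position(truth, t) + stats::rnorm(n, 0, config$noise_sd)
    f <- if (!is.null(config$trap_stiffness)) config$trap_stiffness * x else NULL
    trace <- new_trace(
      t, x, f,
      sample_rate = config$sample_rate,
      meta = list(construct = "intact", substrate = "CI", temperature = 21),
      history = "simulated"
    )
    list(trace = trace, truth = truth)
  })
}

#' Simulate an enzyme-free control record
#'
#' A fixed-tether bead record: no motility states and no jumps, only residual
#' instrumental drift (post-correction scale) plus position noise. The ground
#' truth state path is a single "fixed" interval at zero velocity.
#'
#' @inheritParams simulate_motility_record
#' @return As [simulate_motility_record()].
#' @export
simulate_control_record <- function(config = sim_config()) {
  validate_sim_config(config)
  with_seed(config$seed, {
    sp <- tibble::tibble(
      t_start = 0, t_end = config$duration, state = "fixed", velocity = 0
    )
    drift <- make_drift_path(config$duration, config$drift_rate_scale,
                             config$drift_corr_time)
    truth <- new_sim_truth(
      sp, drift,
      tibble::tibble(t = numeric(0), amplitude = numeric(0),
                     risetime = numeric(0), partner = integer(0)),
      config$duration
    )
    n <- floor(config$duration * config$sample_rate)
    t <- (seq_len(n) - 1) / config$sample_rate
    x <- truth_position(truth, t) + stats::rnorm(n, 0, config$noise_sd)
    f <- if (!is.null(config$trap_stiffness)) config$trap_stiffness * x else NULL
    trace <- new_trace(
      t, x, f,
      sample_rate = config$sample_rate,
      meta = list(construct = "control", substrate = NA, temperature = 21),
      history = "simulated-control"
    )
    list(trace = trace, truth = truth)
  })
}

#' Render fiducial-marker video frames for a drift path
#'
#' Each frame holds `n_markers` Gaussian spots displaced along the motility
#' axis by the drift path sampled at the frame times, plus shot-like pixel
#' noise. Used to exercise the cross-correlation drift tracker against a
#' known injected path.
#'
#' @param drift_path Tibble with columns `t` (s) and `d` (nm), e.g. from
#'   [make_drift_path()].
#' @param frame_rate Video frame rate, Hz (0.5--1 Hz typical).
#' @param n_markers Number of markers (>= 2 for averaging).
#' @param psf_sd Point-spread-function width, px.
#' @param nm_per_px Camera calibration, nm per pixel.
#' @param axis Unit vector of the motility axis in the image plane.
#' @param amplitude,baseline Spot peak and background intensity, counts.
#' @param seed Optional integer seed for the pixel noise.
#' @return A list: `frames` (h x w x n_frames array of counts), `tracks`
#'   (true marker tracks: frame, t, marker, x_px, y_px, d_nm), `rois` (one
#'   pixel rectangle `c(x0, y0, x1, y1)` per marker), `frame_times`,
#'   `nm_per_px`.
#' @export
simulate_fiducial_frames <- function(drift_path, frame_rate = 1, n_markers = 2,
                                     psf_sd = 1.5, nm_per_px = 100,
                                     axis = c(1, 0), amplitude = 20000,
                                     baseline = 100, seed = NULL) {
  if (nm_per_px <= 0) stopf("nm_per_px must be positive")
  if (n_markers < 1) stopf("need at least one marker")
  axis <- axis / sqrt(sum(axis^2))
  with_seed(seed, {
    t_frames <- seq(0, max(drift_path$t), by = 1 / frame_rate)
    d_nm <- stats::approx(drift_path$t, drift_path$d, xout = t_frames, rule = 2)$y
    cell <- 48L
    h <- cell
    w <- cell * n_markers
    centers <- cbind(x = cell * (seq_len(n_markers) - 0.5), y = cell / 2)
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    frames <- array(0, dim = c(h, w, length(t_frames)))
    tracks <- vector("list", length(t_frames))
    for (i in seq_along(t_frames)) {
      disp_px <- d_nm[i] / nm_per_px * axis
      img <- matrix(baseline, h, w)
      for (m in seq_len(n_markers)) {
        cx <- centers[m, "x"] + disp_px[1]
        cy <- centers[m, "y"] + disp_px[2]
        img <- img + amplitude * exp(-((xx - cx)^2 + (yy - cy)^2) / (2 * psf_sd^2))
      }
      img <- img + stats::rnorm(length(img), 0, sqrt(pmax(img, 1)))
      frames[, , i] <- pmin(pmax(round(img), 0), 65535)
      tracks[[i]] <- tibble::tibble(
        frame = i, t = t_frames[i], marker = seq_len(n_markers),
        x_px = centers[, "x"] + disp_px[1], y_px = centers[, "y"] + disp_px[2],
        d_nm = d_nm[i]
      )
    }
    rois <- lapply(seq_len(n_markers), function(m) {
      c(
        x0 = as.integer(centers[m, "x"] - 15), y0 = as.integer(centers[m, "y"] - 15),
        x1 = as.integer(centers[m, "x"] + 16), y1 = as.integer(centers[m, "y"] + 16)
      )
    })
    list(
      frames = frames, tracks = dplyr::bind_rows(tracks), rois = rois,
      frame_times = t_frames, nm_per_px = nm_per_px, axis = axis
    )
  })
}

#' Add a drift path to a trace
#'
#' Linearly interpolates a drift path to the trace time base and adds it to
#' the position channel. Used to inject a common instrument drift that is
#' shared with fiducial-marker video and later removed by [correct_drift()].
#'
#' @param trace A `mot_trace`.
#' @param drift_path Tibble with columns `t`, `d`.
#' @return The trace with drift added (history records the step).
#' @export
add_drift <- function(trace, drift_path) {
  assert_trace(trace)
  d <- stats::approx(drift_path$t, drift_path$d, xout = trace$t, rule = 2)$y
  retrace(trace, trace$t, trace$x + d, trace_force(trace), step = "drift-added")
}

#' Write fiducial frames as a multi-page 16-bit TIFF
#'
#' @param frames h x w x n array of counts (0--65535).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fiducial_tiff <- function(frames, path) {
  pages <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF stack into a frame array
#'
#' @param path TIFF file path.
#' @return h x w x n array of counts.
#' @export
read_fiducial_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]] * 65535
  arr
}
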