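make_shifted_stack <- function(shifts_px, psf_sd = 1.5, size = 33,
                               amplitude = 20000, noise = TRUE, seed = 1) {
  set.seed(seed)
  c0 <- (size + 1) / 2
  yy <- matrix(seq_len(size), size, size)
  xx <- t(yy)
  frames <- array(0, dim = c(size, size, nrow(shifts_px)))
  for (i in seq_len(nrow(shifts_px))) {
    img <- 100 + amplitude *
      exp(-((xx - c0 - shifts_px[i, 1])^2 + (yy - c0 - shifts_px[i, 2])^2) /
            (2 * psf_sd^2))
    if (noise) img <- img + rnorm(length(img), 0, sqrt(img))
    frames[, , i] <- img
  }
  frames
}

test_that("identical frames track to zero displacement", {
  st <- make_shifted_stack(cbind(rep(0, 5), rep(0, 5)), noise = FALSE)
  tr <- track_marker(st, c(1, 1, 33, 33))
  expect_equal(tr$dx_px, rep(0, 5), tolerance = 1e-9)
  expect_equal(tr$dy_px, rep(0, 5), tolerance = 1e-9)
  expect_true(all(tr$quality > 0.99))
})

test_that("integer and sub-pixel shifts are recovered", {
  # integer shift (3, -2) px, noise-free: exact
  st <- make_shifted_stack(rbind(c(0, 0), c(3, -2)), noise = FALSE)
  tr <- track_marker(st, c(1, 1, 33, 33))
  expect_equal(tr$dx_px[2], 3, tolerance = 1e-6)
  expect_equal(tr$dy_px[2], -2, tolerance = 1e-6)
  # 0.4 px sub-pixel shift with shot noise: within 0.1 px
  st2 <- make_shifted_stack(rbind(c(0, 0), c(0.4, 0.4)), seed = 2)
  tr2 <- track_marker(st2, c(1, 1, 33, 33))
  expect_equal(tr2$dx_px[2], 0.4, tolerance = 0.1)
  expect_equal(tr2$dy_px[2], 0.4, tolerance = 0.1)
})

test_that("tracking a flat ROI fails with a diagnostic", {
  st <- array(7, dim = c(16, 16, 3))
  expect_error(track_marker(st, c(1, 1, 16, 16)), "flat ROI")
  expect_error(track_marker(st[, , 1, drop = FALSE], c(1, 1, 16, 16)), "2 frames")
  expect_error(track_marker(st, c(1, 1, 40, 16)), "bounds")
})

test_that("tracked fiducial positions match the injected drift within 0.2 px", {
  dp <- make_drift_path(120, 0.2, seed = 31)
  fid <- simulate_fiducial_frames(dp, frame_rate = 1, nm_per_px = 100, seed = 32)
  for (m in 1:2) {
    tr <- track_marker(fid$frames, fid$rois[[m]], fid$frame_times,
                       fid$nm_per_px)
    truth_px <- (fid$tracks$d_nm[fid$tracks$marker == m] -
                   fid$tracks$d_nm[fid$tracks$marker == m][1]) / fid$nm_per_px
    expect_lt(sqrt(mean((tr$dx_px - truth_px)^2)), 0.2)
  }
})

test_that("averaging two noisy tracks reduces RMS error by about 1/sqrt(2)", {
  set.seed(5)
  n <- 400
  truth <- 0.05 * (0:(n - 1))
  mk <- function() {
    structure(
      tibble::tibble(
        frame = 1:n, t = 0:(n - 1),
        dx_px = truth + rnorm(n, 0, 1), dy_px = 0,
        dx_nm = truth + rnorm(n, 0, 1), dy_nm = 0, quality = 1
      ),
      class = c("marker_track", class(tibble::tibble()))
    )
  }
  rms <- function(tracks) {
    d <- combine_and_smooth(tracks, smooth_window = 1)
    sqrt(mean((d$d - (truth - truth[1]))^2))
  }
  r2 <- mean(replicate(20, rms(list(mk(), mk()))))
  r1 <- mean(replicate(20, suppressWarnings(rms(list(mk())))))
  expect_equal(r2 / r1, 1 / sqrt(2), tolerance = 0.12)
  expect_warning(combine_and_smooth(list(mk())), "single marker")
})

test_that("combine_and_smooth preserves a linear drift exactly", {
  n <- 100
  lin <- structure(
    tibble::tibble(frame = 1:n, t = 0:(n - 1), dx_px = 0.3 * (0:(n - 1)),
                   dy_px = 0, dx_nm = 30 * (0:(n - 1)), dy_nm = 0, quality = 1),
    class = c("marker_track", class(tibble::tibble()))
  )
  d <- combine_and_smooth(list(lin, lin), smooth_window = 20)
  expect_equal(d$d, 30 * (0:(n - 1)), tolerance = 1e-9)
  bad <- lin
  bad$t <- bad$t + 0.5
  expect_error(combine_and_smooth(list(lin, bad)), "share frame times")
})

test_that("drift subtraction is exact, invertible and span-checked", {
  # a fixed tether seen through 0.05 nm/s of linear drift
  tr <- make_ramp_trace(slope = 0.05, duration = 50, rate = 30, intercept = 1)
  drift <- tibble::tibble(t = seq(0, 50, by = 1), d = 0.05 * seq(0, 50, by = 1))
  corr <- correct_drift(tr, drift)
  fit <- fit_segment(corr, 1, 49)
  expect_lt(abs(fit$velocity), 0.005)
  # zero drift is the identity
  zd <- tibble::tibble(t = c(0, 50), d = c(0, 0))
  expect_equal(correct_drift(tr, zd)$x, tr$x)
  # round trip with the negated drift
  neg <- drift
  neg$d <- -neg$d
  expect_equal(correct_drift(correct_drift(tr, drift), neg)$x, tr$x,
               tolerance = 1e-9)
  short <- tibble::tibble(t = c(10, 20), d = c(0, 1))
  expect_error(correct_drift(tr, short), "cover")
})

test_that("corrected synthetic records match ground-truth motility", {
  # known injected drift, rendered to fiducial frames, tracked and removed
  cfg <- sim_config(duration = 120, drift_rate_scale = 0, jump_rate = 0,
                    seed = 77)
  rec <- simulate_motility_record(cfg)
  common <- make_drift_path(120, 0.2, seed = 78)
  trace <- add_drift(rec$trace, common)
  fid <- simulate_fiducial_frames(common, frame_rate = 1, seed = 79)
  tracks <- lapply(1:2, function(m) {
    track_marker(fid$frames, fid$rois[[m]], fid$frame_times, fid$nm_per_px)
  })
  est <- combine_and_smooth(tracks)
  pp <- preprocess_trace(trace)
  corr <- correct_drift(pp$ds, est)
  resid <- corr$x - truth_position(rec$truth, corr$t)
  expect_lt(sqrt(mean(resid^2)), cfg$noise_sd)
})

test_that("z-drift QC flags decaying quality and never flags at threshold 0", {
  mk <- function(quality) {
    structure(
      tibble::tibble(frame = seq_along(quality), t = seq_along(quality) - 1,
                     dx_px = 0, dy_px = 0, dx_nm = 0, dy_nm = 0,
                     quality = quality),
      class = c("marker_track", class(tibble::tibble()))
    )
  }
  good <- qc_z_drift(list(mk(rep(0.95, 40))), threshold = 0.5)
  expect_false(attr(good, "flagged"))
  bad <- qc_z_drift(list(mk(seq(1.0, 0.3, length.out = 40))), threshold = 0.5)
  expect_true(attr(bad, "flagged"))
  none <- qc_z_drift(list(mk(seq(1.0, 0.3, length.out = 40))), threshold = 0)
  expect_false(attr(none, "flagged"))
})

test_that("defocus blur degrades tracking quality enough to be flagged", {
  dp <- tibble::tibble(t = 0:39, d = rep(0, 40))
  fid <- simulate_fiducial_frames(dp, frame_rate = 1, seed = 41)
  # progressive defocus: growing blur via a widening PSF re-render
  frames <- fid$frames
  still <- tibble::tibble(t = c(0, 1), d = c(0, 0))
  for (i in seq_len(dim(frames)[3])) {
    grow <- 1 + 4 * (i - 1) / (dim(frames)[3] - 1)
    f2 <- simulate_fiducial_frames(still, frame_rate = 1,
                                   psf_sd = 1.5 * grow,
                                   amplitude = 20000 / grow^2, seed = 50 + i)
    frames[, , i] <- f2$frames[, , 1]
  }
  tr <- track_marker(frames, fid$rois[[1]])
  qc <- qc_z_drift(list(tr), threshold = 0.5)
  expect_true(attr(qc, "flagged"))
})
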