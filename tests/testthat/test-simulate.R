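test_that("config validation enforces the generator invariants", {
  expect_error(sim_config(duration = 0), "duration")
  expect_error(sim_config(sample_rate = -1), "sample_rate")
  expect_error(sim_config(occupancy_targets = c(0.5, 0.3, 0.3)), "sum")
  expect_error(sim_config(v_forward_mean = 0), "positive")
  expect_error(sim_config(jump_amp_range = c(-1, 5)), "amplitude")
  # occupancy/dwell combinations whose embedded chain is infeasible
  expect_error(
    sim_config(occupancy_targets = c(0.9, 0.05, 0.05)),
    "not realizable"
  )
})

test_that("a forced noiseless forward state ramps exactly", {
  cfg <- sim_config(
    duration = 100, noise_sd = 0, drift_rate_scale = 0, jump_rate = 0,
    seed = 11
  )
  rec <- simulate_motility_record(cfg)
  # overwrite the state path with a single forced state and rebuild
  truth <- rec$truth
  truth$state_path <- tibble::tibble(
    t_start = 0, t_end = 100, state = "forward", velocity = 0.2
  )
  x <- truth_position(truth, rec$trace$t)
  expect_equal(x[1], 0)
  expect_equal(max(x), 0.2 * max(rec$trace$t), tolerance = 1e-12)
  expect_equal(diff(range(diff(x))), 0, tolerance = 1e-12)
})

test_that("same seed gives bit-identical records, different seeds differ", {
  a <- simulate_motility_record(sim_config(duration = 20, seed = 5))
  b <- simulate_motility_record(sim_config(duration = 20, seed = 5))
  c <- simulate_motility_record(sim_config(duration = 20, seed = 6))
  expect_identical(a$trace$x, b$trace$x)
  expect_identical(a$truth$state_path, b$truth$state_path)
  expect_false(identical(a$trace$x, c$trace$x))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_motility_record(sim_config(duration = 10, seed = 1)))
  expect_identical(before, .Random.seed)
})

test_that("state path tiles the record and net displacement is consistent", {
  rec <- simulate_motility_record(sim_config(duration = 500, seed = 2))
  sp <- rec$truth$state_path
  expect_equal(sp$t_start[1], 0)
  expect_equal(sp$t_end[nrow(sp)], 500)
  expect_equal(sp$t_start[-1], sp$t_end[-nrow(sp)], tolerance = 1e-9)
  net <- sum(sp$velocity * (sp$t_end - sp$t_start)) +
    sum(rec$truth$jump_events$amplitude)
  expect_equal(rec$truth$net_displacement, net, tolerance = 1e-6)
})

test_that("trace equals truth plus noise of the configured SD", {
  cfg <- sim_config(duration = 100, seed = 7) # 3e5 samples
  rec <- simulate_motility_record(cfg)
  resid <- rec$trace$x - truth_position(rec$truth, rec$trace$t)
  expect_lt(abs(mean(resid)), 0.05)
  expect_equal(sd(resid), cfg$noise_sd, tolerance = 0.05)
})

test_that("occupancy and dwell distributions match the configured process", {
  # dwell statistics depend only on the state path; a low sampling rate
  # keeps the trace rendering cheap
  cfg <- sim_config(duration = 3000, sample_rate = 50, seed = 3)
  # pool several records for >= 1000 dwells
  dwell <- list()
  occ <- c(forward = 0, backward = 0, pause = 0)
  for (s in 1:6) {
    cfg$seed <- 30 + s
    sp <- simulate_motility_record(cfg)$truth$state_path
    # drop boundary-truncated dwells for the KS test
    inner <- sp[-c(1, nrow(sp)), ]
    dwell[[s]] <- inner
    for (st in names(occ)) {
      occ[st] <- occ[st] + sum((sp$t_end - sp$t_start)[sp$state == st])
    }
  }
  dw <- dplyr::bind_rows(dwell)
  occ <- occ / sum(occ)
  expect_equal(unname(occ), c(0.41, 0.20, 0.39), tolerance = 0.15)
  for (st in c("forward", "backward", "pause")) {
    d <- dw$t_end[dw$state == st] - dw$t_start[dw$state == st]
    expect_gt(length(d), 150)
    ks <- suppressWarnings(ks.test(d, "pexp", rate = 1 / cfg$state_means[[st]]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("moving-state speeds exceed the motility floor; pauses are slow", {
  sp <- simulate_motility_record(sim_config(duration = 2000, seed = 9))$truth$state_path
  expect_true(all(sp$velocity[sp$state == "forward"] > 0.085))
  expect_true(all(sp$velocity[sp$state == "backward"] < -0.085))
  expect_lt(mean(abs(sp$velocity[sp$state == "pause"])), 0.085)
})

test_that("control records are drift plus noise with a single fixed state", {
  rec <- simulate_control_record(sim_config(
    duration = 50, noise_sd = 0, drift_rate_scale = 0, seed = 4
  ))
  expect_equal(rec$trace$x, rep(0, nrow(rec$trace)))
  expect_identical(rec$truth$state_path$state, "fixed")
  expect_equal(nrow(rec$truth$jump_events), 0L)
  a <- simulate_control_record(sim_config(duration = 20, seed = 8))
  b <- simulate_control_record(sim_config(duration = 20, seed = 8))
  expect_identical(a$trace$x, b$trace$x)
})

test_that("drift paths hit the requested straight-line slope scale", {
  slopes <- vapply(1:20, function(s) {
    dp <- make_drift_path(150, 0.037, seed = s)
    unname(stats::coef(stats::lm(dp$d ~ dp$t))[2])
  }, numeric(1))
  expect_equal(mean(abs(slopes)), 0.037, tolerance = 0.15)
  expect_gt(sum(slopes > 0), 2) # sign is random
  expect_gt(sum(slopes < 0), 2)
  expect_equal(make_drift_path(100, 0)$d, rep(0, 101))
})

test_that("jump waveforms complete within the configured risetimes", {
  cfg <- sim_config(duration = 1000, jump_rate = 0.02, noise_sd = 0,
                    drift_rate_scale = 0, seed = 21)
  rec <- simulate_motility_record(cfg)
  ev <- rec$truth$jump_events
  expect_gt(nrow(ev), 4)
  expect_true(all(abs(ev$amplitude) >= 5 & abs(ev$amplitude) <= 20))
  expect_true(all(ev$risetime >= 0.001 & ev$risetime <= 0.01))
  # partner structure is mutual and opposite-signed
  paired <- which(!is.na(ev$partner))
  for (i in paired) {
    j <- ev$partner[i]
    expect_identical(ev$partner[j], i)
    expect_equal(ev$amplitude[j], -ev$amplitude[i])
  }
})

test_that("fiducial frames carry markers that follow the drift path", {
  dp <- tibble::tibble(t = 0:100, d = 0.5 * (0:100)) # 50 nm linear
  fid <- simulate_fiducial_frames(dp, frame_rate = 1, nm_per_px = 100, seed = 2)
  expect_equal(dim(fid$frames)[3], 101)
  tr1 <- fid$tracks[fid$tracks$marker == 1, ]
  expect_equal(max(tr1$d_nm) - min(tr1$d_nm), 50)
  # zero drift: centroids stationary
  fid0 <- simulate_fiducial_frames(tibble::tibble(t = 0:20, d = rep(0, 21)),
                                   seed = 3)
  expect_equal(var(fid0$tracks$x_px[fid0$tracks$marker == 1]), 0)
  expect_error(simulate_fiducial_frames(dp, nm_per_px = -1), "nm_per_px")
})

test_that("fiducial TIFF round-trips through a 16-bit multipage file", {
  dp <- make_drift_path(10, 0.1, seed = 1)
  fid <- simulate_fiducial_frames(dp, frame_rate = 1, seed = 1)
  path <- withr::local_tempfile(fileext = ".tif")
  write_fiducial_tiff(fid$frames, path)
  back <- read_fiducial_tiff(path)
  expect_equal(dim(back), dim(fid$frames))
  expect_equal(back, fid$frames, tolerance = 1e-4)
})
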