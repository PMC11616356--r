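test_that("weighted exponential MLE equals the closed-form weighted mean", {
  f1 <- fit_exponential_weighted(c(1, 2, 3))
  expect_equal(f1$params$mean, 2)
  expect_equal(f1$n_obs, 3)
  expect_equal(f1$n_effective, 3)
  # N_R = floor(duration / 10): {30, 10} s -> weights {3, 1}
  f2 <- fit_exponential_weighted(c(1, 4), durations = c(30, 10))
  expect_equal(f2$params$mean, 1.75)
  expect_equal(f2$n_obs, 2)
  expect_equal(f2$n_effective, 4)
  expect_error(fit_exponential_weighted(numeric(0)), "empty")
  expect_error(fit_exponential_weighted(c(-1, 2)), "non-negative")
  expect_error(fit_exponential_weighted(c(1, 2), durations = c(30, 5)), "basis")
})

test_that("weighted-fit CIs calibrate against the exponential likelihood", {
  # independent oracle: unweighted MLE via fitdistrplus on a plain sample
  skip_if_not_installed("fitdistrplus")
  set.seed(4)
  v <- rexp(300, 1 / 0.17)
  f <- fit_exponential_weighted(v)
  alt <- fitdistrplus::fitdist(v, "exp")
  expect_equal(f$params$mean, 1 / unname(alt$estimate), tolerance = 1e-6)
  expect_lt(f$ci95$mean[1], 0.17)
  expect_gt(f$ci95$mean[2], 0.17)
  # chi-square CI width matches the large-sample 2/sqrt(n) rule
  expect_equal(diff(f$ci95$mean) / f$params$mean, 4 / sqrt(300),
               tolerance = 0.05)
})

test_that("truncated exponential MLE is exactly mean minus t0", {
  f <- fit_truncated_exponential(c(20, 30))
  expect_equal(f$params$tau, 15)
  expect_equal(f$params$mean, 25)
  expect_error(fit_truncated_exponential(c(5, 20)), "t0")
  expect_warning(fit_truncated_exponential(c(10, 10)), "degenerate")
  # Monte Carlo recovery: tau = 17, n = 200, within 2 SE = 2 tau / sqrt(n)
  set.seed(6)
  d <- 10 + rexp(200, 1 / 17)
  fr <- fit_truncated_exponential(d)
  expect_lt(abs(fr$params$tau - 17), 2 * 17 / sqrt(200))
  expect_lt(fr$ci95$tau[1], fr$params$tau)
})

test_that("EM mixture: monotone log-likelihood, beats the single fit", {
  set.seed(9)
  d <- 10 + c(rexp(250, 1 / 15), rexp(250, 1 / 120))
  fit <- fit_double_exponential_em(d)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  single <- fit_truncated_exponential(d)
  expect_gte(fit$loglik, single$loglik)
  expect_lte(fit$params$t1, fit$params$t2)
  expect_equal(fit$params$A1 + fit$params$A2, 1, tolerance = 1e-9)
})

test_that("EM recovers a 50/50 mixture of 15 s and 120 s within 2 SE", {
  set.seed(10)
  d <- 10 + c(rexp(250, 1 / 15), rexp(250, 1 / 120))
  fit <- fit_double_exponential_em(d)
  se <- function(p) (fit$ci95[[p]][2] - fit$params[[p]]) / 1.96
  expect_lt(abs(fit$params$t1 - 15), 2 * se("t1"))
  expect_lt(abs(fit$params$t2 - 120), 2 * se("t2"))
  expect_lt(abs(fit$params$A1 - 0.5), 2 * se("A1"))
})

test_that("EM on single-exponential data degenerates towards the single fit", {
  set.seed(11)
  d <- 10 + rexp(400, 1 / 30)
  fit <- suppressWarnings(fit_double_exponential_em(d))
  single <- fit_truncated_exponential(d)
  # likelihood-ratio improvement stays below the chi-square noise floor
  expect_lt(2 * (fit$loglik - single$loglik), qchisq(0.99, df = 2))
})

test_that("EM with a pinned single component reproduces the truncated MLE", {
  set.seed(12)
  d <- 10 + rexp(100, 1 / 20)
  fit <- suppressWarnings(fit_double_exponential_em(d, tol = 1e-8,
                                                    max_iter = 20000))
  single <- fit_truncated_exponential(d)
  # when the mixture collapses, its weighted mean matches tau-hat
  mix_mean <- fit$params$A1 * fit$params$t1 + fit$params$A2 * fit$params$t2
  expect_equal(mix_mean, single$params$tau, tolerance = 0.05 * single$params$tau)
})

test_that("pause threshold is the exponential quantile in closed form", {
  expect_equal(derive_pause_threshold(0.037, 0.90), 0.037 * log(10))
  expect_equal(round(derive_pause_threshold(0.037, 0.90), 4), 0.0852)
  expect_equal(derive_pause_threshold(1, 1 - 1 / exp(1)), 1)
  expect_equal(derive_pause_threshold(0.1, 0.5), 0.1 * log(2))
  expect_error(derive_pause_threshold(0.037, 1), "quantile")
  expect_error(derive_pause_threshold(0.037, 0), "quantile")
  # linear in mu, monotone in the quantile
  mus <- c(0.02, 0.04, 0.08)
  expect_equal(derive_pause_threshold(mus[3]) / derive_pause_threshold(mus[1]), 4)
  qs <- sapply(c(0.5, 0.7, 0.9, 0.99), derive_pause_threshold, control_fit = 0.05)
  expect_true(all(diff(qs) > 0))
  # accepts a control dist_fit
  ctl <- fit_exponential_weighted(rep(0.037, 5))
  expect_equal(derive_pause_threshold(ctl), 0.037 * log(10))
  expect_error(derive_pause_threshold(fit_truncated_exponential(c(20, 30))),
               "exponential")
})

test_that("an injected sigmoidal step is detected with correct amplitude", {
  set.seed(14)
  tr <- make_ramp_trace(slope = 0, duration = 20, rate = 3000, noise_sd = 2)
  tr <- inject_step(tr, 10, 12, 0.001)
  ev <- detect_jumps(tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$amplitude, 12, tolerance = 0.5)
  expect_equal(ev$t, 10, tolerance = 0.05)
  expect_lte(ev$transition_time, 0.0015)
})

test_that("control records produce no jump events at default thresholds", {
  for (s in 1:4) {
    rec <- simulate_control_record(sim_config(duration = 150, seed = 80 + s))
    ev <- detect_jumps(rec$trace)
    expect_equal(nrow(ev), 0)
  }
})

test_that("toggle pairs are detected and mutually partnered", {
  set.seed(15)
  tr <- make_ramp_trace(slope = 0, duration = 30, rate = 3000, noise_sd = 2)
  tr <- inject_step(tr, 10, 10, 0.002)
  tr <- inject_step(tr, 12, -10, 0.002)
  ev <- detect_jumps(tr)
  expect_equal(nrow(ev), 2)
  expect_equal(sort(ev$amplitude), c(-10, 10), tolerance = 0.6)
  expect_equal(ev$partner, c(2L, 1L))
  clean <- remove_jumps(tr, ev)
  expect_lt(abs(fit_segment(clean, 1, 29)$velocity), 0.1)
})

test_that("jump detection: recall and false positives on synthetic records", {
  cfg <- sim_config(duration = 150, jump_rate = 0.05,
                    jump_reversible_frac = 0, seed = 0)
  hits <- 0
  total <- 0
  fp <- 0
  for (s in 1:10) {
    cfg$seed <- 90 + s
    rec <- simulate_motility_record(cfg)
    ev <- detect_jumps(rec$trace)
    truth <- rec$truth$jump_events
    total <- total + nrow(truth)
    for (i in seq_len(nrow(truth))) {
      m <- which(abs(ev$t - truth$t[i]) < 0.5 &
                   sign(ev$amplitude) == sign(truth$amplitude[i]))
      if (length(m) > 0) hits <- hits + 1
    }
    matched <- sapply(seq_len(nrow(ev)), function(j) {
      any(abs(truth$t - ev$t[j]) < 0.5)
    })
    if (nrow(ev)) fp <- fp + sum(!matched)
  }
  expect_gt(total, 40)
  expect_gte(hits / total, 0.95)
  expect_lte(fp / (10 * 150) * 100, 0.01) # events per 100 s
})

test_that("tidy and glance expose fit parameters and diagnostics", {
  f <- fit_exponential_weighted(c(1, 4), durations = c(30, 10))
  td <- tidy(f)
  expect_equal(td$term, "mean")
  expect_equal(td$estimate, 1.75)
  expect_true(td$conf.low < 1.75 && td$conf.high > 1.75)
  g <- glance(f)
  expect_equal(g$family, "exp")
  expect_equal(g$n_effective, 4)
  set.seed(16)
  em <- fit_double_exponential_em(10 + c(rexp(100, 1 / 15), rexp(100, 1 / 100)))
  expect_true(glance(em)$converged)
  expect_equal(nrow(tidy(em)), length(em$params))
})
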