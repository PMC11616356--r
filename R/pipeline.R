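#' Pipeline configuration
#'
#' All module defaults in one place: conditioning rates, the minimum segment
#' duration, the control-derived pause threshold, the weight basis for
#' time-weighted velocity fits, the dwell-time truncation point, the EM
#' tolerance, the force bin width and the bootstrap replicate count. Every
#' [run_pipeline()] call can write the fully resolved configuration next to
#' its outputs.
#'
#' @param target_rate Decimation target, Hz.
#' @param ewma_window EWMA window, samples.
#' @param downsample Downsample factor.
#' @param min_duration Minimum retained segment duration, s.
#' @param pause_threshold Pause velocity threshold, nm/s.
#' @param weight_basis Time-weighting basis, s.
#' @param t0 Dwell-time truncation point, s.
#' @param em_tol EM convergence tolerance, s.
#' @param force_bin_width Force bin width, pN.
#' @param bootstrap_B Bootstrap replicates.
#' @param n_replicates Segmentation replicates.
#' @param penalty_scale Automatic changepoint penalty multiplier.
#' @param replicate_jitter Fractional penalty jitter across replicates.
#' @param jump_min_amplitude,jump_max_transition Jump-detection floor (nm)
#'   and maximum transition time (s).
#' @param drift_smooth_window Drift smoothing window, s.
#' @param seed Top-level seed; expanded per stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(target_rate = 3000, ewma_window = 20,
                            downsample = 100, min_duration = 10,
                            pause_threshold = 0.085, weight_basis = 10,
                            t0 = 10, em_tol = 1e-5, force_bin_width = 3.5,
                            bootstrap_B = 10000, n_replicates = 3,
                            penalty_scale = 3, replicate_jitter = 0.2,
                            jump_min_amplitude = 5, jump_max_transition = 0.01,
                            drift_smooth_window = 20, seed = NULL) {
  structure(
    list(
      target_rate = target_rate, ewma_window = ewma_window,
      downsample = downsample, min_duration = min_duration,
      pause_threshold = pause_threshold, weight_basis = weight_basis,
      t0 = t0, em_tol = em_tol, force_bin_width = force_bin_width,
      bootstrap_B = bootstrap_B, n_replicates = n_replicates,
      penalty_scale = penalty_scale, replicate_jitter = replicate_jitter,
      jump_min_amplitude = jump_min_amplitude,
      jump_max_transition = jump_max_transition,
      drift_smooth_window = drift_smooth_window, seed = seed
    ),
    class = "pipeline_config"
  )
}

process_one_record <- function(entry, config, drift_correct = TRUE) {
  trace <- if (inherits(entry, "mot_trace")) entry else entry$trace
  assert_trace(trace)
  pp <- preprocess_trace(trace, config$target_rate, config$ewma_window,
                         config$downsample)
  jumps <- detect_jumps(pp$dec,
                        min_amplitude = config$jump_min_amplitude,
                        max_transition = config$jump_max_transition)
  ds <- pp$ds
  qc <- NULL
  drift <- NULL
  fiducial <- if (!inherits(entry, "mot_trace")) entry$fiducial else NULL
  if (drift_correct && !is.null(fiducial)) {
    tracks <- lapply(seq_along(fiducial$rois), function(m) {
      track_marker(fiducial$frames, fiducial$rois[[m]],
                   frame_times = fiducial$frame_times,
                   nm_per_px = fiducial$nm_per_px)
    })
    qc <- qc_z_drift(tracks)
    drift <- combine_and_smooth(tracks, axis = fiducial$axis %||% c(1, 0),
                                smooth_window = config$drift_smooth_window)
    ds <- correct_drift(ds, drift)
  } else if (drift_correct && !inherits(entry, "mot_trace") &&
             !is.null(entry$tracks)) {
    tracks <- entry$tracks
    qc <- qc_z_drift(tracks)
    drift <- combine_and_smooth(tracks, smooth_window = config$drift_smooth_window)
    ds <- correct_drift(ds, drift)
  }
  ds <- remove_jumps(ds, jumps)
  seg_cfg <- segmentation_config(
    min_duration = config$min_duration,
    pause_threshold = config$pause_threshold,
    penalty_scale = config$penalty_scale,
    n_replicates = config$n_replicates,
    replicate_jitter = config$replicate_jitter
  )
  segments <- segment_record(ds, seg_cfg)
  list(trace = ds, jumps = jumps, drift = drift, qc = qc, segments = segments)
}

#' Run the full motility analysis pipeline
#'
#' Conditions each record (decimate, EWMA, downsample), detects and removes
#' abrupt displacements, applies fiducial-marker drift correction when
#' marker video or tracks accompany a record, segments each record in
#' replicate, classifies segments, extracts runs and pauses, fits the
#' velocity and dwell-time distributions, and tabulates the dataset
#' summary. Deterministic given the config seed.
#'
#' @param records A list of records: each element either a `mot_trace` or a
#'   list with elements `trace` (required), `fiducial` (optional, as
#'   returned by [simulate_fiducial_frames()]) or `tracks` (optional list
#'   of `marker_track`s).
#' @param config A [pipeline_config()].
#' @param drift_correct Apply drift correction where marker data exist.
#' @param fits Fit velocity and dwell-time distributions (disable for
#'   control-style runs with no moving segments).
#' @param out_dir Optional directory; when given, the segment table, fit
#'   results, summary, resolved config and a run manifest are written
#'   there.
#' @return A `mot_pipeline` list: `segments`, `runs`, `pauses`, `jumps`,
#'   `fits`, `summary`, `records` (processed traces), `qc`, `config`.
#' @export
run_pipeline <- function(records, config = pipeline_config(),
                         drift_correct = TRUE, fits = TRUE, out_dir = NULL) {
  if (inherits(records, "mot_trace")) records <- list(records)
  if (length(records) == 0) stopf("need at least one record")
  processed <- vector("list", length(records))
  for (i in seq_along(records)) {
    processed[[i]] <- tryCatch(
      process_one_record(records[[i]], config, drift_correct),
      error = function(e) stopf("record %d failed: %s", i, conditionMessage(e))
    )
  }
  segments <- dplyr::bind_rows(lapply(processed, `[[`, "segments"))
  segments <- classify_segments(segments, config$pause_threshold)
  rp <- extract_runs_and_pauses(segments)
  rec_tbl <- tibble::tibble(
    record_id = vapply(processed, function(p) {
      trace_meta(p$trace)$record_id %||% "record"
    }, character(1)),
    duration = vapply(processed, function(p) {
      nrow(p$trace) / sample_rate(p$trace)
    }, numeric(1))
  )
  fit_list <- list()
  if (fits) {
    ret <- dplyr::filter(segments, .data$retained)
    fw <- dplyr::filter(ret, !is.na(.data$direction), .data$direction == "forward")
    bw <- dplyr::filter(ret, !is.na(.data$direction), .data$direction == "backward")
    # direction-specific velocity PDFs include all same-signed segments
    # (paused segments enter the class matching their relative sign)
    fw_all <- dplyr::filter(ret, .data$rel_velocity > 0)
    bw_all <- dplyr::filter(ret, .data$rel_velocity <= 0)
    safe_fit <- function(expr) tryCatch(expr, error = function(e) NULL,
                                        warning = function(w) suppressWarnings(expr))
    fit_list$velocity_forward <- safe_fit(fit_exponential_weighted(
      abs(fw_all$rel_velocity), fw_all$duration, config$weight_basis))
    fit_list$velocity_backward <- safe_fit(fit_exponential_weighted(
      abs(bw_all$rel_velocity), bw_all$duration, config$weight_basis))
    if (nrow(rp$runs)) {
      for (dir in c("forward", "backward")) {
        rr <- dplyr::filter(rp$runs, .data$direction == dir)
        if (nrow(rr) == 0) next
        fit_list[[paste0("run_distance_", dir)]] <-
          safe_fit(fit_exponential_weighted(rr$distance))
        ok <- rr$duration >= config$t0
        if (sum(ok) > 0) {
          fit_list[[paste0("run_duration_", dir)]] <-
            safe_fit(fit_truncated_exponential(rr$duration[ok], config$t0))
        }
        if (sum(ok) >= 4) {
          fit_list[[paste0("run_duration_", dir, "_2exp")]] <-
            safe_fit(fit_double_exponential_em(rr$duration[ok], config$t0,
                                               config$em_tol))
        }
      }
    }
    if (nrow(rp$pauses)) {
      ok <- rp$pauses$duration >= config$t0
      if (sum(ok) > 0) {
        fit_list$pause_duration <-
          safe_fit(fit_truncated_exponential(rp$pauses$duration[ok], config$t0))
      }
      if (sum(ok) >= 4) {
        fit_list$pause_duration_2exp <-
          safe_fit(fit_double_exponential_em(rp$pauses$duration[ok], config$t0,
                                             config$em_tol))
      }
    }
  }
  summary <- summarize_dataset(segments, rp$runs, rp$pauses, rec_tbl,
                               lifetime_cutoff = config$min_duration)
  out <- structure(
    list(
      segments = segments, runs = rp$runs, pauses = rp$pauses,
      jumps = dplyr::bind_rows(lapply(seq_along(processed), function(i) {
        j <- processed[[i]]$jumps
        if (nrow(j)) j$record_id <- rec_tbl$record_id[i]
        j
      })),
      fits = fit_list, summary = summary,
      records = lapply(processed, `[[`, "trace"),
      qc = lapply(processed, `[[`, "qc"),
      config = config
    ),
    class = "mot_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seg_path <- file.path(out_dir, "segments.tsv")
  utils::write.table(result$segments, seg_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(result$runs, file.path(out_dir, "runs.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(result$pauses, file.path(out_dir, "pauses.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(result$summary, file.path(out_dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (nm in names(result$fits)) {
    if (!is.null(result$fits[[nm]])) {
      write_fit_json(result$fits[[nm]], file.path(out_dir, paste0("fit_", nm, ".json")))
    }
  }
  write_fit_json(result$config, file.path(out_dir, "config.json"))
  manifest <- list(
    written = format(Sys.time(), tz = "UTC"),
    artifacts = list.files(out_dir),
    n_records = result$summary$n_records
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.mot_pipeline <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<mot_pipeline> %d records, %.0f s observed; %d retained segments\n",
    s$n_records, s$total_time, s$n_segments
  ))
  cat(sprintf(
    "  occupancy: forward %.1f%%, backward %.1f%%, paused %.1f%%\n",
    100 * s$frac_forward, 100 * s$frac_backward, 100 * s$frac_paused
  ))
  if (!is.null(x$fits$velocity_forward)) {
    cat(sprintf("  forward velocity: %.3f nm/s [%.3f, %.3f]\n",
                x$fits$velocity_forward$params$mean,
                x$fits$velocity_forward$ci95$mean[1],
                x$fits$velocity_forward$ci95$mean[2]))
  }
  if (!is.null(x$fits$velocity_backward)) {
    cat(sprintf("  backward velocity: %.3f nm/s [%.3f, %.3f]\n",
                x$fits$velocity_backward$params$mean,
                x$fits$velocity_backward$ci95$mean[1],
                x$fits$velocity_backward$ci95$mean[2]))
  }
  invisible(x)
}

#' Simulate a batch of motility or control records
#'
#' Convenience wrapper producing `n_records` independent records under one
#' configuration with per-record child seeds, paired with fiducial-marker
#' video so the drift-correction stage is exercised end to end.
#'
#' Drift visibility differs between the two record types, mirroring the
#' experimental design. A motility record's drift (its own
#' `drift_rate_scale` path plus any shared `common_drift_scale` instrument
#' drift) is rendered into the fiducial frames, so correction removes it up
#' to tracking error. An enzyme-free control record instead carries its
#' drift as the *residual that survives correction* -- the quantity the
#' control analysis measures -- so its fiducial frames show only the shared
#' common-mode drift.
#'
#' @param n_records Number of records.
#' @param config A [sim_config()]; its `seed` seeds the whole batch.
#' @param control Simulate enzyme-free control records instead of motility
#'   records.
#' @param common_drift_scale Straight-line slope scale (nm/s) of the shared
#'   instrument drift added to every record and its markers; 0 disables it.
#' @param frame_rate Fiducial video frame rate, Hz.
#' @param fiducial Render fiducial frames (disable to study uncorrected
#'   records).
#' @return A list of records suitable for [run_pipeline()], each with
#'   `trace`, `fiducial` (or NULL) and `truth`.
#' @export
simulate_dataset <- function(n_records, config = sim_config(),
                             control = FALSE, common_drift_scale = 0.2,
                             frame_rate = 1, fiducial = TRUE) {
  # derive per-record seeds through the RNG itself: arithmetic seed
  # schedules (master + i * constant) leave records subtly correlated
  seed_tbl <- if (is.null(config$seed)) NULL else {
    with_seed(config$seed,
              matrix(sample.int(2147482000, 3 * n_records), n_records, 3))
  }
  lapply(seq_len(n_records), function(i) {
    cfg <- config
    cfg$seed <- if (is.null(seed_tbl)) NULL else seed_tbl[i, 1]
    rec <- if (control) simulate_control_record(cfg) else simulate_motility_record(cfg)
    rec$trace <- retrace(rec$trace, rec$trace$t, rec$trace$x,
                         trace_force(rec$trace))
    attr(rec$trace, "meta")$record_id <- sprintf("%s%03d",
                                                 if (control) "ctl" else "rec", i)
    common <- if (common_drift_scale > 0) {
      make_drift_path(
        cfg$duration, common_drift_scale, corr_time = 1000, fluct_frac = 0.3,
        seed = if (is.null(seed_tbl)) NULL else seed_tbl[i, 2]
      )
    } else {
      tibble::tibble(t = c(0, cfg$duration), d = c(0, 0))
    }
    if (common_drift_scale > 0) rec$trace <- add_drift(rec$trace, common)
    # markers see the common drift always; a motility record's own drift is
    # instrument drift (visible), a control's is post-correction residual
    # (invisible)
    visible <- common
    if (!control) {
      own <- stats::approx(rec$truth$drift_path$t, rec$truth$drift_path$d,
                           xout = visible$t, rule = 2)$y
      visible$d <- visible$d + own
    }
    fid <- NULL
    if (fiducial) {
      fid <- simulate_fiducial_frames(
        visible, frame_rate = frame_rate,
        seed = if (is.null(seed_tbl)) NULL else seed_tbl[i, 3]
      )
    }
    list(trace = rec$trace, fiducial = fid, truth = rec$truth)
  })
}
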