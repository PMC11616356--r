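#' Segmentation configuration
#'
#' Controls the automated constant-velocity changepoint segmentation that
#' replaces by-eye segmentation: an exact dynamic-programming search over a
#' candidate breakpoint grid, with per-piece cost equal to the residual sum
#' of squares of an ordinary least-squares line and a fixed penalty per
#' breakpoint. Replicate segmentations perturb the penalty to emulate
#' independent human segmenters.
#'
#' @param min_duration Minimum segment duration retained for analysis, s.
#'   Shorter pieces are kept for tiling but flagged excluded.
#' @param pause_threshold Absolute velocity below which a segment is a
#'   pause, nm/s. The default derives from control records via
#'   [derive_pause_threshold()].
#' @param penalty Changepoint penalty (RSS units) or `"auto"`:
#'   `penalty_scale * sigma^2 * log(n)` with `sigma` estimated robustly from
#'   first differences.
#' @param penalty_scale Multiplier for the automatic penalty. The default is
#'   calibrated so mean segment duration on default synthetic records is
#'   close to the ~25 s state dwell scale.
#' @param n_replicates Number of replicate segmentations.
#' @param replicate_jitter Fractional penalty perturbation across replicates;
#'   replicate penalties span `penalty * (1 +/- replicate_jitter)`.
#' @param grid_spacing Candidate-breakpoint spacing, s.
#' @param min_piece Minimum piece duration the search may produce, s (pieces
#'   between `min_piece` and `min_duration` are tiled but excluded).
#' @param seed Unused by the deterministic replicate scheme; kept so a
#'   randomised scheme can be slotted in.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(min_duration = 10,
                                pause_threshold = 0.085,
                                penalty = "auto",
                                penalty_scale = 3,
                                n_replicates = 3,
                                replicate_jitter = 0.2,
                                grid_spacing = 1,
                                min_piece = 5,
                                seed = NULL) {
  if (min_duration <= 0) stopf("min_duration must be positive")
  if (n_replicates < 1) stopf("n_replicates must be >= 1")
  if (min_piece <= 0 || min_piece > min_duration) {
    stopf("min_piece must be in (0, min_duration]")
  }
  structure(
    list(
      min_duration = min_duration, pause_threshold = pause_threshold,
      penalty = penalty, penalty_scale = penalty_scale,
      n_replicates = n_replicates, replicate_jitter = replicate_jitter,
      grid_spacing = grid_spacing, min_piece = min_piece, seed = seed
    ),
    class = "segmentation_config"
  )
}

# Exact DP over a candidate-boundary grid. bnd: sorted sample indices of
# candidate boundaries, first = 1, last = n + 1. Returns chosen boundaries.
dp_segment <- function(t, x, bnd, min_len, beta) {
  m <- length(bnd)
  # prefix sums for O(1) interval OLS cost
  c1 <- c(0, cumsum(x))
  ct <- c(0, cumsum(t))
  ctt <- c(0, cumsum(t * t))
  cxx <- c(0, cumsum(x * x))
  ctx <- c(0, cumsum(t * x))
  seg_cost <- function(a, b) { # samples a .. b inclusive, vectorised over a
    n <- b - a + 1
    s1 <- c1[b + 1] - c1[a]
    st <- ct[b + 1] - ct[a]
    stt <- ctt[b + 1] - ctt[a]
    sxx <- cxx[b + 1] - cxx[a]
    stx <- ctx[b + 1] - ctx[a]
    stt_c <- stt - st^2 / n
    sxx_c <- sxx - s1^2 / n
    stx_c <- stx - st * s1 / n
    rss <- sxx_c - ifelse(stt_c > 1e-12, stx_c^2 / stt_c, 0)
    pmax(rss, 0)
  }
  F <- rep(Inf, m)
  F[1] <- 0
  prev <- integer(m)
  for (j in 2:m) {
    i <- which(bnd[j] - bnd[seq_len(j - 1)] >= min_len)
    if (length(i) == 0) next
    cand <- F[i] + seg_cost(bnd[i], bnd[j] - 1) + beta
    k <- which.min(cand)
    if (is.finite(cand[k])) {
      F[j] <- cand[k]
      prev[j] <- i[k]
    }
  }
  if (!is.finite(F[m])) {
    return(c(bnd[1], bnd[m])) # fall back: single segment
  }
  path <- m
  while (path[1] != 1) path <- c(prev[path[1]], path)
  bnd[path]
}

robust_sigma <- function(x) {
  d <- diff(x)
  stats::median(abs(d - stats::median(d))) / 0.6745 / sqrt(2)
}

#' Segment a record into constant-velocity pieces
#'
#' Partitions a drift-corrected, downsampled record into contiguous pieces,
#' fits each by ordinary least squares, and repeats the search
#' `n_replicates` times with jittered penalties. Pieces shorter than
#' `min_duration` tile the record but are flagged `retained = FALSE` and
#' excluded from downstream fits and occupancy accounting.
#'
#' @param trace A drift-corrected, downsampled `mot_trace`.
#' @param config A [segmentation_config()].
#' @return A `mot_segments` tibble: `record_id`, `replicate`, `t_start`,
#'   `t_end`, `duration`, `velocity` (nm/s, signed OLS slope), `intercept`,
#'   `resid_sd`, `distance` (velocity x duration), `mean_force` (NA without
#'   a force channel), `n_samples`, `retained`.
#' @export
segment_record <- function(trace, config = segmentation_config()) {
  assert_trace(trace)
  rid <- trace_meta(trace)$record_id
  if (is.null(rid)) rid <- "record"
  dur <- nrow(trace) / sample_rate(trace)
  if (dur < config$min_duration) {
    warnf("record shorter than min_duration (%.1f s < %g s): no segments",
          dur, config$min_duration)
    return(empty_segments())
  }
  t <- trace$t
  x <- trace$x
  n <- length(t)
  rate <- sample_rate(trace)
  g <- max(1L, round(config$grid_spacing * rate))
  bnd <- unique(c(seq(1L, n, by = g), n + 1L))
  if (bnd[length(bnd)] != n + 1L) bnd <- c(bnd, n + 1L)
  min_len <- max(3L, round(config$min_piece * rate))
  beta0 <- if (identical(config$penalty, "auto")) {
    config$penalty_scale * robust_sigma(x)^2 * log(n)
  } else {
    as.numeric(config$penalty)
  }
  beta0 <- max(beta0, 1e-8)
  mult <- if (config$n_replicates == 1) 1 else {
    1 + config$replicate_jitter * seq(-1, 1, length.out = config$n_replicates)
  }
  f <- trace_force(trace)
  reps <- purrr::imap_dfr(mult, function(mu, rep_id) {
    cuts <- dp_segment(t, x, bnd, min_len, beta0 * mu)
    a <- cuts[-length(cuts)]
    b <- cuts[-1] - 1L
    fits <- purrr::map2_dfr(a, b, function(ai, bi) {
      ol <- ols_line(t[ai:bi], x[ai:bi])
      tibble::tibble(
        t_start = t[ai], t_end = t[bi] + 1 / rate,
        velocity = ol$slope, intercept = ol$intercept,
        resid_sd = ol$resid_sd, n_samples = ol$n,
        mean_force = if (!is.null(f)) mean(f[ai:bi]) else NA_real_
      )
    })
    fits$replicate <- rep_id
    fits
  })
  reps$duration <- reps$t_end - reps$t_start
  reps$distance <- reps$velocity * reps$duration
  reps$retained <- reps$duration >= config$min_duration - 1e-9
  reps$record_id <- rid
  out <- reps[, c("record_id", "replicate", "t_start", "t_end", "duration",
                  "velocity", "intercept", "resid_sd", "distance",
                  "mean_force", "n_samples", "retained")]
  structure(out, class = c("mot_segments", class(out)),
            penalty = beta0, config = config)
}

empty_segments <- function() {
  out <- tibble::tibble(
    record_id = character(0), replicate = integer(0), t_start = numeric(0),
    t_end = numeric(0), duration = numeric(0), velocity = numeric(0),
    intercept = numeric(0), resid_sd = numeric(0), distance = numeric(0),
    mean_force = numeric(0), n_samples = integer(0), retained = logical(0)
  )
  structure(out, class = c("mot_segments", class(out)))
}

#' Fit a constant-velocity line to a trace interval
#'
#' Closed-form ordinary least squares over `[t_start, t_end)`; the slope is
#' the segment velocity in nm/s.
#'
#' @param trace A `mot_trace`.
#' @param t_start,t_end Interval bounds, s (>= 3 samples).
#' @return A one-row tibble: `velocity`, `intercept`, `resid_sd`, `n_samples`.
#' @export
fit_segment <- function(trace, t_start, t_end) {
  assert_trace(trace)
  idx <- which(trace$t >= t_start - 1e-12 & trace$t < t_end - 1e-12)
  if (length(idx) < 3) stopf("segment has fewer than 3 samples")
  ol <- ols_line(trace$t[idx], trace$x[idx])
  tibble::tibble(velocity = ol$slope, intercept = ol$intercept,
                 resid_sd = ol$resid_sd, n_samples = ol$n)
}

#' Classify segments by direction and pause state
#'
#' The net progress sign of each record/replicate is the sign of the summed
#' signed distance over retained segments. Moving segments sharing that sign
#' are `forward` (reported positive via `rel_velocity`), opposite ones
#' `backward` (negative); segments with absolute velocity strictly below the
#' pause threshold are `paused` and carry no direction. A record with
#' exactly zero net displacement tie-breaks to forward = positive x (a
#' message notes it).
#'
#' @param segments A `mot_segments` tibble.
#' @param pause_threshold Pause threshold, nm/s.
#' @return The tibble with `state` (`"moving"`/`"paused"`), `direction`
#'   (`"forward"`/`"backward"`/NA), `rel_velocity` (progress-relative,
#'   forward positive) and `net_sign` columns added.
#' @export
classify_segments <- function(segments, pause_threshold = 0.085) {
  cls <- class(segments)
  out <- segments |>
    dplyr::group_by(.data$record_id, .data$replicate) |>
    dplyr::mutate(net_sign = {
      net <- sum(.data$distance[.data$retained])
      if (net == 0) {
        message("net displacement exactly 0: tie-break forward = positive x")
        1
      } else {
        sign(net)
      }
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      state = dplyr::if_else(abs(.data$velocity) < pause_threshold,
                             "paused", "moving"),
      rel_velocity = .data$velocity * .data$net_sign,
      direction = dplyr::case_when(
        state == "paused" ~ NA_character_,
        rel_velocity > 0 ~ "forward",
        TRUE ~ "backward"
      )
    )
  class(out) <- cls
  out
}

#' Extract runs and pauses from classified segments
#'
#' A run is a maximal block of time-adjacent retained moving segments
#' sharing a direction; a pause is a maximal block of adjacent retained
#' paused segments. Excluded (short) segments interrupt adjacency, so
#' continuity is never bridged across unanalysed stretches. Run distance is
#' the summed signed distance, reported positive.
#'
#' @param segments A classified `mot_segments` tibble (see
#'   [classify_segments()]).
#' @return A list with tibbles `runs` (`record_id`, `replicate`,
#'   `direction`, `t_start`, `t_end`, `duration`, `distance`, `n_segments`)
#'   and `pauses` (same, without direction/distance).
#' @export
extract_runs_and_pauses <- function(segments) {
  if (!"state" %in% names(segments)) {
    stopf("segments must be classified first (see classify_segments())")
  }
  seg <- segments |>
    dplyr::filter(.data$retained) |>
    dplyr::arrange(.data$record_id, .data$replicate, .data$t_start)
  if (nrow(seg) == 0) {
    return(list(runs = tibble::tibble(), pauses = tibble::tibble()))
  }
  blocks <- seg |>
    dplyr::group_by(.data$record_id, .data$replicate) |>
    dplyr::mutate(
      adjacent = c(TRUE, abs(.data$t_start[-1] -
                               .data$t_end[-dplyr::n()]) < 1e-6),
      key = paste(.data$state, dplyr::coalesce(.data$direction, "-")),
      new_block = !.data$adjacent | .data$key != dplyr::lag(.data$key,
                                                            default = ""),
      block = cumsum(.data$new_block)
    ) |>
    dplyr::group_by(.data$record_id, .data$replicate, .data$block) |>
    dplyr::summarise(
      state = .data$state[1], direction = .data$direction[1],
      t_start = min(.data$t_start), t_end = max(.data$t_end),
      duration = sum(.data$duration), distance = abs(sum(.data$distance)),
      n_segments = dplyr::n(), .groups = "drop"
    )
  list(
    runs = blocks |>
      dplyr::filter(.data$state == "moving") |>
      dplyr::select("record_id", "replicate", "direction", "t_start",
                    "t_end", "duration", "distance", "n_segments"),
    pauses = blocks |>
      dplyr::filter(.data$state == "paused") |>
      dplyr::select("record_id", "replicate", "t_start", "t_end",
                    "duration", "n_segments")
  )
}
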