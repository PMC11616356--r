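seg_speed_weights <- function(group, basis) {
  if (is.data.frame(group)) {
    vcol <- if ("rel_velocity" %in% names(group)) "rel_velocity" else "velocity"
    v <- abs(group[[vcol]])
    w <- if ("duration" %in% names(group)) {
      floor(group$duration / basis)
    } else {
      rep(1, nrow(group))
    }
  } else {
    v <- abs(as.numeric(group))
    w <- rep(1, length(v))
  }
  keep <- w >= 1
  list(v = v[keep], w = w[keep])
}

#' Bootstrap two-sample test on time-weighted exponential means
#'
#' Tests H0: mu1 = mu2 against H1: mu1 != mu2, where each group mean is the
#' duration-weighted exponential MLE of absolute segment velocities. The
#' null is built by recentering both weighted samples onto the pooled mean;
#' segments are resampled with replacement within groups (each carrying its
#' weight -- the independent unit is the segment, not the replicated
#' pseudo-observation) and the two-sided tail probability of
#' `|diff| >= |observed|` is reported with an add-one correction, so
#' `p >= 1/(B + 1)`.
#'
#' @param group_a,group_b Segment tibbles (columns `rel_velocity` or
#'   `velocity`, and `duration`) or plain numeric speed vectors (unit
#'   weights).
#' @param B Bootstrap replicates (>= 100).
#' @param basis Weight basis, s.
#' @param seed Optional integer seed; results are deterministic given it.
#' @return A `boot_test`: `observed_diff`, `p_value`, `B`, group sizes,
#'   group means.
#' @export
bootstrap_mean_test <- function(group_a, group_b, B = 10000, basis = 10,
                                seed = NULL) {
  if (B < 100) stopf("B must be >= 100 for a stable p-value")
  a <- seg_speed_weights(group_a, basis)
  b <- seg_speed_weights(group_b, basis)
  if (length(a$v) == 0 || length(b$v) == 0) stopf("both groups must be non-empty")
  mu_a <- sum(a$w * a$v) / sum(a$w)
  mu_b <- sum(b$w * b$v) / sum(b$w)
  obs <- mu_a - mu_b
  pooled <- (sum(a$w * a$v) + sum(b$w * b$v)) / (sum(a$w) + sum(b$w))
  va <- a$v - mu_a + pooled
  vb <- b$v - mu_b + pooled
  with_seed(seed, {
    na <- length(va)
    nb <- length(vb)
    ia <- matrix(sample.int(na, na * B, replace = TRUE), na, B)
    ib <- matrix(sample.int(nb, nb * B, replace = TRUE), nb, B)
    da <- colSums(matrix(a$w[ia] * va[ia], na, B)) /
      colSums(matrix(a$w[ia], na, B))
    db <- colSums(matrix(b$w[ib] * vb[ib], nb, B)) /
      colSums(matrix(b$w[ib], nb, B))
    diff_star <- da - db
    p <- (1 + sum(abs(diff_star) >= abs(obs))) / (B + 1)
    structure(
      list(observed_diff = obs, p_value = p, B = B, seed = seed,
           n = c(a = na, b = nb), means = c(a = mu_a, b = mu_b)),
      class = "boot_test"
    )
  })
}

#' @export
print.boot_test <- function(x, ...) {
  cat(sprintf(
    "<boot_test> diff = %.4g (means %.4g vs %.4g), p = %.4g (B = %d, n = %d/%d)\n",
    x$observed_diff, x$means[1], x$means[2], x$p_value, x$B, x$n[1], x$n[2]
  ))
  invisible(x)
}

#' Bin forward segments by applied force and fit per-bin velocities
#'
#' Bins forward-moving segments by their mean applied force into
#' `width`-wide bins centred on 0 pN (edges at +/- width/2, +/- 3 width/2,
#' ...), then fits the duration-weighted exponential velocity distribution
#' within each bin. Empty bins are omitted; bins with fewer than `min_n`
#' segments are flagged low-count.
#'
#' @param segments Classified segments with a `mean_force` column.
#' @param width Bin width, pN.
#' @param min_n Low-count flag threshold.
#' @param basis Weight basis, s.
#' @return A tibble: `bin_center`, `bin_width`, `n_segments`, `mean`,
#'   `ci_lo`, `ci_hi`, `low_count`, with the `dist_fit` objects in a `fit`
#'   list-column.
#' @export
bin_by_force <- function(segments, width = 3.5, min_n = 5, basis = 10) {
  if (!"mean_force" %in% names(segments) || all(is.na(segments$mean_force))) {
    stopf("segments carry no force channel")
  }
  seg <- segments |>
    dplyr::filter(.data$retained, .data$direction == "forward",
                  !is.na(.data$mean_force))
  if (nrow(seg) == 0) stopf("no forward segments with force to bin")
  seg$bin_center <- width * round(seg$mean_force / width)
  out <- seg |>
    dplyr::group_by(.data$bin_center) |>
    dplyr::group_modify(function(d, key) {
      fit <- fit_exponential_weighted(abs(d$rel_velocity), d$duration, basis)
      tibble::tibble(
        bin_width = width, n_segments = nrow(d),
        mean = fit$params$mean,
        ci_lo = fit$ci95$mean[1], ci_hi = fit$ci95$mean[2],
        low_count = nrow(d) < min_n, fit = list(fit)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$bin_center)
  if (any(out$low_count)) {
    message(sum(out$low_count), " force bin(s) flagged low-count (n < ", min_n, ")")
  }
  out
}

#' Summarise a segmented dataset
#'
#' Time-weighted occupancy fractions over retained segments (forward /
#' backward / paused), run and pause counts and means, total observation
#' time, and the mean record (bond) lifetime over records longer than the
#' cutoff.
#'
#' @param segments Classified segments.
#' @param runs,pauses Run and pause tables from [extract_runs_and_pauses()].
#' @param records Optional tibble with `record_id` and `duration` (s) per
#'   record; when absent, record durations are taken from the segment span.
#' @param lifetime_cutoff Records must exceed this duration (s) to enter the
#'   bond-lifetime mean.
#' @return A one-row tibble of summary statistics; occupancy fractions sum
#'   to 1.
#' @export
summarize_dataset <- function(segments, runs = NULL, pauses = NULL,
                              records = NULL, lifetime_cutoff = 10) {
  seg <- dplyr::filter(segments, .data$retained)
  occ_key <- dplyr::if_else(seg$state == "paused", "paused", seg$direction)
  tot <- sum(seg$duration)
  frac <- function(k) sum(seg$duration[occ_key == k]) / tot
  if (is.null(records)) {
    records <- segments |>
      dplyr::group_by(.data$record_id) |>
      dplyr::summarise(duration = max(.data$t_end) - min(.data$t_start),
                       .groups = "drop")
  }
  lt <- records$duration[records$duration > lifetime_cutoff]
  tibble::tibble(
    n_records = nrow(records),
    n_segments = nrow(seg),
    total_time = sum(records$duration),
    retained_time = tot,
    frac_forward = frac("forward"),
    frac_backward = frac("backward"),
    frac_paused = frac("paused"),
    n_runs = if (is.null(runs)) NA_integer_ else nrow(runs),
    n_pauses = if (is.null(pauses)) NA_integer_ else nrow(pauses),
    mean_run_distance = if (is.null(runs) || nrow(runs) == 0) NA_real_ else mean(runs$distance),
    mean_run_duration = if (is.null(runs) || nrow(runs) == 0) NA_real_ else mean(runs$duration),
    mean_pause_duration = if (is.null(pauses) || nrow(pauses) == 0) NA_real_ else mean(pauses$duration),
    mean_bond_lifetime = if (length(lt)) mean(lt) else NA_real_
  )
}
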