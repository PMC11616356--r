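#' Plot a bead-position trace
#'
#' @param object A `mot_trace`.
#' @param downsample Plot at most this many points (thinned evenly).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mot_trace <- function(object, downsample = 20000, ...) {
  df <- tibble::as_tibble(object)
  if (nrow(df) > downsample) {
    df <- df[seq(1L, nrow(df), length.out = downsample), ]
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$x)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "position (nm)") +
    ggplot2::theme_minimal()
}

#' Plot a fitted distribution over its data
#'
#' Step histogram of the (weight-replicated, for velocity fits) sample with
#' the fitted probability density overlaid.
#'
#' @param object A `dist_fit`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dist_fit <- function(object, bins = 30, ...) {
  v <- object$data$values
  w <- object$data$weights %||% rep(1, length(v))
  df <- tibble::tibble(value = rep(v, times = w))
  xmax <- max(df$value) * 1.05
  xs <- seq(if (object$family == "exp") 0 else object$params$t0, xmax,
            length.out = 400)
  dens <- switch(object$family,
    exp = stats::dexp(xs, rate = 1 / object$params$mean),
    trunc_exp = stats::dexp(xs - object$params$t0, rate = 1 / object$params$tau),
    trunc_2exp = {
      y <- xs - object$params$t0
      object$params$A1 / object$params$t1 * exp(-y / object$params$t1) +
        object$params$A2 / object$params$t2 * exp(-y / object$params$t2)
    }
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey40") +
    ggplot2::geom_line(
      data = tibble::tibble(x = xs, y = dens),
      ggplot2::aes(x = .data$x, y = .data$y),
      colour = "firebrick", linewidth = 0.8
    ) +
    ggplot2::labs(x = "value", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot a segmented record
#'
#' The downsampled trace with fitted constant-velocity lines overlaid,
#' coloured by classification (forward / backward / paused).
#'
#' @param trace The (downsampled, corrected) `mot_trace` that was segmented.
#' @param segments Classified segments for one replicate of this record.
#' @param replicate Which replicate to show.
#' @return A ggplot object.
#' @export
plot_segments <- function(trace, segments, replicate = 1) {
  seg <- segments[segments$replicate == replicate, ]
  seg$class <- ifelse(seg$state == "paused", "paused", seg$direction)
  seg$x_start <- seg$intercept + seg$velocity * seg$t_start
  seg$x_end <- seg$intercept + seg$velocity * seg$t_end
  ggplot2::ggplot() +
    ggplot2::geom_line(
      data = tibble::as_tibble(trace),
      ggplot2::aes(x = .data$t, y = .data$x),
      colour = "grey70", linewidth = 0.3
    ) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$t_start, xend = .data$t_end,
                   y = .data$x_start, yend = .data$x_end,
                   colour = .data$class),
      linewidth = 0.9
    ) +
    ggplot2::scale_colour_manual(values = c(
      forward = "forestgreen", backward = "darkorange", paused = "steelblue"
    ), na.value = "grey50") +
    ggplot2::labs(x = "time (s)", y = "position (nm)", colour = NULL) +
    ggplot2::theme_minimal()
}
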