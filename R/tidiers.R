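#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a distribution fit
#'
#' @param x A `dist_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.dist_fit <- function(x, ...) {
  terms <- names(x$params)
  tibble::tibble(
    term = terms,
    estimate = unlist(x$params, use.names = FALSE),
    conf.low = vapply(terms, function(p) {
      ci <- x$ci95[[p]]
      if (is.null(ci)) NA_real_ else ci[1]
    }, numeric(1)),
    conf.high = vapply(terms, function(p) {
      ci <- x$ci95[[p]]
      if (is.null(ci)) NA_real_ else ci[2]
    }, numeric(1))
  )
}

#' Glance at a distribution fit
#'
#' @param x A `dist_fit`.
#' @param ... Unused.
#' @return A one-row tibble: family, log-likelihood, observation counts,
#'   convergence flags where applicable.
#' @export
glance.dist_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    logLik = x$loglik,
    n_obs = x$n_obs,
    n_effective = x$n_effective,
    n_iter = x$n_iter %||% NA_integer_,
    converged = x$converged %||% NA,
    degenerate = x$degenerate %||% NA
  )
}

#' Tidy a bootstrap test
#'
#' @param x A `boot_test`.
#' @param ... Unused.
#' @return A one-row tibble: `estimate` (observed mean difference),
#'   `p.value`, group means and sizes.
#' @export
tidy.boot_test <- function(x, ...) {
  tibble::tibble(
    estimate = x$observed_diff,
    p.value = x$p_value,
    mean_a = x$means[["a"]],
    mean_b = x$means[["b"]],
    n_a = x$n[["a"]],
    n_b = x$n[["b"]],
    B = x$B
  )
}

#' @rdname tidy.boot_test
#' @export
glance.boot_test <- function(x, ...) tidy.boot_test(x)
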