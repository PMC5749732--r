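#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cosine fit into a one-row tibble
#'
#' @param x A `cosine_fit`.
#' @param ... Unused.
#' @return Tibble with `a`, `tau`, `theta`, `offset`.
#' @method tidy cosine_fit
#' @export
tidy.cosine_fit <- function(x, ...) {
  tibble::tibble(a = x$a, tau = x$tau, theta = x$theta, offset = x$offset)
}

#' Fit-level summary of a cosine fit
#'
#' @param x A `cosine_fit`.
#' @param ... Unused.
#' @return Tibble with `rss`, `sigma` (residual SD), `n_points`,
#'   `converged`, `segment_label`, `accepted`.
#' @method glance cosine_fit
#' @export
glance.cosine_fit <- function(x, ...) {
  dof <- max(x$n_points - 4, 1)
  tibble::tibble(
    rss = x$rss, sigma = sqrt(x$rss / dof), n_points = x$n_points,
    converged = x$converged, segment_label = x$segment_label,
    accepted = circadian_filter(x)
  )
}

#' Tidy a phase-response curve
#'
#' @param x A `prc`.
#' @param ... Unused.
#' @return The per-stimulus table with group labels.
#' @method tidy prc
#' @export
tidy.prc <- function(x, ...) tibble::as_tibble(x$table)

#' Group-level summary of a phase-response curve
#'
#' @param x A `prc`.
#' @param ... Unused.
#' @return One row per group with `n`, `mean_shift`, `sem_shift`, plus the
#'   delay-vs-advance t-test statistic and p-value.
#' @method glance prc
#' @export
glance.prc <- function(x, ...) {
  g <- x$groups
  g$t_statistic <- if (is.null(x$t_test)) NA_real_ else unname(x$t_test$statistic)
  g$t_p <- if (is.null(x$t_test)) NA_real_ else x$t_test$p.value
  g
}
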