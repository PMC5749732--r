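#' Plot traces with protocol stages
#'
#' Line plot of per-cell traces; cold phases are shaded when a protocol is
#' given.
#'
#' @param traces Tidy trace tibble (`cell_id`, `time_h`, `value`).
#' @param protocol Optional [temperature_protocol()].
#' @return A ggplot.
#' @export
plot_traces <- function(traces, protocol = NULL) {
  p <- ggplot2::ggplot(traces,
                       ggplot2::aes(.data$time_h, .data$value,
                                    group = .data$cell_id))
  if (!is.null(protocol)) {
    cp <- cold_phases(protocol)
    p <- p + ggplot2::geom_rect(
      data = cp, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$cold_onset_h, xmax = .data$cold_end_h,
                   ymin = -Inf, ymax = Inf),
      fill = "lightblue", alpha = 0.4
    )
  }
  p + ggplot2::geom_line(alpha = 0.6, linewidth = 0.3) +
    ggplot2::labs(x = "time (h)", y = "bioluminescence (gray)") +
    ggplot2::theme_minimal()
}

#' @method autoplot cosine_fit
#' @export
autoplot.cosine_fit <- function(object, segment = NULL, ...) {
  tau <- object$tau
  t <- if (is.null(segment)) seq(0, 3 * tau, tau / 100) else segment$time_h
  df <- tibble::tibble(time_h = t, value = predict(object, t))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$value)) +
    ggplot2::geom_line(color = "firebrick")
  if (!is.null(segment)) {
    p <- p + ggplot2::geom_point(data = segment, size = 0.5, alpha = 0.5)
  }
  p + ggplot2::labs(x = "time (h)", y = "value",
                    title = sprintf("cosine fit: tau = %.2f h", tau)) +
    ggplot2::theme_minimal()
}

#' Polar plot of circadian peak phases
#'
#' One point per cell on the 24-h circadian clock face, faceted by stage;
#' the arrow marks the mean phase with length equal to the resultant length
#' (clustering).
#'
#' @param phases Tibble with `ct` and `stage`.
#' @return A ggplot with `coord_polar`.
#' @export
plot_polar_phases <- function(phases) {
  arrows <- phases |>
    dplyr::group_by(.data$stage) |>
    dplyr::group_modify(function(d, key) {
      md <- mean_direction(ct_to_angle(d$ct))
      tibble::tibble(mean_ct = angle_to_ct(md$mean_angle), r = md$r_bar)
    }) |>
    dplyr::ungroup()
  ggplot2::ggplot(phases, ggplot2::aes(x = .data$ct, y = 1)) +
    ggplot2::geom_jitter(width = 0, height = 0.06, size = 1.5, alpha = 0.7) +
    ggplot2::geom_segment(
      data = arrows,
      ggplot2::aes(x = .data$mean_ct, xend = .data$mean_ct, y = 0,
                   yend = .data$r),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      color = "darkorange", linewidth = 0.8
    ) +
    ggplot2::coord_polar() +
    ggplot2::scale_x_continuous(limits = c(0, 24),
                                breaks = seq(0, 18, 6),
                                labels = paste0("CT", seq(0, 18, 6))) +
    ggplot2::ylim(0, 1.1) +
    ggplot2::facet_wrap(~stage) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @method autoplot prc
#' @export
autoplot.prc <- function(object, ...) {
  tab <- object$table
  ctu <- ifelse(tab$onset_ct < 6, tab$onset_ct + 24, tab$onset_ct)
  grid <- data.frame(ct = seq(min(ctu), max(ctu), length.out = 200))
  grid$shift <- stats::predict(object$poly_fit, newdata = grid)
  ggplot2::ggplot(tab, ggplot2::aes(ifelse(.data$onset_ct < 6,
                                           .data$onset_ct + 24,
                                           .data$onset_ct),
                                    .data$shift_ct)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(color = .data$group)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(.data$ct, .data$shift),
                       inherit.aes = FALSE, color = "grey30") +
    ggplot2::labs(x = "stimulus onset (CT, unwrapped)",
                  y = "phase shift (circadian h)",
                  color = NULL,
                  title = "Phase-response curve") +
    ggplot2::theme_minimal()
}
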