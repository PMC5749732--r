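#' Normalize a trace so its maximum hits a target gray level
#'
#' Single-cell bioluminescence recordings from different movies are made
#' comparable by scaling each trace so that its maximum equals `target`
#' (conventionally gray level 255).
#'
#' @param traces Tidy trace tibble (`cell_id`, `time_h`, `value`); one or
#'   many cells. Scaling is per cell.
#' @param target Target maximum (default 255).
#' @return The tibble with `value` rescaled per cell.
#' @export
normalize_max <- function(traces, target = 255) {
  traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::mutate(value = {
      m <- max(.data$value)
      if (m <= 0) stop("cannot normalize an all-zero/negative trace",
                       call. = FALSE)
      .data$value * target / m
    }) |>
    dplyr::ungroup()
}

#' Subtract a per-sample background series from traces
#'
#' @param traces Tidy trace tibble (`cell_id`, `time_h`, `value`).
#' @param background Numeric vector with one value per sample of each cell
#'   (all cells share the time grid), typically from
#'   [estimate_background()]. Resulting values may be negative.
#' @return The tibble with background-subtracted `value`.
#' @export
subtract_background <- function(traces, background) {
  traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::mutate(value = {
      if (dplyr::n() != length(background)) {
        stop("background length must match the trace length", call. = FALSE)
      }
      .data$value - background
    }) |>
    dplyr::ungroup()
}

# centered running mean with truncated (shrinking) windows at the edges
running_mean <- function(x, half_width) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half_width, 1L)
  hi <- pmin(seq_len(n) + half_width, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Remove slow baseline trends by subtracting a running average
#'
#' Subtracts a centered `window_h` (default 24 h) running average from each
#' trace, then adds back the raw trace's minimum gray level so magnitudes
#' stay comparable across cells. Windows shrink at the edges (no padding);
#' the first and last `window_h/2` hours are therefore edge-affected and
#' flagged in the output.
#'
#' @param traces Tidy trace tibble (`cell_id`, `time_h`, `value`).
#' @param window_h Running-average window in hours (default 24).
#' @return The tibble with detrended `value` and a logical `edge` column
#'   marking edge-affected samples.
#' @export
detrend_running_average <- function(traces, window_h = 24) {
  traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(d, key) {
      dt <- median(diff(d$time_h))
      half <- round(window_h / (2 * dt))
      if (nrow(d) < 2 * half + 1) {
        stop("trace shorter than the detrending window", call. = FALSE)
      }
      trend <- running_mean(d$value, half)
      d$value <- d$value - trend + min(d$value)
      d$edge <- seq_len(nrow(d)) <= half |
        seq_len(nrow(d)) > nrow(d) - half
      d
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("cell_id")
}

#' Assign protocol stages to trace samples
#'
#' Labels each sample `Before` (`[0, start_h)`), `During`
#' (`[start_h, end_h)`) or `After` (`[end_h, end)`), and marks the samples
#' belonging to the last `last_k` (default 3) temperature cycles -- the
#' window used for During-period fits.
#'
#' @param traces Tidy trace tibble (`cell_id`, `time_h`, `value`).
#' @param protocol A [temperature_protocol()]; must lie within the recording.
#' @param last_k Cycles in the `during_last` window (default 3).
#' @return The tibble with `stage` (factor Before/During/After) and logical
#'   `during_last` columns.
#' @export
assign_stages <- function(traces, protocol, last_k = 3) {
  t_max <- max(traces$time_h)
  if (protocol$end_h > t_max + 1e-9) {
    stop("protocol extends beyond the recording", call. = FALSE)
  }
  st <- protocol_stages(protocol, last_k)
  traces |>
    dplyr::mutate(
      stage = factor(
        dplyr::case_when(
          .data$time_h < protocol$start_h ~ "Before",
          .data$time_h < protocol$end_h ~ "During",
          TRUE ~ "After"
        ),
        levels = c("Before", "During", "After")
      ),
      during_last = .data$time_h >= st$during_last[1] &
        .data$time_h < st$during_last[2]
    )
}

#' Standard preprocessing chain for a set of traces
#'
#' Convenience wrapper: optional max-normalization, optional background
#' subtraction, running-average detrending, and stage assignment.
#'
#' @inheritParams detrend_running_average
#' @inheritParams assign_stages
#' @param background Optional per-sample background vector.
#' @param normalize If `TRUE` (default), normalize each trace max to 255
#'   before detrending.
#' @return Preprocessed, stage-labelled tidy trace tibble.
#' @export
preprocess_traces <- function(traces, protocol, background = NULL,
                              normalize = TRUE, window_h = 24, last_k = 3) {
  out <- traces
  if (!is.null(background)) out <- subtract_background(out, background)
  if (normalize) out <- normalize_max(out)
  out <- detrend_running_average(out, window_h = window_h)
  assign_stages(out, protocol, last_k = last_k)
}
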