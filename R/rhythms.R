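#' FFT-based initial guess for the cosine fit
#'
#' Seeds the nonlinear least-squares cosine fit from the discrete Fourier
#' transform of the (demeaned) segment: the initial period is the inverse of
#' the frequency of the largest periodogram ordinate inside the circadian
#' band (1/30 to 1/18 per hour by default), and initial amplitude and phase
#' come from the complex coefficient at that frequency. The guess is only as
#' fine as the Fourier grid (bin width `1/(n*dt)` per hour).
#'
#' @param segment Data frame with `time_h` (uniform grid) and `value`.
#' @param period_band Periods considered rhythmic, hours. Default `c(18, 30)`.
#' @return List `a0`, `tau0`, `theta0`, `offset0`, `low_power` (TRUE when
#'   the in-band peak is weak relative to the median periodogram ordinate --
#'   the guess is still returned but flagged).
#' @export
fft_initial_guess <- function(segment, period_band = c(18, 30)) {
  x <- segment$value
  t <- segment$time_h
  n <- length(x)
  if (n < 8) stop("segment too short for a spectral guess", call. = FALSE)
  dt <- (t[n] - t[1]) / (n - 1)
  xc <- x - mean(x)
  F <- stats::fft(xc)
  freq <- (seq_len(n) - 1) / (n * dt)
  band <- freq >= 1 / period_band[2] & freq <= 1 / period_band[1]
  if (!any(band)) {
    stop("no Fourier frequency inside the circadian band; segment too short",
         call. = FALSE)
  }
  power <- Mod(F)^2
  k <- which(band)[which.max(power[band])]
  half <- power[2:floor(n / 2 + 1)]
  low_power <- power[k] < 4 * stats::median(half)
  f0 <- freq[k]
  tau0 <- 1 / f0
  a0 <- 2 * Mod(F[k]) / n
  # for b = a*cos(2*pi*f*t - theta) on t = t1 + j*dt: Arg(F_k) = 2*pi*f*t1 - theta
  theta0 <- (2 * pi * f0 * t[1] - Arg(F[k])) %% (2 * pi)
  list(a0 = a0, tau0 = tau0, theta0 = theta0, offset0 = mean(x),
       low_power = low_power)
}

#' Fit a cosine model to one trace segment
#'
#' Least-squares fit of `f(t) = a * cos(2*pi*t/tau - theta) + offset` by
#' Levenberg-Marquardt, seeded from [fft_initial_guess()] unless an `init`
#' list is supplied. `a` is the amplitude in gray levels, `tau` the period in
#' hours; `theta` and `offset` shift the curve along the axes. Parameters
#' are canonicalized to `a >= 0`, `theta` in `[0, 2pi)`. Non-convergence is
#' reported via the `converged` flag, not an error; a constant segment
#' yields `a = 0`, `offset = mean` with a warning.
#'
#' @param segment Data frame with `time_h` and `value` (>= 8 samples).
#' @param init Optional list with `a0`, `tau0`, `theta0`, `offset0`.
#' @param period_band Band passed to the spectral guess. Default `c(18, 30)`.
#' @param max_iter Maximum Levenberg-Marquardt iterations. Default 500.
#' @param tol Relative-RSS convergence tolerance. Default 1e-8.
#' @param segment_label Optional stage label stored in the fit.
#' @return Object of class `cosine_fit`: fields `a`, `tau`, `theta`,
#'   `offset`, `rss`, `n_points`, `converged`, `segment_label`. Supports
#'   [generics::tidy()], [generics::glance()], `predict()` and
#'   [ggplot2::autoplot()].
#' @examples
#' t <- seq(0, 96, 0.5)
#' seg <- tibble::tibble(time_h = t, value = 30 * cos(2 * pi * t / 24 - 1) + 100)
#' fit_cosine(seg)
#' @export
fit_cosine <- function(segment, init = NULL, period_band = c(18, 30),
                       max_iter = 500, tol = 1e-8, segment_label = NA_character_) {
  stopifnot(all(c("time_h", "value") %in% names(segment)))
  n <- nrow(segment)
  if (n < 8) stop("need at least 8 samples to fit", call. = FALSE)
  y <- segment$value
  t <- segment$time_h
  if (stats::sd(y) == 0) {
    warning("constant segment: returning a zero-amplitude fit")
    return(new_cosine_fit(0, period_band[2], 0, mean(y), 0, n, TRUE,
                          segment_label))
  }
  if (is.null(init)) {
    init <- tryCatch(fft_initial_guess(segment, period_band),
                     error = function(e) NULL)
    if (is.null(init)) {
      init <- list(a0 = stats::sd(y) * sqrt(2), tau0 = mean(period_band),
                   theta0 = 0, offset0 = mean(y))
    }
  }
  df <- data.frame(t = t, y = y)
  pred0 <- init$a0 * cos(2 * pi * t / init$tau0 - init$theta0) + init$offset0
  rss0 <- sum((y - pred0)^2)
  tss <- sum((y - mean(y))^2)
  if (rss0 <= 1e-12 * tss) {
    # the spectral guess already sits at a (numerically) zero-residual
    # minimum; the LM solver would see a singular gradient there
    a <- init$a0; theta <- init$theta0
    if (a < 0) { a <- -a; theta <- theta + pi }
    return(new_cosine_fit(a, abs(init$tau0), theta %% (2 * pi), init$offset0,
                          rss0, n, TRUE, segment_label))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a * cos(2 * pi * t / tau - theta) + offset,
      data = df,
      start = list(a = init$a0, tau = init$tau0, theta = init$theta0,
                   offset = init$offset0),
      control = minpack.lm::nls.lm.control(
        maxiter = max_iter, ftol = tol, ptol = 1e-10
      )
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(new_cosine_fit(init$a0, init$tau0, init$theta0 %% (2 * pi),
                          init$offset0, rss0, n, FALSE, segment_label))
  }
  cf <- as.list(stats::coef(fit))
  a <- cf$a; theta <- cf$theta
  if (a < 0) {
    a <- -a
    theta <- theta + pi
  }
  theta <- theta %% (2 * pi)
  tau <- abs(cf$tau)
  conv <- fit$convInfo$isConv %||% TRUE
  new_cosine_fit(a, tau, theta, cf$offset, sum(stats::resid(fit)^2), n,
                 conv, segment_label)
}

new_cosine_fit <- function(a, tau, theta, offset, rss, n, converged, label) {
  structure(
    list(a = a, tau = tau, theta = theta, offset = offset, rss = rss,
         n_points = n, converged = converged, segment_label = label),
    class = "cosine_fit"
  )
}

#' @export
print.cosine_fit <- function(x, ...) {
  cat(sprintf(
    "cosine fit%s: a = %.3g, tau = %.4g h, theta = %.3g rad, offset = %.4g (rss %.3g, n %d%s)\n",
    if (is.na(x$segment_label)) "" else paste0(" [", x$segment_label, "]"),
    x$a, x$tau, x$theta, x$offset, x$rss, x$n_points,
    if (x$converged) "" else ", NOT converged"
  ))
  invisible(x)
}

#' @export
predict.cosine_fit <- function(object, time_h, ...) {
  object$a * cos(2 * pi * time_h / object$tau - object$theta) + object$offset
}

#' Circadian-band acceptance of a fitted period
#'
#' Only periods inside the circadian band are included in downstream
#' analysis; the fit must also have converged. Band limits are inclusive.
#'
#' @param fit A `cosine_fit`, or a numeric period.
#' @param band Inclusive period band in hours. Default `c(18, 30)`.
#' @return Logical.
#' @export
circadian_filter <- function(fit, band = c(18, 30)) {
  if (inherits(fit, "cosine_fit")) {
    fit$converged && fit$tau >= band[1] && fit$tau <= band[2]
  } else {
    fit >= band[1] & fit <= band[2]
  }
}

#' Relative amplitude of a fitted rhythm
#'
#' The absolute fitted amplitude divided by the mean of the unprocessed
#' (raw) data over the same segment -- a dimensionless measure of rhythm
#' robustness comparable across cells.
#'
#' @param fit A `cosine_fit`.
#' @param raw_values Raw (unprocessed) gray values of the same segment;
#'   their mean must be > 0.
#' @return Numeric fold value `a / mean(raw_values)`.
#' @export
relative_amplitude <- function(fit, raw_values) {
  m <- mean(raw_values)
  if (m <= 0) stop("raw segment mean must be > 0", call. = FALSE)
  fit$a / m
}

#' Fit cosines per cell and stage
#'
#' Runs [fit_cosine()] on each cell's `Before`, `During` and `After`
#' segments of a stage-labelled trace table. Following standard practice the
#' During fit uses only the samples of the last temperature cycles (the
#' `during_last` window) to minimize entrainment transients. Relative
#' amplitudes are computed against `raw_traces` when supplied.
#'
#' @param traces Stage-labelled tidy traces (from [preprocess_traces()] or
#'   [assign_stages()]).
#' @param raw_traces Optional unprocessed traces on the same grid for
#'   relative amplitudes.
#' @param period_band Inclusive circadian band (h). Default `c(18, 30)`.
#' @return Tibble: `cell_id`, `stage`, `a`, `tau`, `theta`, `offset`,
#'   `rss`, `n_points`, `converged`, `accepted`, and `rel_amp` when raw
#'   traces are given.
#' @export
fit_stages <- function(traces, raw_traces = NULL, period_band = c(18, 30)) {
  stopifnot("stage" %in% names(traces))
  one <- function(d, key) {
    if ("edge" %in% names(d)) d <- d[!d$edge, ]  # detrend edge artefacts bias tau
    seg <- if (key$stage == "During" && "during_last" %in% names(d)) {
      d[d$during_last, ]
    } else {
      d
    }
    if (nrow(seg) < 8) {
      return(tibble::tibble(a = NA_real_, tau = NA_real_, theta = NA_real_,
                            offset = NA_real_, rss = NA_real_,
                            n_points = nrow(seg), converged = FALSE))
    }
    f <- fit_cosine(seg, period_band = period_band,
                    segment_label = as.character(key$stage))
    tibble::tibble(a = f$a, tau = f$tau, theta = f$theta, offset = f$offset,
                   rss = f$rss, n_points = f$n_points, converged = f$converged)
  }
  fits <- traces |>
    dplyr::group_by(.data$cell_id, .data$stage) |>
    dplyr::group_modify(one) |>
    dplyr::ungroup() |>
    dplyr::mutate(accepted = .data$converged & !is.na(.data$tau) &
                    .data$tau >= period_band[1] & .data$tau <= period_band[2])
  if (!is.null(raw_traces)) {
    raw_means <- traces |>
      dplyr::select("cell_id", "time_h", "stage") |>
      dplyr::inner_join(raw_traces, by = c("cell_id", "time_h")) |>
      dplyr::group_by(.data$cell_id, .data$stage) |>
      dplyr::summarise(raw_mean = mean(.data$value), .groups = "drop")
    fits <- fits |>
      dplyr::left_join(raw_means, by = c("cell_id", "stage")) |>
      dplyr::mutate(rel_amp = .data$a / .data$raw_mean) |>
      dplyr::select(-"raw_mean")
  }
  fits
}

#' Period summary statistics per stage
#'
#' Mean, SD and coefficient of variation (CV = SD/mean x 100%) of accepted
#' periods per stage (and per extra grouping columns, e.g. condition).
#' Stages with fewer than 2 accepted fits get `NA` SD/CV and are flagged.
#'
#' @param fits A [fit_stages()] tibble (needs `stage`, `tau`, `accepted`).
#' @param ... Extra grouping columns (tidy-select), e.g. a condition column.
#' @param paired_only If `TRUE`, restrict to cells with accepted fits in all
#'   stages present (repeated-measures layout). Default `FALSE`.
#' @return Tibble: groups, `n`, `mean_tau`, `sd_tau`, `cv_pct`, `reliable`.
#' @export
period_summary <- function(fits, ..., paired_only = FALSE) {
  acc <- dplyr::filter(fits, .data$accepted)
  if (paired_only) {
    n_stages <- length(unique(acc$stage))
    acc <- acc |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::filter(dplyr::n_distinct(.data$stage) == n_stages) |>
      dplyr::ungroup()
  }
  acc |>
    dplyr::group_by(.data$stage, ...) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_tau = mean(.data$tau),
      sd_tau = if (dplyr::n() >= 2) stats::sd(.data$tau) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      cv_pct = 100 * .data$sd_tau / .data$mean_tau,
      reliable = .data$n >= 2
    )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
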