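#' Pick circadian peaks by smoothing plus local parabola fits
#'
#' The segment is smoothed with a centered running average (default 11 h);
#' local maxima of the smoothed series at least `min_separation_h` apart
#' (default 12 h, half a circadian cycle, to guard against noise-induced
#' double peaks) become candidates. Around each candidate an ordinary
#' least-squares quadratic is fitted to the *unsmoothed* values over
#' `fit_points` samples (default 30, i.e. 15 h at 0.5-h sampling); the
#' parabola's vertex is the peak time. Candidates whose parabola is not
#' concave-down or whose vertex falls outside the fit window are rejected.
#'
#' @param segment Data frame with `time_h` (uniform grid) and `value`;
#'   optionally `cell_id`.
#' @param smooth_window_h Running-average window (h). Default 11.
#' @param fit_points Samples in each local parabola fit. Default 30.
#' @param min_separation_h Minimum distance between peaks (h). Default 12.
#' @return Tibble with `cell_id` (if present), `peak_time_h`, `peak_height`
#'   (parabola value at the vertex), sorted by time; empty (zero rows) when
#'   no peak is found.
#' @export
pick_peaks <- function(segment, smooth_window_h = 11, fit_points = 30,
                       min_separation_h = 12) {
  t <- segment$time_h
  y <- segment$value
  n <- length(y)
  dt <- (t[n] - t[1]) / (n - 1)
  if (t[n] - t[1] < smooth_window_h) {
    stop("segment shorter than the smoothing window", call. = FALSE)
  }
  half <- round(smooth_window_h / (2 * dt))
  s <- running_mean(y, half)

  # local maxima of the smoothed series
  d <- diff(s)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  empty <- tibble::tibble(peak_time_h = numeric(0), peak_height = numeric(0))
  if ("cell_id" %in% names(segment)) {
    empty <- tibble::tibble(cell_id = character(0), peak_time_h = numeric(0),
                            peak_height = numeric(0))
  }
  if (length(cand) == 0) return(empty)

  # enforce minimum separation, keeping the higher smoothed value
  ord <- cand[order(s[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(t[i] - t[kept]) >= min_separation_h)) kept <- c(kept, i)
  }
  kept <- sort(kept)

  m <- fit_points
  res <- purrr::map_dfr(kept, function(i) {
    lo <- i - floor((m - 1) / 2)
    hi <- lo + m - 1
    if (lo < 1) { lo <- 1L; hi <- min(m, n) }
    if (hi > n) { hi <- n; lo <- max(1L, n - m + 1L) }
    tw <- t[lo:hi]
    yw <- y[lo:hi]
    tc <- tw - t[i]  # center for conditioning
    co <- unname(stats::coef(stats::lm(yw ~ tc + I(tc^2))))
    if (!is.finite(co[3]) || co[3] >= 0) return(NULL)
    vertex <- -co[2] / (2 * co[3])
    if (vertex < tc[1] || vertex > tc[length(tc)]) return(NULL)
    tibble::tibble(
      peak_time_h = t[i] + vertex,
      peak_height = co[1] + co[2] * vertex + co[3] * vertex^2
    )
  })
  if (nrow(res) == 0) return(empty)
  res <- dplyr::arrange(res, .data$peak_time_h)
  if ("cell_id" %in% names(segment)) {
    res <- dplyr::mutate(res, cell_id = segment$cell_id[1],
                         .before = "peak_time_h")
  }
  res
}

#' Pick peaks for every cell of a trace table
#'
#' @param traces Tidy trace tibble (`cell_id`, `time_h`, `value`, optionally
#'   `stage`).
#' @inheritParams pick_peaks
#' @return Tibble `cell_id`, `peak_time_h`, `peak_height`, and `stage` when
#'   the input carries stage labels (stage of the sample nearest the peak).
#' @export
pick_peaks_all <- function(traces, smooth_window_h = 11, fit_points = 30,
                           min_separation_h = 12) {
  out <- traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(d, key) {
      pk <- pick_peaks(d, smooth_window_h, fit_points, min_separation_h)
      dplyr::select(pk, -dplyr::any_of("cell_id"))
    }) |>
    dplyr::ungroup()
  if ("stage" %in% names(traces) && nrow(out) > 0) {
    ref <- dplyr::distinct(traces, .data$cell_id, .data$time_h, .data$stage)
    out <- out |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::mutate(stage = {
        tt <- ref$time_h[ref$cell_id == .data$cell_id[1]]
        ss <- ref$stage[ref$cell_id == .data$cell_id[1]]
        ss[vapply(.data$peak_time_h, function(p) which.min(abs(tt - p)),
                  integer(1))]
      }) |>
      dplyr::ungroup()
  }
  out
}

#' Circadian time of a free-running peak
#'
#' Elapsed real hours since a reference event are converted to circadian
#' hours by rescaling the time axis with the cell's own period
#' (`24/tau_before` circadian hours per real hour) and added to the
#' reference's circadian time, modulo 24. The conventional anchor for
#' peripheral PER2 reporters places the bioluminescence peak at CT18, so
#' passing a reference peak with `ref_ct = 18` (the default) maps that peak
#' to CT18. Passing `ref_time_h = 0, ref_ct = 0` simply rescales the
#' recording time axis.
#'
#' @param peak_time_h Peak time(s), hours from recording start.
#' @param tau_before The cell's free-running period (h), in `[18, 30]`.
#' @param ref_time_h Reference event time (h); required.
#' @param ref_ct Circadian time assigned to the reference. Default 18.
#' @return CT in `[0, 24)`.
#' @export
to_circadian_free_run <- function(peak_time_h, tau_before, ref_time_h,
                                  ref_ct = 18) {
  if (missing(ref_time_h) || is.null(ref_time_h) || anyNA(ref_time_h)) {
    stop("missing reference peak for the circadian-time anchor", call. = FALSE)
  }
  if (any(tau_before < 18 | tau_before > 30)) {
    stop("tau_before outside the circadian band [18, 30]", call. = FALSE)
  }
  (ref_ct + (peak_time_h - ref_time_h) * 24 / tau_before) %% 24
}

#' Circadian time of a peak during temperature cycles
#'
#' During entrainment one zeitgeber cycle is one circadian day: the time
#' axis is rescaled by `24/T` and anchored so that the end of the cold
#' phase is CT12 (the middle of the circadian day), independent of the
#' cycle length.
#'
#' @param peak_time_h Peak time(s), hours from recording start; must lie in
#'   the During window.
#' @param protocol A [temperature_protocol()].
#' @return CT in `[0, 24)`.
#' @export
to_circadian_entrained <- function(peak_time_h, protocol) {
  if (any(peak_time_h < protocol$start_h | peak_time_h >= protocol$end_h)) {
    stop("peak outside the During window", call. = FALSE)
  }
  t_cold_end1 <- protocol$start_h + protocol$cold_h
  (12 + (peak_time_h - t_cold_end1) * 24 / protocol$cycle_length_h) %% 24
}

#' Expected peak by extrapolating the Before cosine fit
#'
#' The first maximum of `a*cos(2*pi*t/tau - theta) + offset` at or after
#' `window_start_h`, in absolute recording time. Used as the unperturbed
#' reference against which the actually observed peak defines a phase shift.
#'
#' @param before_fit An accepted (`circadian_filter()`) `cosine_fit` of the
#'   Before segment, fitted on absolute recording time.
#' @param window_start_h Search window start (h).
#' @return Expected peak time (h).
#' @export
expected_peak <- function(before_fit, window_start_h) {
  if (!circadian_filter(before_fit)) {
    stop("Before fit rejected; cannot extrapolate an expected peak",
         call. = FALSE)
  }
  tau <- before_fit$tau
  t0 <- tau * before_fit$theta / (2 * pi)  # one cosine maximum
  k <- ceiling((window_start_h - t0) / tau)
  t0 + k * tau
}

#' Phase shift between expected and observed peak, in circadian hours
#'
#' The shift elicited by a stimulus is the difference between the expected
#' peak (extrapolated from Before) and the actually observed peak, converted
#' to circadian hours with the cell's own period. An actual peak *later*
#' than expected is a phase *delay* (negative); earlier is an advance
#' (positive). The default conversion divides real hours by `tau/24`
#' (i.e. multiplies by `24/tau`), so a fixed real-hour displacement counts
#' for fewer circadian hours in a longer-period cell;
#' `convention = "multiply"` (real hours times `tau/24`) is retained as a
#' documented alternative.
#'
#' @param expected_peak_h Expected peak time (h).
#' @param actual_peak_h Observed peak time (h); must pair with the expected
#'   peak within half a period.
#' @param tau_before The cell's free-running period (h).
#' @param convention `"divide"` (default) or `"multiply"`.
#' @return Signed shift in circadian hours.
#' @export
phase_shift <- function(expected_peak_h, actual_peak_h, tau_before,
                        convention = c("divide", "multiply")) {
  convention <- match.arg(convention)
  d <- expected_peak_h - actual_peak_h
  if (any(abs(d) >= tau_before / 2)) {
    stop(sprintf(
      "ambiguous cycle pairing: expected %s vs actual %s differ by >= tau/2",
      paste(signif(expected_peak_h, 6), collapse = ","),
      paste(signif(actual_peak_h, 6), collapse = ",")
    ), call. = FALSE)
  }
  if (convention == "divide") d * 24 / tau_before else d * tau_before / 24
}

#' Pair each expected peak with the nearest observed peak
#'
#' @param expected_peak_h Expected peak time (h).
#' @param peaks Vector of observed peak times (h).
#' @param tau_before Period used for the pairing window (`+- tau/2`).
#' @return The observed peak nearest the expected one, or `NA` if none lies
#'   within half a period.
#' @export
match_actual_peak <- function(expected_peak_h, peaks, tau_before) {
  if (length(peaks) == 0) return(NA_real_)
  d <- abs(peaks - expected_peak_h)
  i <- which.min(d)
  if (d[i] >= tau_before / 2) NA_real_ else peaks[i]
}

#' Circadian time of a stimulus onset
#'
#' The onset phase is referenced to the cell's last free-running peak before
#' the stimulus, which carries the canonical peripheral PER2 peak phase
#' CT18: `CT = (18 + (onset - last_peak) * 24/tau) mod 24`.
#'
#' @param stimulus_onset_h Onset time (h).
#' @param before_peaks Vector of Before peak times (h); at least one must
#'   precede the onset.
#' @param tau_before The cell's free-running period (h).
#' @return CT in `[0, 24)`.
#' @export
onset_ct <- function(stimulus_onset_h, before_peaks, tau_before) {
  prior <- before_peaks[before_peaks <= stimulus_onset_h]
  if (length(prior) == 0) {
    stop("no Before peak precedes the stimulus onset", call. = FALSE)
  }
  ref <- max(prior)
  (18 + (stimulus_onset_h - ref) * 24 / tau_before) %% 24
}

#' Entrainment filter on the During period
#'
#' A cell counts as entrained when its fitted During period lies within
#' `tol_h` (default 1 h, inclusive) of the zeitgeber cycle length.
#'
#' @param tau_during Fitted During period(s) (h).
#' @param protocol A [temperature_protocol()].
#' @param tol_h Tolerance (h). Default 1.
#' @return Logical.
#' @export
entrainment_filter <- function(tau_during, protocol, tol_h = 1) {
  abs(tau_during - protocol$cycle_length_h) <= tol_h
}

#' Assemble a phase-response curve from single-stimulus shifts
#'
#' Groups shifts by the circadian time at which the stimulus hit the cell:
#' onsets in `[CT6, CT18)` form the delay group, the remainder (`[CT18,
#' CT6)` across midnight) the advance group. Reports group means with SEM, a
#' Welch two-sample t-test between the groups, and -- for display only -- a
#' 4th-order polynomial least-squares fit of shift on onset CT, fitted on CT
#' unwrapped to `[6, 30)` so the curve is continuous across the midnight
#' gap.
#'
#' @param shifts Tibble with `onset_ct`, `shift_ct`, optionally `cell_id`
#'   and `fold_change` (amplitude response).
#' @return Object of class `prc`: list with `table` (the input plus
#'   `group`), `groups` (per-group n/mean/SEM), `t_test` (htest or NULL),
#'   `poly_fit` (lm). Supports `tidy()` and `autoplot()`.
#' @export
build_prc <- function(shifts) {
  stopifnot(all(c("onset_ct", "shift_ct") %in% names(shifts)))
  if (nrow(shifts) < 3) stop("need at least 3 shifts to build a PRC",
                             call. = FALSE)
  tab <- shifts |>
    dplyr::mutate(group = ifelse(.data$onset_ct >= 6 & .data$onset_ct < 18,
                                 "delay", "advance"))
  groups <- tab |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_shift = mean(.data$shift_ct),
      sem_shift = stats::sd(.data$shift_ct) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  both <- all(c("delay", "advance") %in% groups$group) &&
    all(groups$n[match(c("delay", "advance"), groups$group)] >= 2)
  tt <- if (both) {
    tryCatch(stats::t.test(shift_ct ~ group, data = tab),
             error = function(e) NULL)  # e.g. zero-variance groups
  } else {
    NULL
  }
  ct_unwrapped <- ifelse(tab$onset_ct < 6, tab$onset_ct + 24, tab$onset_ct)
  pf <- stats::lm(shift_ct ~ poly(ct, 4, raw = TRUE),
                  data = data.frame(ct = ct_unwrapped,
                                    shift_ct = tab$shift_ct))
  structure(list(table = tab, groups = groups, t_test = tt, poly_fit = pf),
            class = "prc")
}

#' @export
print.prc <- function(x, ...) {
  cat("Phase-response curve:", nrow(x$table), "stimuli\n")
  print(x$groups)
  if (!is.null(x$t_test)) {
    cat(sprintf("delay vs advance: t = %.3g, p = %.3g\n",
                x$t_test$statistic, x$t_test$p.value))
  }
  invisible(x)
}

#' Amplitude response to a stimulus (fold change)
#'
#' Fold change of the relative amplitude after vs before the stimulus:
#' `relative_amplitude(after) / relative_amplitude(before)`.
#'
#' @param before_fit,after_fit Accepted `cosine_fit`s.
#' @param raw_before,raw_after Raw (unprocessed) values of the two segments.
#' @return Numeric fold change.
#' @export
amplitude_response <- function(before_fit, after_fit, raw_before, raw_after) {
  ra_b <- relative_amplitude(before_fit, raw_before)
  if (ra_b <= 0) stop("zero Before amplitude: fold change undefined",
                      call. = FALSE)
  relative_amplitude(after_fit, raw_after) / ra_b
}

#' Phase relationship between entrained peaks and the cold phase
#'
#' For each entrained cell, the signed lag (real hours, in `(-T/2, T/2]`)
#' between each of its last two During peaks and the onset of the nearest
#' cold phase is averaged; an ordinary least-squares regression of this lag
#' on the cell's intrinsic Before period then asks whether the entrained
#' phase relationship depends on the intrinsic period.
#'
#' @param peaks_during Tibble `cell_id`, `peak_time_h` of During peaks.
#' @param protocol A [temperature_protocol()].
#' @param tau_before Tibble `cell_id`, `tau_before`.
#' @return List: `table` (`cell_id`, `mean_lag_h`, `tau_before`; cells with
#'   fewer than 2 peaks in the last two cycles are dropped), `slope`, `r2`,
#'   `p`, and the `lm` fit.
#' @export
phase_relationship <- function(peaks_during, protocol, tau_before) {
  T <- protocol$cycle_length_h
  last2_start <- protocol$end_h - 2 * T
  lag_of <- function(p) {
    l <- (p - protocol$start_h) %% T
    ifelse(l > T / 2, l - T, l)
  }
  tab <- peaks_during |>
    dplyr::filter(.data$peak_time_h >= last2_start,
                  .data$peak_time_h < protocol$end_h) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(mean_lag_h = mean(lag_of(.data$peak_time_h)),
                     .groups = "drop") |>
    dplyr::inner_join(tau_before, by = "cell_id")
  if (nrow(tab) < 3) {
    return(list(table = tab, slope = NA_real_, r2 = NA_real_, p = NA_real_,
                fit = NULL))
  }
  fit <- stats::lm(mean_lag_h ~ tau_before, data = tab)
  sm <- summary(fit)
  list(table = tab, slope = unname(stats::coef(fit)[2]),
       r2 = sm$r.squared,
       p = stats::coef(sm)[2, 4],
       fit = fit)
}
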