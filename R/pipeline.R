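#' Build a run configuration
#'
#' All analysis parameters with their conventional defaults: 30-min
#' sampling, 24-h detrending window, 18-30 h circadian band, last-3-cycles
#' During fits, 11-h peak smoothing, 30-point parabola windows, +-1 h
#' entrainment tolerance. Any block can be overridden.
#'
#' @param protocol List of [temperature_protocol()] arguments.
#' @param synthetic List: `n_cells`, `duration_h`, `dt_h`, `dt_obs_h`, and
#'   `params` (overrides for [oscillator_params()]).
#' @param input_traces Optional path to a tidy trace CSV (`cell_id`,
#'   `time_h`, `value`); when given, the synthetic block is ignored.
#' @param preprocess,rhythms,phase Parameter blocks (see defaults in source).
#' @param seed Integer master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(protocol = list(cycle_length_h = 20, cold_h = 10,
                                       delta_t = 4, n_cycles = 6,
                                       start_h = 72, temp_warm = 37),
                       synthetic = list(), input_traces = NULL,
                       preprocess = list(), rhythms = list(), phase = list(),
                       seed = 1) {
  syn <- utils::modifyList(
    list(n_cells = 20, duration_h = 264, dt_h = 0.05, dt_obs_h = 0.5,
         params = list()),
    synthetic
  )
  structure(
    list(
      protocol = protocol,
      synthetic = syn,
      input_traces = input_traces,
      preprocess = utils::modifyList(
        list(window_h = 24, normalize = TRUE, last_k = 3), preprocess),
      rhythms = utils::modifyList(list(period_band = c(18, 30)), rhythms),
      phase = utils::modifyList(
        list(smooth_window_h = 11, fit_points = 30, min_separation_h = 12,
             entrain_tol_h = 1), phase),
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Demonstration configurations
#'
#' `demo_config("t20")` is a synthetic fibroblast-style experiment: 20
#' cells, intrinsic periods near 24 h, six T20 cycles (10 h at 33 degC /
#' 10 h at 37 degC) starting at 72 h, with forcing strong enough to entrain
#' within three cycles. `demo_config("t24")` applies the same forcing with a
#' T24 (12 h / 12 h) cycle, a near-resonant zeitgeber that leaves the mean
#' period essentially unchanged.
#'
#' @param which `"t20"` or `"t24"`.
#' @param seed Master seed. Default 1.
#' @param n_cells Number of cells. Default 20.
#' @return A `run_config`.
#' @export
demo_config <- function(which = c("t20", "t24"), seed = 1, n_cells = 20) {
  which <- match.arg(which)
  T <- if (which == "t20") 20 else 24
  cold <- T / 2
  run_config(
    protocol = list(cycle_length_h = T, cold_h = cold, delta_t = 4,
                    n_cycles = 6, start_h = 72, temp_warm = 37),
    synthetic = list(
      n_cells = n_cells,
      duration_h = 72 + 6 * T + 72,
      params = list(forcing_eps = 1.2)
    ),
    seed = seed
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates trace generation (or loading), viability QC, preprocessing,
#' stage-wise cosine fits, peak picking, circadian-time conversion,
#' and circular statistics. Deterministic given the config seed.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, all result tables are
#'   written there as CSV plus a `run_log.json` with the full configuration
#'   (no timestamps, so repeated runs are byte-identical).
#' @return A list of class `circatrack_run`: `traces_raw`, `traces`, `qc`,
#'   `fits`, `period_summary`, `peaks`, `phases`, `circ`, `stats`,
#'   `protocol`, `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  protocol <- do.call(temperature_protocol, config$protocol)

  if (!is.null(config$input_traces)) {
    traces_raw <- readr::read_csv(config$input_traces, show_col_types = FALSE)
    if (nrow(traces_raw) == 0) {
      stop("input trace table is empty; nothing to analyze", call. = FALSE)
    }
    traces_raw <- dplyr::select(traces_raw, "cell_id", "time_h", "value")
  } else {
    syn <- config$synthetic
    params <- do.call(oscillator_params, syn$params)
    sim <- simulate_cells(syn$n_cells, protocol, params, syn$duration_h,
                          dt_h = syn$dt_h, dt_obs_h = syn$dt_obs_h,
                          seed = config$seed)
    traces_raw <- sim$traces
  }

  # viability QC on raw traces
  qc <- traces_raw |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(~ dplyr::select(viability_qc(.x), -"cell_id")) |>
    dplyr::ungroup()
  kept <- qc$cell_id[qc$keep]
  if (length(kept) == 0) stop("all cells excluded by viability QC",
                              call. = FALSE)
  traces_kept <- dplyr::filter(traces_raw, .data$cell_id %in% kept)

  pp <- config$preprocess
  traces <- preprocess_traces(traces_kept, protocol,
                              normalize = pp$normalize,
                              window_h = pp$window_h, last_k = pp$last_k)

  fits <- fit_stages(traces, raw_traces = traces_kept,
                     period_band = config$rhythms$period_band)
  psum <- period_summary(fits)

  ph <- config$phase
  peaks <- pick_peaks_all(traces, smooth_window_h = ph$smooth_window_h,
                          fit_points = ph$fit_points,
                          min_separation_h = ph$min_separation_h)

  phases <- stage_phases(peaks, fits, protocol)
  circ <- circular_summary(phases)

  stats <- run_stats(fits, phases)

  run <- structure(
    list(traces_raw = traces_raw, traces = traces, qc = qc, fits = fits,
         period_summary = psum, peaks = peaks, phases = phases, circ = circ,
         stats = stats, protocol = protocol, config = config),
    class = "circatrack_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Representative circadian peak phase per cell and stage
#'
#' Follows the reporting convention for polar phase plots: `Before` uses the
#' last peak before the cycles, `During` the circular mean of the last two
#' During-peak phases, `After` the first peak after release. Before/After
#' phases rescale the recording time axis by the cell's own fitted period
#' (`24/tau` circadian hours per hour); During phases use the entrained
#' conversion (CT12 = end of cold phase).
#'
#' @param peaks [pick_peaks_all()] output with `stage`.
#' @param fits [fit_stages()] output (accepted periods per stage).
#' @param protocol A [temperature_protocol()].
#' @return Tibble `cell_id`, `stage`, `ct`.
#' @export
stage_phases <- function(peaks, fits, protocol) {
  acc <- dplyr::filter(fits, .data$accepted)
  tau_of <- function(id, st) {
    v <- acc$tau[acc$cell_id == id & acc$stage == st]
    if (length(v) == 1) v else NA_real_
  }
  rows <- list()
  for (id in unique(peaks$cell_id)) {
    pk <- peaks[peaks$cell_id == id, ]
    bf <- pk$peak_time_h[pk$stage == "Before"]
    du <- pk$peak_time_h[pk$stage == "During"]
    af <- pk$peak_time_h[pk$stage == "After"]
    tb <- tau_of(id, "Before")
    ta <- tau_of(id, "After")
    if (length(bf) > 0 && !is.na(tb)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        cell_id = id, stage = "Before",
        ct = to_circadian_free_run(max(bf), tb, ref_time_h = 0, ref_ct = 0))
    }
    if (length(du) >= 1) {
      last2 <- utils::tail(sort(du), 2)
      cts <- to_circadian_entrained(last2, protocol)
      md <- mean_direction(ct_to_angle(cts))
      if (md$defined) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          cell_id = id, stage = "During", ct = angle_to_ct(md$mean_angle))
      }
    }
    if (length(af) > 0 && !is.na(ta)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        cell_id = id, stage = "After",
        ct = to_circadian_free_run(min(af), ta, ref_time_h = 0, ref_ct = 0))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(cell_id = character(0), stage = character(0),
                          ct = numeric(0)))
  }
  out$stage <- factor(out$stage, levels = c("Before", "During", "After"))
  dplyr::arrange(out, .data$cell_id, .data$stage)
}

# reporting-level closed-form statistics (paired t-tests on periods,
# Watson-Williams on phases)
run_stats <- function(fits, phases) {
  out <- list()
  acc <- dplyr::filter(fits, .data$accepted)
  wide <- tidyr::pivot_wider(dplyr::select(acc, "cell_id", "stage", "tau"),
                             names_from = "stage", values_from = "tau")
  pair <- function(s1, s2) {
    if (!all(c(s1, s2) %in% names(wide))) return(NULL)
    d <- wide[stats::complete.cases(wide[, c(s1, s2)]), ]
    if (nrow(d) < 3) return(NULL)
    tt <- stats::t.test(d[[s1]], d[[s2]], paired = TRUE)
    tibble::tibble(test = sprintf("paired t: tau %s vs %s", s1, s2),
                   statistic = unname(tt$statistic), p = tt$p.value,
                   n = nrow(d))
  }
  out$before_during <- pair("Before", "During")
  out$before_after <- pair("Before", "After")
  a <- phases$ct[phases$stage == "Before"]
  b <- phases$ct[phases$stage == "During"]
  if (length(a) >= 5 && length(b) >= 5) {
    ww <- watson_williams(ct_to_angle(a), ct_to_angle(b))
    out$phase_bd <- tibble::tibble(
      test = "Watson-Williams: phase Before vs During",
      statistic = ww$F, p = ww$p, n = ww$n_a + ww$n_b)
  }
  dplyr::bind_rows(out)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) readr::write_csv(x, file.path(out_dir, name))
  wr(run$qc, "qc.csv")
  wr(run$traces, "traces_processed.csv")
  wr(run$fits, "fits.csv")
  wr(run$period_summary, "period_summary.csv")
  wr(run$peaks, "peaks.csv")
  wr(run$phases, "phases.csv")
  wr(run$circ, "circstats.csv")
  if (nrow(run$stats) > 0) wr(run$stats, "stats.csv")
  cfg <- run$config
  log <- list(
    config = cfg[setdiff(names(cfg), "class")],
    config_hash = rlang::hash(cfg),
    n_cells_in = length(unique(run$traces_raw$cell_id)),
    n_cells_kept = length(unique(run$traces$cell_id))
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.circatrack_run <- function(x, ...) {
  cat("circatrack run:", length(unique(x$traces$cell_id)), "cells kept of",
      length(unique(x$traces_raw$cell_id)), "\n")
  print(x$protocol)
  cat("\nPeriod summary:\n")
  print(x$period_summary)
  cat("\nPhase clustering (Rayleigh):\n")
  print(x$circ)
  invisible(x)
}

#' Read / write protocol and parameter configs as YAML
#'
#' @param path YAML file.
#' @return `read_config_yaml` returns a `run_config`.
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_config_yaml
#' @param config A `run_config`.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
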