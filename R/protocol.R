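#' Define a temperature-cycle (T-cycle) protocol
#'
#' A T-cycle is a square-wave zeitgeber: `n_cycles` repeats of a cold phase
#' followed by a warm phase, embedded in an otherwise constant-temperature
#' recording. The canonical protocols are T20 (10 h at 33 degC, 10 h at
#' 37 degC) and T24 (12 h / 12 h), both with `delta_t = 4` degC, starting a
#' few days into the recording. Each cycle starts with the cold phase. The
#' protocol partitions the recording into the three analysis stages
#' `Before` (free run), `During` (cycles applied) and `After` (free run).
#'
#' @param cycle_length_h Cycle length T in hours (e.g. 20 or 24).
#' @param cold_h Duration of the cold phase in hours; must be `< cycle_length_h`.
#' @param delta_t Temperature difference warm - cold in degC (> 0).
#' @param n_cycles Number of cycles (>= 1).
#' @param start_h Time of the first cold-phase onset, hours from recording start.
#' @param temp_warm Warm-phase temperature in degC (default 37, the culture
#'   temperature; the recording outside the cycles is held at this value).
#'
#' @return An object of class `temperature_protocol`: a list with fields
#'   `cycle_length_h`, `cold_h`, `warm_h`, `temp_cold`, `temp_warm`,
#'   `delta_t`, `n_cycles`, `start_h`, `end_h`.
#' @examples
#' t20 <- temperature_protocol(20, 10, 4, 6, 72)
#' temperature_at(t20, c(71, 73, 85))
#' @export
temperature_protocol <- function(cycle_length_h, cold_h, delta_t, n_cycles,
                                 start_h, temp_warm = 37) {
  stopifnot(is.numeric(cycle_length_h), is.numeric(cold_h), is.numeric(delta_t))
  if (cycle_length_h <= 0 || cold_h <= 0 || cold_h >= cycle_length_h) {
    stop("invalid protocol: need 0 < cold_h < cycle_length_h", call. = FALSE)
  }
  if (delta_t <= 0) stop("invalid protocol: delta_t must be > 0", call. = FALSE)
  if (n_cycles < 1) stop("invalid protocol: n_cycles must be >= 1", call. = FALSE)
  if (start_h < 0) stop("invalid protocol: start_h must be >= 0", call. = FALSE)
  structure(
    list(
      cycle_length_h = cycle_length_h,
      cold_h = cold_h,
      warm_h = cycle_length_h - cold_h,
      temp_cold = temp_warm - delta_t,
      temp_warm = temp_warm,
      delta_t = delta_t,
      n_cycles = as.integer(n_cycles),
      start_h = start_h,
      end_h = start_h + n_cycles * cycle_length_h
    ),
    class = "temperature_protocol"
  )
}

#' @export
print.temperature_protocol <- function(x, ...) {
  cat(sprintf(
    "T%g temperature protocol: %d x (%g h @ %g degC cold, %g h @ %g degC warm)\n",
    x$cycle_length_h, x$n_cycles, x$cold_h, x$temp_cold, x$warm_h, x$temp_warm
  ))
  cat(sprintf("  During: [%g, %g) h; constant %g degC outside\n",
              x$start_h, x$end_h, x$temp_warm))
  invisible(x)
}

#' Temperature at given times
#'
#' Square wave, cold first within each cycle; `temp_warm` (constant culture
#' temperature) outside the `During` window.
#'
#' @param protocol A [temperature_protocol()].
#' @param time_h Numeric vector of times in hours from recording start.
#' @return Numeric vector of temperatures in degC.
#' @export
temperature_at <- function(protocol, time_h) {
  stopifnot(inherits(protocol, "temperature_protocol"))
  inside <- time_h >= protocol$start_h & time_h < protocol$end_h
  phase <- (time_h - protocol$start_h) %% protocol$cycle_length_h
  ifelse(inside & phase < protocol$cold_h, protocol$temp_cold, protocol$temp_warm)
}

#' Normalized thermal forcing z(t)
#'
#' The zeitgeber input the synthetic oscillator sees. Inside the During
#' window `z(t) = (temperature_at(t) - midpoint) / delta_t`, i.e. -1/2
#' during cold phases and +1/2 during warm phases; outside the cycles the
#' culture sits at its constant reference temperature and no zeitgeber is
#' applied, so `z = 0` (the forcing is the cyclic deviation, not the
#' absolute temperature).
#'
#' @inheritParams temperature_at
#' @return Numeric vector in `{-1/2, 0, +1/2}`.
#' @export
forcing_z <- function(protocol, time_h) {
  mid <- (protocol$temp_warm + protocol$temp_cold) / 2
  inside <- time_h >= protocol$start_h & time_h < protocol$end_h
  ifelse(inside,
         (temperature_at(protocol, time_h) - mid) / protocol$delta_t,
         0)
}

#' Stage boundaries of a protocol
#'
#' Half-open partition of the recording: `Before = [0, start_h)`,
#' `During = [start_h, end_h)`, `After = [end_h, recording end)`; also the
#' During sub-window restricted to the last `last_k` cycles, used for
#' During-period fits to minimize transients.
#'
#' @param protocol A [temperature_protocol()].
#' @param last_k How many final cycles make up the `during_last` window
#'   (default 3).
#' @return A list with `before = c(0, start_h)`, `during = c(start_h, end_h)`,
#'   `during_last = c(end_h - last_k*T, end_h)`, and `end_h`.
#' @export
protocol_stages <- function(protocol, last_k = 3) {
  k <- min(last_k, protocol$n_cycles)
  list(
    before = c(0, protocol$start_h),
    during = c(protocol$start_h, protocol$end_h),
    during_last = c(protocol$end_h - k * protocol$cycle_length_h, protocol$end_h),
    end_h = protocol$end_h
  )
}

#' Onsets and ends of the cold phases
#'
#' @param protocol A [temperature_protocol()].
#' @return A tibble with one row per cycle: `cycle`, `cold_onset_h`,
#'   `cold_end_h`.
#' @export
cold_phases <- function(protocol) {
  k <- seq_len(protocol$n_cycles) - 1L
  tibble::tibble(
    cycle = k + 1L,
    cold_onset_h = protocol$start_h + k * protocol$cycle_length_h,
    cold_end_h = protocol$start_h + k * protocol$cycle_length_h + protocol$cold_h
  )
}
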