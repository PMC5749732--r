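#' Parameters of the synthetic single-cell oscillator population
#'
#' The generator integrates, per cell, a stochastic Poincare (amplitude-phase)
#' oscillator -- the standard minimal limit-cycle model for cellular circadian
#' clocks -- with additive square-wave thermal forcing on the x-coordinate and
#' optional all-to-all mean-field coupling. It is a phenomenological stand-in
#' for the recordings the analysis is designed for, not a mechanistic
#' gene-network model.
#'
#' @param tau_mean Mean intrinsic free-running period (h). Default 24.
#' @param tau_sd SD of intrinsic periods across cells (h). Default 1.5.
#'   Periods are drawn from a normal truncated to the circadian band
#'   \[18, 30\] h.
#' @param lambda_relax Amplitude relaxation rate (1/h). Default 0.1.
#' @param amp_target Limit-cycle radius A (arbitrary units). Default 1.
#' @param forcing_eps Thermal forcing strength (rad/h per unit normalized
#'   temperature). Default 0.6, strong enough that a T20 cycle entrains a
#'   24 h oscillator within about 3 cycles.
#' @param coupling_K Mean-field coupling strength (1/h). Default 0
#'   (dispersed fibroblast-like cultures); positive values emulate dense,
#'   communicating cultures.
#' @param noise_phase_sd Intensity of the intrinsic white noise on the
#'   oscillator coordinates, scaled so that for r near A it acts as phase
#'   diffusion of about this many rad per sqrt(h). Default 0.02.
#' @param noise_obs_sd SD of additive observation noise (gray levels).
#'   Default 3.
#' @param baseline0 Initial bioluminescence baseline (gray levels).
#'   Default 150.
#' @param damping_halflife_h Half-life of the slow multiplicative baseline
#'   decay (h), emulating luciferin consumption/cell settling. Default
#'   120, slow enough that a 10-11 day recording retains well over the 10%
#'   final signal that the viability screen demands of analyzable cells.
#' @param init_phase_kappa von Mises concentration of the initial phases.
#'   Default 0 (uniform: an unsynchronized free-running culture); positive
#'   values emulate cultures partially synchronized by plating or a medium
#'   change.
#' @return A list of class `oscillator_params`.
#' @export
oscillator_params <- function(tau_mean = 24, tau_sd = 1.5, lambda_relax = 0.1,
                              amp_target = 1, forcing_eps = 0.6,
                              coupling_K = 0, noise_phase_sd = 0.02,
                              noise_obs_sd = 3, baseline0 = 150,
                              damping_halflife_h = 120,
                              init_phase_kappa = 0) {
  p <- list(
    tau_mean = tau_mean, tau_sd = tau_sd, lambda_relax = lambda_relax,
    amp_target = amp_target, forcing_eps = forcing_eps,
    coupling_K = coupling_K, noise_phase_sd = noise_phase_sd,
    noise_obs_sd = noise_obs_sd, baseline0 = baseline0,
    damping_halflife_h = damping_halflife_h,
    init_phase_kappa = init_phase_kappa
  )
  if (p$tau_mean < 18 || p$tau_mean > 30) {
    stop("tau_mean must lie in the circadian band [18, 30] h", call. = FALSE)
  }
  rates <- c(p$lambda_relax, p$forcing_eps, p$coupling_K, p$noise_phase_sd,
             p$noise_obs_sd, p$tau_sd)
  if (any(rates < 0)) stop("rates and noise SDs must be >= 0", call. = FALSE)
  if (p$amp_target <= 0) stop("amp_target must be > 0", call. = FALSE)
  class(p) <- "oscillator_params"
  p
}

# normal truncated to [lo, hi] by rejection; n small so this is cheap
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Simulate a population of single-cell circadian reporter traces
#'
#' Integrates `n_cells` coupled stochastic Poincare oscillators by
#' Euler-Maruyama and converts the x-coordinate into a bioluminescence-like
#' gray-value trace with a slowly decaying baseline and additive observation
#' noise, sampled every `dt_obs_h` (default 0.5 h, matching 30-min camera
#' exposures).
#'
#' The per-cell state is `(x, y)` with radius `r = sqrt(x^2 + y^2)`:
#' \deqn{dx = [-(2\pi/\tau_i) y + \lambda x (A - r) + K(\bar x - x) +
#'   \epsilon z(t)] dt + \sigma A\, dW_x}
#' \deqn{dy = [ (2\pi/\tau_i) x + \lambda y (A - r) + K(\bar y - y)] dt +
#'   \sigma A\, dW_y}
#' where `z(t)` is the normalized temperature [forcing_z()] (-1/2 cold,
#' +1/2 warm/constant), `x-bar, y-bar` are population means (mean-field
#' coupling) and `tau_i ~ TruncNormal(tau_mean, tau_sd, [18, 30])`. The
#' observable is
#' `b(t) = baseline0 * 2^(-t/halflife) * (1 + (x + A)/(2A)) + N(0, noise_obs_sd)`.
#' Initial phases sit on the limit cycle (radius A), drawn uniformly (an
#' unsynchronized free-running culture) or from a von Mises distribution
#' when `init_phase_kappa > 0` (a partially synchronized culture).
#'
#' @param n_cells Number of cells (>= 1).
#' @param protocol A [temperature_protocol()], or `NULL` for constant
#'   temperature (no forcing).
#' @param params An [oscillator_params()] list.
#' @param duration_h Recording length (h); must cover the protocol.
#' @param dt_h Integration step (h), must be <= 0.1 and divide `dt_obs_h`.
#' @param dt_obs_h Observation sampling interval (h). Default 0.5.
#' @param seed Integer seed; identical inputs + seed give identical output.
#'
#' @return A list of class `simulated_population` with tibbles
#'   `traces` (`cell_id`, `time_h`, `value`), `cells` (`cell_id`,
#'   `true_tau`), and `phase` (`cell_id`, `time_h`, `phase_rad` in
#'   \[0, 2pi); phase 0 is the trace maximum of the noise-free oscillator).
#' @examples
#' t20 <- temperature_protocol(20, 10, 4, 6, 72)
#' sim <- simulate_cells(3, t20, duration_h = 240, seed = 1)
#' head(sim$traces)
#' @export
simulate_cells <- function(n_cells, protocol = NULL,
                           params = oscillator_params(), duration_h,
                           dt_h = 0.05, dt_obs_h = 0.5, seed = 1) {
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  if (dt_h > 0.1) stop("dt_h too coarse for stable integration (need <= 0.1 h)",
                       call. = FALSE)
  steps_per_obs <- dt_obs_h / dt_h
  if (abs(steps_per_obs - round(steps_per_obs)) > 1e-9) {
    stop("dt_h must divide dt_obs_h", call. = FALSE)
  }
  steps_per_obs <- round(steps_per_obs)
  if (!is.null(protocol) && protocol$end_h > duration_h) {
    stop("duration_h must cover the protocol", call. = FALSE)
  }
  set.seed(seed)
  p <- params
  A <- p$amp_target
  tau <- rtruncnorm(n_cells, p$tau_mean, p$tau_sd, 18, 30)
  omega <- 2 * pi / tau

  phi0 <- if (p$init_phase_kappa > 0) {
    rvonmises(n_cells, mu = stats::runif(1, 0, 2 * pi),
              kappa = p$init_phase_kappa)
  } else {
    stats::runif(n_cells, 0, 2 * pi)
  }
  x <- A * cos(phi0)
  y <- A * sin(phi0)

  n_obs <- floor(duration_h / dt_obs_h) + 1L
  t_obs <- (seq_len(n_obs) - 1L) * dt_obs_h
  xs <- matrix(NA_real_, n_obs, n_cells)
  ys <- matrix(NA_real_, n_obs, n_cells)
  xs[1, ] <- x
  ys[1, ] <- y

  n_steps <- (n_obs - 1L) * steps_per_obs
  t_grid <- (seq_len(n_steps) - 1L) * dt_h
  z <- if (is.null(protocol)) rep(0, n_steps) else forcing_z(protocol, t_grid)
  sig <- p$noise_phase_sd * A * sqrt(dt_h)

  for (s in seq_len(n_steps)) {
    r <- sqrt(x^2 + y^2)
    relax <- p$lambda_relax * (A - r)
    xb <- mean(x); yb <- mean(y)
    dx <- (-omega * y + relax * x + p$coupling_K * (xb - x) +
             p$forcing_eps * z[s]) * dt_h
    dy <- (omega * x + relax * y + p$coupling_K * (yb - y)) * dt_h
    if (sig > 0) {
      dx <- dx + sig * stats::rnorm(n_cells)
      dy <- dy + sig * stats::rnorm(n_cells)
    }
    x <- x + dx
    y <- y + dy
    if (s %% steps_per_obs == 0L) {
      k <- s %/% steps_per_obs + 1L
      xs[k, ] <- x
      ys[k, ] <- y
    }
  }

  env <- p$baseline0 * 2^(-t_obs / p$damping_halflife_h)
  b <- env * (1 + (xs + A) / (2 * A))
  if (p$noise_obs_sd > 0) {
    b <- b + matrix(stats::rnorm(length(b), 0, p$noise_obs_sd), nrow(b))
  }

  ids <- sprintf("cell_%02d", seq_len(n_cells))
  traces <- tibble::tibble(
    cell_id = rep(ids, each = n_obs),
    time_h = rep(t_obs, n_cells),
    value = as.vector(b)
  )
  phase <- tibble::tibble(
    cell_id = rep(ids, each = n_obs),
    time_h = rep(t_obs, n_cells),
    phase_rad = as.vector(atan2(ys, xs)) %% (2 * pi)
  )
  structure(
    list(
      traces = traces,
      cells = tibble::tibble(cell_id = ids, true_tau = tau),
      phase = phase,
      protocol = protocol,
      params = p,
      dt_obs_h = dt_obs_h,
      seed = seed
    ),
    class = "simulated_population"
  )
}

#' Ground-truth peak times of simulated cells
#'
#' Times at which the (noise-free) oscillator phase crosses 0 mod 2pi, i.e.
#' the maxima of the x-coordinate and hence of the rendered bioluminescence
#' rhythm. Crossings are located by linear interpolation of the unwrapped
#' phase on the observation grid.
#'
#' @param sim A [simulate_cells()] result.
#' @return Tibble with `cell_id`, `peak_time_h`.
#' @export
true_peak_times <- function(sim) {
  stopifnot(inherits(sim, "simulated_population"))
  sim$phase |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(d, key) {
      phi <- unwrap_phase(d$phase_rad)
      targets <- seq(ceiling(phi[1] / (2 * pi)), floor(phi[length(phi)] / (2 * pi)))
      if (length(targets) == 0) {
        return(tibble::tibble(peak_time_h = numeric(0)))
      }
      tt <- vapply(targets * 2 * pi, function(target) {
        i <- which(phi[-1] >= target & phi[-length(phi)] < target)[1]
        if (is.na(i)) return(NA_real_)
        w <- (target - phi[i]) / (phi[i + 1] - phi[i])
        d$time_h[i] + w * (d$time_h[i + 1] - d$time_h[i])
      }, numeric(1))
      tibble::tibble(peak_time_h = tt[!is.na(tt)])
    }) |>
    dplyr::ungroup()
}

# unwrap angles (rad) to a continuous increasing-ish series
unwrap_phase <- function(phi) {
  d <- diff(phi)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(phi[1], d))
}

#' Render a synthetic bioluminescence movie from simulated cells
#'
#' Each cell becomes an isotropic Gaussian spot whose integrated intensity
#' equals its trace value at that frame; spot centers follow a reflected
#' random walk (cell motility). Additive Gaussian background noise and
#' salt-type "hot pixels" (transient bright outliers, for testing outlier
#' removal) complete the image model. One frame is rendered per observation
#' sample.
#'
#' @param sim A [simulate_cells()] result.
#' @param frame_shape_px `c(height, width)` in pixels. Default `c(64, 64)`.
#' @param spot_sigma_px Gaussian spot SD in px. Default 1.5 (a compact,
#'   clearly visible cell at 10x magnification).
#' @param motility_sd_px Per-frame displacement SD in px. Default 0.3.
#' @param background_level Constant background offset (gray). Default 10.
#' @param noise_sd Background noise SD (gray). Default 1; with the default
#'   trace scale this leaves cells well above the noise floor, as in usable
#'   recordings.
#' @param hot_pixel_rate Per-pixel probability of a hot pixel per frame.
#'   Default 0.
#' @param hot_pixel_value Gray value added at a hot pixel. Default 1000.
#' @param seed Integer seed for positions and pixel noise.
#' @return A list of class `rendered_movie`: `stack` (array time x height x
#'   width, gray values >= 0), `tracks` (tibble `frame`, `cell_id`, `row`,
#'   `col` -- ground-truth continuous positions, 0-based like pixel
#'   coordinates), `dt_h`.
#' @export
render_movie <- function(sim, frame_shape_px = c(64, 64), spot_sigma_px = 1.5,
                         motility_sd_px = 0.3, background_level = 10,
                         noise_sd = 1, hot_pixel_rate = 0,
                         hot_pixel_value = 1000, seed = 1) {
  stopifnot(inherits(sim, "simulated_population"))
  set.seed(seed)
  h <- frame_shape_px[1]; w <- frame_shape_px[2]
  wide <- tidyr::pivot_wider(sim$traces, names_from = "cell_id",
                             values_from = "value")
  t_obs <- wide$time_h
  vals <- as.matrix(wide[, -1, drop = FALSE])
  n_frames <- length(t_obs)
  n_cells <- ncol(vals)
  margin <- 3 * spot_sigma_px
  if (2 * margin >= min(h, w)) {
    stop("spots do not fit inside the frame", call. = FALSE)
  }

  # reflected random walk per cell, continuous 0-based coordinates
  pos <- array(NA_real_, c(n_frames, n_cells, 2))
  pos[1, , 1] <- stats::runif(n_cells, margin, h - 1 - margin)
  pos[1, , 2] <- stats::runif(n_cells, margin, w - 1 - margin)
  reflect <- function(u, lo, hi) {
    span <- 2 * (hi - lo)
    v <- (u - lo) %% span
    lo + pmin(v, span - v)
  }
  for (f in seq_len(n_frames - 1L)) {
    step <- matrix(stats::rnorm(2 * n_cells, 0, motility_sd_px), n_cells)
    pos[f + 1L, , 1] <- reflect(pos[f, , 1] + step[, 1], margin, h - 1 - margin)
    pos[f + 1L, , 2] <- reflect(pos[f, , 2] + step[, 2], margin, w - 1 - margin)
  }

  rows <- seq_len(h) - 1
  cols <- seq_len(w) - 1
  stack <- array(background_level, c(n_frames, h, w))
  overlap <- FALSE
  for (f in seq_len(n_frames)) {
    frame <- matrix(0, h, w)
    for (i in seq_len(n_cells)) {
      kr <- stats::dnorm(rows, pos[f, i, 1], spot_sigma_px)
      kc <- stats::dnorm(cols, pos[f, i, 2], spot_sigma_px)
      frame <- frame + vals[f, i] * outer(kr, kc)
    }
    if (!overlap && n_cells > 1) {
      dmin <- min(stats::dist(pos[f, , , drop = TRUE]))
      if (dmin < 2 * spot_sigma_px) overlap <- TRUE
    }
    stack[f, , ] <- stack[f, , ] + frame
  }
  if (noise_sd > 0) {
    stack <- stack + array(stats::rnorm(length(stack), 0, noise_sd), dim(stack))
  }
  if (hot_pixel_rate > 0) {
    hot <- stats::runif(length(stack)) < hot_pixel_rate
    stack[hot] <- stack[hot] + hot_pixel_value
  }
  stack[stack < 0] <- 0
  if (overlap) warning("spot centers came within 2*spot_sigma of each other")

  tracks <- tibble::tibble(
    frame = rep(seq_len(n_frames), n_cells),
    cell_id = rep(colnames(vals), each = n_frames),
    row = as.vector(pos[, , 1]),
    col = as.vector(pos[, , 2])
  )
  structure(list(stack = stack, tracks = tracks, dt_h = sim$dt_obs_h),
            class = "rendered_movie")
}

#' Write / read an image stack as multi-page TIFF
#'
#' Stacks are stored as 16-bit grayscale; `write_stack_tiff` scales by
#' `1/scale_max` into \[0, 1\] as the tiff package expects, and
#' `read_stack_tiff` undoes the scaling.
#'
#' @param stack Array (time x height x width), values in `[0, scale_max]`.
#' @param path Output file.
#' @param scale_max Full-scale gray value (default 65535).
#' @return `path`, invisibly (writer); the stack array (reader).
#' @export
write_stack_tiff <- function(stack, path, scale_max = 65535) {
  frames <- lapply(seq_len(dim(stack)[1]), function(f) {
    m <- stack[f, , ] / scale_max
    m[m > 1] <- 1
    m[m < 0] <- 0
    m
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, scale_max = 65535) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  stack <- array(NA_real_, c(length(frames), dim(frames[[1]])[1:2]))
  for (f in seq_along(frames)) {
    m <- frames[[f]]
    if (length(dim(m)) == 3) m <- m[, , 1]
    stack[f, , ] <- m * scale_max
  }
  stack
}
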