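#' Map circadian time to an angle
#'
#' CT0 maps to angle 0, counterclockwise, `2*pi` per 24 circadian hours.
#'
#' @param ct Circadian times (h).
#' @return Angles in `[0, 2pi)`.
#' @export
ct_to_angle <- function(ct) (2 * pi * ct / 24) %% (2 * pi)

#' @rdname ct_to_angle
#' @param angle_rad Angles (rad).
#' @export
angle_to_ct <- function(angle_rad) (24 * angle_rad / (2 * pi)) %% 24

#' Circular mean direction and resultant length
#'
#' The mean of the unit vectors `(cos a, sin a)`: its direction is the mean
#' angle, its length `R-bar` in `[0, 1]` measures phase clustering (1 =
#' unanimous, 0 = balanced). The mean angle is undefined (NA, flagged) when
#' `R-bar` vanishes.
#'
#' @param angles_rad Numeric vector of angles (rad), n >= 1.
#' @return List `mean_angle` (rad in `[0, 2pi)`, NA if undefined), `r_bar`,
#'   `n`, `defined`.
#' @export
mean_direction <- function(angles_rad) {
  n <- length(angles_rad)
  if (n == 0) stop("empty circular sample", call. = FALSE)
  C <- mean(cos(angles_rad))
  S <- mean(sin(angles_rad))
  r <- sqrt(C^2 + S^2)
  defined <- r >= 1e-12
  list(
    mean_angle = if (defined) atan2(S, C) %% (2 * pi) else NA_real_,
    r_bar = r, n = n, defined = defined
  )
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether a circular sample is uniformly distributed against a
#' unimodal alternative. The statistic is `Z = n * R-bar^2`; the p-value
#' uses the standard series approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - Z n)) - (1 + 2n))`, accurate for n of a
#' few and above. The conventional significance level for phase clustering
#' is p < 0.05. For n < 3 the p-value is flagged unreliable.
#'
#' @param angles_rad Numeric vector of angles (rad).
#' @return One-row tibble: `n`, `r_bar`, `mean_angle_rad`, `mean_ct`, `Z`,
#'   `p`, `reliable`.
#' @export
rayleigh_test <- function(angles_rad) {
  md <- mean_direction(angles_rad)
  n <- md$n
  Z <- n * md$r_bar^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Z * n)) - (1 + 2 * n))
  p <- min(max(p, 0), 1)
  tibble::tibble(
    n = n, r_bar = md$r_bar, mean_angle_rad = md$mean_angle,
    mean_ct = if (md$defined) angle_to_ct(md$mean_angle) else NA_real_,
    Z = Z, p = p, reliable = n >= 3
  )
}

# ML-style estimate of the von Mises concentration from R-bar
# (standard piecewise approximation)
kappa_from_rbar <- function(r) {
  if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
}

#' Watson-Williams test for equal mean directions of two circular samples
#'
#' The circular analogue of the two-sample test: with group resultant
#' lengths `R1`, `R2` and pooled resultant `R`, the statistic is
#' \deqn{F = K (N - 2) \frac{R_1 + R_2 - R}{N - R_1 - R_2}}
#' with the standard concentration correction `K = 1 + 3/(8 kappa)`, `kappa`
#' estimated from the weighted mean resultant length `(R1 + R2)/N`, compared
#' to `F(1, N - 2)`. The test assumes von Mises samples with common, fairly
#' high concentration; when `(R1 + R2)/N < 0.45` a warning flag is set.
#'
#' @param angles_a,angles_b Numeric angle vectors (rad), both non-empty;
#'   n >= 5 per group recommended.
#' @return One-row tibble: `n_a`, `n_b`, `F`, `p`, `kappa`, `rbar_within`,
#'   `assumption_ok`.
#' @export
watson_williams <- function(angles_a, angles_b) {
  if (length(angles_a) == 0 || length(angles_b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n1 <- length(angles_a); n2 <- length(angles_b); N <- n1 + n2
  R1 <- n1 * mean_direction(angles_a)$r_bar
  R2 <- n2 * mean_direction(angles_b)$r_bar
  R <- N * mean_direction(c(angles_a, angles_b))$r_bar
  rw <- (R1 + R2) / N
  kappa <- kappa_from_rbar(rw)
  K <- 1 + 3 / (8 * kappa)
  denom <- N - R1 - R2
  Fstat <- if (denom <= 0) Inf else K * (N - 2) * (R1 + R2 - R) / denom
  p <- stats::pf(Fstat, 1, N - 2, lower.tail = FALSE)
  tibble::tibble(
    n_a = n1, n_b = n2, F = Fstat, p = p, kappa = kappa,
    rbar_within = rw, assumption_ok = rw >= 0.45
  )
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; used for calibration simulations of the
#' circular tests.
#'
#' @param n Number of draws.
#' @param mu Mean direction (rad).
#' @param kappa Concentration (>= 0); 0 gives the uniform distribution.
#' @return Angles in `[0, 2pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    ok <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    theta <- sign(u3 - 0.5) * acos(f)
    acc <- theta[ok]
    k <- length(acc)
    if (k > 0) {
      out[(got + 1):(got + k)] <- acc
      got <- got + k
    }
  }
  (out + mu) %% (2 * pi)
}

#' Circular summary of peak phases per stage
#'
#' Runs [rayleigh_test()] on the CT phases of each stage (and any further
#' grouping column).
#'
#' @param phases Tibble with `ct` and `stage` (plus optional grouping
#'   columns in `...`).
#' @param ... Extra grouping columns.
#' @return Tibble of Rayleigh results, one row per group.
#' @export
circular_summary <- function(phases, ...) {
  phases |>
    dplyr::group_by(.data$stage, ...) |>
    dplyr::group_modify(~ rayleigh_test(ct_to_angle(.x$ct))) |>
    dplyr::ungroup()
}
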