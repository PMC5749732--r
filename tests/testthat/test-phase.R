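test_that("a sampled parabola yields its vertex exactly", {
  t <- seq(35, 65, 0.5)
  seg <- tibble::tibble(time_h = t, value = -(t - 50)^2 + 100)
  pk <- pick_peaks(seg)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$peak_time_h, 50, tolerance = 1e-9)
  expect_equal(pk$peak_height, 100, tolerance = 1e-9)
})

test_that("noiseless cosine peaks are located to within a few minutes", {
  t <- seq(0, 96, 0.5)
  seg <- tibble::tibble(time_h = t, value = 30 * cos(2 * pi * t / 24) + 100)
  pk <- pick_peaks(seg)
  truth <- c(24, 48, 72)  # interior maxima (0 and 96 sit on the boundary)
  matched <- vapply(truth, function(tt) min(abs(pk$peak_time_h - tt)),
                    numeric(1))
  expect_true(all(matched < 0.05))
  # minimum separation respected
  expect_true(all(diff(pk$peak_time_h) >= 12))
})

test_that("flat input yields an empty peak set, not an error", {
  seg <- tibble::tibble(time_h = seq(0, 48, 0.5), value = rep(3, 97))
  expect_equal(nrow(pick_peaks(seg)), 0)
})

test_that("peaks of noisy simulated cells sit near the true phase maxima", {
  sim <- simulate_cells(8, NULL, oscillator_params(forcing_eps = 0),
                        duration_h = 144, seed = 12)
  tr <- sim$traces
  tr$stage <- factor("Before", levels = c("Before", "During", "After"))
  tr <- detrend_running_average(tr)
  pk <- pick_peaks_all(tr)
  truth <- dplyr::rename(true_peak_times(sim), true_time_h = "peak_time_h")
  err <- pk |>
    dplyr::filter(peak_time_h > 12, peak_time_h < 132) |>  # skip detrend edges
    dplyr::inner_join(truth, by = "cell_id", relationship = "many-to-many") |>
    dplyr::group_by(cell_id, peak_time_h) |>
    dplyr::summarise(err = min(abs(peak_time_h - true_time_h)),
                     .groups = "drop")
  expect_gt(nrow(err), 20)
  expect_true(all(err$err < 0.5))
})

test_that("free-running circadian time rescales by the cell's own period", {
  expect_equal(to_circadian_free_run(50, 24, ref_time_h = 50), 18)
  expect_equal(to_circadian_free_run(56, 24, ref_time_h = 50), 0)
  expect_equal(to_circadian_free_run(56, 20, ref_time_h = 50), 1.2)
  expect_error(to_circadian_free_run(56, 17, ref_time_h = 50), "band")
  expect_error(to_circadian_free_run(56, 24, ref_time_h = NULL), "reference")
})

test_that("entrained circadian time anchors the cold-phase end at CT12", {
  t20 <- temperature_protocol(20, 10, 4, 6, 72)
  expect_equal(to_circadian_entrained(82, t20), 12)      # end of first cold
  expect_equal(to_circadian_entrained(87, t20), 18)      # +5 h on T20
  expect_equal(to_circadian_entrained(102, t20), 12)     # next cycle, same CT
  t24 <- temperature_protocol(24, 12, 4, 6, 72)
  expect_equal(to_circadian_entrained(96, t24), 0)       # +12 h on T24
  expect_error(to_circadian_entrained(60, t20), "During")
})

test_that("the expected peak extrapolates the Before fit forward", {
  seg <- cosine_segment(a = 30, tau = 24, theta = 0, offset = 100, t_end = 71.5)
  f <- fit_cosine(seg)
  expect_equal(expected_peak(f, 71), 72, tolerance = 1e-6)
  seg20 <- cosine_segment(a = 30, tau = 20, theta = 0, offset = 100,
                          t_end = 71.5)
  f20 <- fit_cosine(seg20)
  expect_equal(expected_peak(f20, 71), 80, tolerance = 1e-6)
  f20$tau <- 17  # outside the band: rejected fits cannot be extrapolated
  expect_error(expected_peak(f20, 71), "rejected")
})

test_that("phase shifts follow the delay-negative sign convention", {
  expect_equal(phase_shift(48, 52, 24), -4)
  expect_equal(phase_shift(48, 48, 24), 0)
  expect_equal(phase_shift(50, 48, 20), 2.4)
  # the multiply convention is available but distinct
  expect_equal(phase_shift(50, 48, 20, convention = "multiply"), 2 * 20 / 24)
  expect_error(phase_shift(48, 62, 24), "ambiguous")
})

test_that("the shift identity holds to machine precision on a grid", {
  for (tau in c(18, 20.5, 24, 27, 30)) {
    deltas <- seq(-tau / 2 + 0.1, tau / 2 - 0.1, length.out = 21)
    got <- vapply(deltas, function(d) phase_shift(60, 60 + d, tau), numeric(1))
    expect_equal(got, -deltas * 24 / tau, tolerance = 1e-12)
  }
})

test_that("peak pairing picks the nearest candidate within half a period", {
  expect_equal(match_actual_peak(72, c(50, 71, 95), 24), 71)
  expect_true(is.na(match_actual_peak(72, c(50, 95), 20)))
  expect_true(is.na(match_actual_peak(72, numeric(0), 24)))
})

test_that("stimulus-onset circadian time is anchored at the CT18 peak", {
  expect_equal(onset_ct(72, c(40, 72), 24), 18)
  expect_equal(onset_ct(78, c(40, 72), 24), 0)
  expect_equal(onset_ct(92, c(40, 72), 24), 14)
  expect_error(onset_ct(30, c(40, 72), 24), "precedes")
})

test_that("entrainment requires the During period within 1 h of the cycle", {
  t20 <- temperature_protocol(20, 10, 4, 6, 72)
  expect_true(entrainment_filter(20.4, t20))
  expect_true(entrainment_filter(21.0, t20))
  expect_false(entrainment_filter(21.5, t20))
})

test_that("PRC grouping separates delays (CT6-18) from advances", {
  shifts <- tibble::tibble(onset_ct = c(8, 12, 20), shift_ct = c(-3, -5, 2))
  prc <- build_prc(shifts)
  g <- prc$groups
  expect_equal(g$mean_shift[g$group == "delay"], -4)
  expect_equal(g$mean_shift[g$group == "advance"], 2)

  zeros <- tibble::tibble(onset_ct = c(2, 8, 14, 20), shift_ct = rep(0, 4))
  prc0 <- build_prc(zeros)
  expect_true(all(prc0$groups$mean_shift == 0))
  # zero-variance groups cannot be significantly different
  p0 <- if (is.null(prc0$t_test)) NA_real_ else prc0$t_test$p.value
  expect_true(is.na(p0) || p0 > 0.05)

  expect_error(build_prc(shifts[1:2, ]), "3")
})

test_that("amplitude response is the fold change of relative amplitudes", {
  seg <- cosine_segment(a = 10, tau = 24, theta = 0, offset = 100, t_end = 96)
  f <- fit_cosine(seg)
  raw <- rep(100, 20)
  expect_equal(amplitude_response(f, f, raw, raw), 1, tolerance = 1e-9)
  f2 <- f; f2$a <- 20
  expect_equal(amplitude_response(f, f2, raw, raw), 2, tolerance = 1e-9)
})

test_that("phase relationships regress entrained lag on intrinsic period", {
  t20 <- temperature_protocol(20, 10, 4, 6, 72)
  onsets <- cold_phases(t20)$cold_onset_h[5:6]
  taus <- tibble::tibble(cell_id = c("a", "b", "c", "d"),
                         tau_before = c(24.1, 24.5, 25, 25.5))
  # peaks exactly at the cold onsets: zero lag for everyone
  pk0 <- tidyr::expand_grid(cell_id = taus$cell_id, peak_time_h = onsets)
  pr0 <- phase_relationship(pk0, t20, taus)
  expect_true(all(abs(pr0$table$mean_lag_h) < 1e-12))
  expect_equal(pr0$slope, 0, tolerance = 1e-12)

  # constructed linear dependence: lag = 2 * (tau - 24)
  pk1 <- taus |>
    dplyr::rowwise() |>
    dplyr::reframe(cell_id = cell_id,
                   peak_time_h = onsets + 2 * (tau_before - 24))
  pr1 <- phase_relationship(pk1, t20, taus)
  expect_equal(pr1$slope, 2, tolerance = 1e-9)
  expect_equal(pr1$r2, 1, tolerance = 1e-9)
})

test_that("CT conversions are 24-periodic in their natural arguments", {
  t20 <- temperature_protocol(20, 10, 4, 6, 72)
  # one zeitgeber cycle later: same entrained CT
  expect_equal(to_circadian_entrained(85, t20),
               to_circadian_entrained(85 + 20, t20))
  # one intrinsic period later: same free-running CT
  expect_equal(to_circadian_free_run(60, 22, ref_time_h = 10),
               to_circadian_free_run(60 + 22, 22, ref_time_h = 10),
               tolerance = 1e-9)
})

test_that("entrained and free-running CT agree for phase-locked resonant cells", {
  # tau == T == 24, noise-free, strongly forced: peaks lock to the zeitgeber
  t24 <- temperature_protocol(24, 12, 4, 6, 72)
  sim <- simulate_cells(3, t24,
                        oscillator_params(forcing_eps = 1.2, tau_sd = 0,
                                          noise_phase_sd = 0,
                                          noise_obs_sd = 0),
                        duration_h = 288, seed = 13)
  tr <- preprocess_traces(sim$traces, t24)
  pk <- pick_peaks_all(tr)
  last2 <- pk |>
    dplyr::filter(stage == "During", peak_time_h >= t24$end_h - 48)
  for (id in unique(last2$cell_id)) {
    p <- last2$peak_time_h[last2$cell_id == id]
    ct_e <- to_circadian_entrained(p, t24)
    # free-run conversion anchored one intrinsic period earlier at the same CT
    ct_f <- to_circadian_free_run(p, 24, ref_time_h = p - 24,
                                  ref_ct = ct_e[1])
    expect_equal(ct_f[1], ct_e[1], tolerance = 0.2)
    # and the locked peaks repeat at the same entrained CT
    if (length(p) == 2) expect_equal(ct_e[1], ct_e[2], tolerance = 0.2)
  }
})
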