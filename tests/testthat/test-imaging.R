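make_stack <- function(frames) {
  # frames: list of matrices
  out <- array(NA_real_, c(length(frames), nrow(frames[[1]]), ncol(frames[[1]])))
  for (i in seq_along(frames)) out[i, , ] <- frames[[i]]
  out
}

test_that("temporal denoising leaves constants fixed and trusts gain 0 fully", {
  const <- make_stack(replicate(5, matrix(7, 4, 4), simplify = FALSE))
  expect_equal(kalman_stack_filter(const), const)
  noisy <- make_stack(lapply(1:5, function(i) matrix(i * 1.5, 3, 3)))
  expect_equal(kalman_stack_filter(noisy, gain = 0), noisy)
  expect_error(kalman_stack_filter(noisy[1, , , drop = FALSE]), "2 frames")
  expect_error(kalman_stack_filter(noisy, gain = 1), "gain")
})

test_that("the denoising recursion matches a hand-executed scalar oracle", {
  z <- c(10, 20, 20, 20)
  stack <- array(z, c(4, 1, 1))
  got <- as.vector(kalman_stack_filter(stack, gain = 0.8,
                                       initial_variance = 0.05))
  expect_equal(got, kalman_scalar_oracle(z, 0.8, 0.05), tolerance = 1e-12)
  # and with other settings
  got2 <- as.vector(kalman_stack_filter(stack, gain = 0.5,
                                        initial_variance = 1))
  expect_equal(got2, kalman_scalar_oracle(z, 0.5, 1), tolerance = 1e-12)
  # smoothing: later estimates lie between first value and the plateau
  expect_true(all(got[2:4] > 10 & got[2:4] < 20))
})

test_that("outlier removal replaces only deviant pixels, strictly above threshold", {
  frame <- matrix(50, 7, 7)
  frame[4, 4] <- 250  # +200 hot pixel
  st <- make_stack(list(frame))
  out <- remove_outliers(st, radius_px = 1, threshold = 100)
  expect_equal(out[1, 4, 4], 50)
  hot_idx <- (4 - 1) * 7 + 4  # column-major linear index of the hot pixel
  expect_equal(out[1, , ][-hot_idx], frame[-hot_idx])  # others untouched
  # deviation exactly at the threshold is kept
  frame2 <- matrix(50, 5, 5)
  frame2[3, 3] <- 150
  out2 <- remove_outliers(make_stack(list(frame2)), 1, 100)
  expect_equal(out2[1, 3, 3], 150)
  # ... but epsilon more is replaced
  frame2[3, 3] <- 150.001
  out3 <- remove_outliers(make_stack(list(frame2)), 1, 100)
  expect_equal(out3[1, 3, 3], 50)
})

test_that("outlier removal equals the brute-force median oracle and is idempotent", {
  set.seed(42)
  frame <- matrix(stats::runif(15 * 12, 0, 300), 15, 12)
  st <- make_stack(list(frame))
  got <- remove_outliers(st, 1, 100)[1, , ]
  expect_equal(got, median_outlier_oracle(frame, 1, 100))
  # radius 2 as well
  got2 <- remove_outliers(st, 2, 50)[1, , ]
  expect_equal(got2, median_outlier_oracle(frame, 2, 50))
})

test_that("outlier removal is idempotent on sparse impulsive noise", {
  set.seed(43)
  base <- outer(seq(40, 80, length.out = 20), seq(60, 90, length.out = 18),
                function(a, b) (a + b) / 2)  # smooth background
  frame <- base
  hits <- cbind(sample(20, 6), sample(18, 6))
  frame[hits] <- frame[hits] + 400  # sparse hot pixels
  st <- array(frame, c(1, 20, 18))
  once <- remove_outliers(st, 1, 100)
  expect_equal(remove_outliers(once, 1, 100), once)
})

test_that("background is the mean of ROI means, per frame", {
  st <- make_stack(replicate(3, matrix(7, 8, 8), simplify = FALSE))
  rois <- tibble::tibble(row0 = c(0, 0, 6, 6), col0 = c(0, 6, 0, 6),
                         row1 = c(2, 2, 8, 8), col1 = c(2, 8, 2, 8))
  expect_equal(estimate_background(st, rois), rep(7, 3))

  frame <- matrix(0, 8, 8)
  frame[1:2, 1:2] <- 2; frame[1:2, 7:8] <- 4
  frame[7:8, 1:2] <- 6; frame[7:8, 7:8] <- 8
  expect_equal(estimate_background(make_stack(list(frame)), rois), 5)

  bad <- tibble::tibble(row0 = 0, col0 = 0, row1 = 0, col1 = 2)
  expect_error(estimate_background(st, bad), "empty")
})

test_that("background series recovers a known additive offset on a rendered movie", {
  sim <- simulate_cells(1, NULL, oscillator_params(noise_obs_sd = 0), 24,
                        seed = 3)
  mov <- render_movie(sim, frame_shape_px = c(48, 48), background_level = 25,
                      noise_sd = 1, motility_sd_px = 0, seed = 3)
  # corner ROIs far from the single centered-ish spot
  rois <- tibble::tibble(row0 = c(0, 0, 44, 44), col0 = c(0, 44, 0, 44),
                         row1 = c(4, 4, 48, 48), col1 = c(4, 48, 4, 48))
  bg <- estimate_background(mov$stack, rois)
  expect_lt(max(abs(bg - 25)), 1)  # spot tails + noise/sqrt(npix)
})

test_that("a static bright spot is tracked without drifting", {
  frame <- matrix(1, 9, 9)
  frame[5, 6] <- 100
  st <- make_stack(replicate(6, frame, simplify = FALSE))
  tr <- track_spot(st, start_pos = c(4, 5), max_step_px = 2)
  expect_true(all(tr$positions$row == 4))
  expect_true(all(tr$positions$col == 5))
})

test_that("tracking is globally optimal and prefers smooth paths over bright jumps", {
  # dim smooth spot vs bright jittery spot, 5 frames
  frames <- lapply(1:5, function(f) {
    m <- matrix(0, 9, 9)
    m[5, 2 + f - 1] <- 100                       # smooth: one column per frame
    m[ifelse(f %% 2 == 1, 2, 8), 2 + f - 1] <- 200  # bright, jumps 6 px
    m
  })
  st <- make_stack(frames)
  cands <- lapply(frames, function(m) {
    idx <- which(m > 0, arr.ind = TRUE)
    cbind(idx[, 1] - 1L, idx[, 2] - 1L)
  })
  got <- track_spot(st, start_pos = c(4, 1), max_step_px = 7,
                    motion_penalty = 0.5)
  best <- enumerate_best_path(st, cands, 7, 0.5)
  for (f in 1:5) {
    expect_equal(got$positions$row[f], best$path[[f]][1])
    expect_equal(got$positions$col[f], best$path[[f]][2])
  }
  expect_true(all(got$positions$row == 4))  # the smooth path
  # with no motion penalty the bright jumper wins instead
  got0 <- track_spot(st, start_pos = c(4, 1), max_step_px = 7,
                     motion_penalty = 0)
  best0 <- enumerate_best_path(st, cands, 7, 0)
  expect_equal(got0$positions$row, vapply(best0$path, `[`, integer(1), 1))
})

test_that("tracking reports the frame where the target is lost", {
  frames <- lapply(1:4, function(f) {
    m <- matrix(0, 9, 9)
    if (f < 3) m[5, 5] <- 100 else m[1, 1] <- 100  # jumps beyond reach
    m
  })
  expect_error(track_spot(make_stack(frames), c(4, 4), max_step_px = 2),
               "frame 3")
})

test_that("trace extraction averages the window and clips at borders", {
  st <- make_stack(replicate(4, matrix(9, 6, 6), simplify = FALSE))
  tr <- extract_trace(st, fixed_track(4, c(2, 2)))
  expect_equal(tr$value, rep(9, 4))
  expect_equal(tr$time_h, (0:3) * 0.5)

  frame <- matrix(0, 7, 7)
  frame[4, 4] <- 90
  tr2 <- extract_trace(make_stack(list(frame, frame)), fixed_track(2, c(3, 3)))
  expect_equal(tr2$value, rep(10, 2))  # 90 / 9

  # border clipping: corner window has 4 pixels
  frame3 <- matrix(8, 5, 5)
  tr3 <- extract_trace(make_stack(list(frame3)), fixed_track(1, c(0, 0)))
  expect_equal(tr3$value, 8)
})

test_that("adding a constant to the stack adds it to the extracted trace", {
  set.seed(1)
  st <- array(stats::runif(10 * 12 * 12, 0, 200), c(10, 12, 12))
  chain <- function(s) {
    s2 <- remove_outliers(kalman_stack_filter(s), 1, 100)
    extract_trace(s2, fixed_track(10, c(6, 6)))$value
  }
  base <- chain(st)
  shifted <- chain(st + 55)
  expect_equal(shifted, base + 55, tolerance = 1e-9)
})

test_that("viability QC keeps rhythmic cells and names the exclusion reason", {
  t <- seq(0, 120, 0.5)
  good <- tibble::tibble(cell_id = "a", time_h = t,
                         value = 100 + 30 * cos(2 * pi * t / 24))
  expect_true(viability_qc(good)$keep)

  dying <- tibble::tibble(cell_id = "b", time_h = t,
                          value = (100 + 30 * cos(2 * pi * t / 24)) *
                            exp(-t / 20))
  qc <- viability_qc(dying)
  expect_false(qc$keep)
  expect_equal(qc$reason, "strong reduction")

  flat <- tibble::tibble(cell_id = "c", time_h = t, value = 200)
  qc2 <- viability_qc(flat)
  expect_false(qc2$keep)
  expect_equal(qc2$reason, "loss of rhythmicity")
})
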