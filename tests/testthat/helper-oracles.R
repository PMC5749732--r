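# Independent oracles, kept deliberately naive and separate from the package
# implementations they check.

# Profiled grid search for the cosine model: for each trial period the
# remaining parameters are linear and solved exactly; returns the period at
# the residual-sum-of-squares minimum.
grid_cosine_tau <- function(time_h, value, taus = seq(18, 30, length.out = 201)) {
  rss <- vapply(taus, function(tau) {
    X <- cbind(cos(2 * pi * time_h / tau), sin(2 * pi * time_h / tau), 1)
    sum(stats::lm.fit(X, value)$residuals^2)
  }, numeric(1))
  list(tau = taus[which.min(rss)], step = taus[2] - taus[1], rss = min(rss))
}

# Scalar step-by-step execution of the documented denoising recursion.
kalman_scalar_oracle <- function(z, gain, initial_variance) {
  R <- gain / (1 - gain)
  Q <- 1 - gain
  est <- z[1]
  P <- initial_variance
  out <- numeric(length(z))
  out[1] <- est
  for (t in 2:length(z)) {
    K <- P / (P + R)
    est <- est + K * (z[t] - est)
    P <- (1 - K) * P + Q
    out[t] <- est
  }
  out
}

# Brute-force per-pixel median replacement with replicated edges.
median_outlier_oracle <- function(frame, r, threshold) {
  h <- nrow(frame); w <- ncol(frame)
  out <- frame
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      ri <- pmin(pmax((i - r):(i + r), 1), h)
      cj <- pmin(pmax((j - r):(j + r), 1), w)
      med <- stats::median(as.vector(frame[ri, cj]))
      if (abs(frame[i, j] - med) > threshold) out[i, j] <- med
    }
  }
  out
}

# Exhaustive enumeration of all feasible candidate paths on a tiny movie;
# mirrors the tracking score definition but explores every path.
enumerate_best_path <- function(stack, cands, max_step_px, motion_penalty) {
  lo <- min(stack); hi <- max(stack)
  norm <- (stack - lo) / (hi - lo)
  n <- length(cands)
  best <- list(score = -Inf, path = NULL)
  recurse <- function(t, path, score) {
    if (t > n) {
      if (score > best$score) best <<- list(score = score, path = path)
      return(invisible())
    }
    for (k in seq_len(nrow(cands[[t]]))) {
      p <- cands[[t]][k, ]
      inten <- norm[t, p[1] + 1, p[2] + 1]
      if (t == 1) {
        recurse(2, list(p), inten)
      } else {
        prev <- path[[t - 1]]
        d2 <- sum((p - prev)^2)
        if (d2 <= max_step_px^2) {
          recurse(t + 1, c(path, list(p)), score + inten - motion_penalty * d2)
        }
      }
    }
  }
  recurse(1, list(), 0)
  best
}

# noiseless cosine segment builder
cosine_segment <- function(a = 30, tau = 24, theta = 1, offset = 100,
                           t_end = 96, dt = 0.5, t0 = 0) {
  t <- seq(t0, t_end, dt)
  tibble::tibble(time_h = t,
                 value = a * cos(2 * pi * t / tau - theta) + offset)
}
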