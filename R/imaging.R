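#' Temporal Kalman-type denoising of an image stack
#'
#' Per-pixel scalar recursive filter in the spirit of the Kalman stack filters
#' used for low-light bioluminescence movies. For each pixel, with
#' observations `z_t`:
#' \preformatted{
#'   xhat_0 = z_0,  P_0 = initial_variance
#'   for t >= 1:  K = P / (P + R)
#'                xhat_t = xhat_{t-1} + K * (z_t - xhat_{t-1})
#'                P <- (1 - K) * P + Q
#' }
#' with measurement variance `R = gain / (1 - gain)` and process noise
#' `Q = 1 - gain`, so that the update weight `K` converges to `1 - gain`:
#' asymptotically the filter is an exponentially weighted average in which
#' `gain` is the weight held by the running estimate. `gain = 0` gives `K = 1`
#' everywhere, i.e. the identity (the measurement is fully trusted). The
#' first frame always passes through unchanged. Defaults (gain 0.8, initial
#' variance 0.05) follow common stack-filter practice. This recursion is one
#' documented interpretation of the loosely specified plugin-style filters.
#'
#' @param stack Numeric array, time x height x width, >= 2 frames.
#' @param gain Prediction weight in `[0, 1)`. Default 0.8.
#' @param initial_variance Initial estimate variance `P_0` (> 0). Default 0.05.
#' @return Filtered stack, same dimensions.
#' @export
kalman_stack_filter <- function(stack, gain = 0.8, initial_variance = 0.05) {
  check_stack(stack)
  if (gain < 0 || gain >= 1) stop("gain must be in [0, 1)", call. = FALSE)
  if (initial_variance <= 0) stop("initial_variance must be > 0", call. = FALSE)
  n <- dim(stack)[1]
  if (n < 2) stop("stack must have at least 2 frames", call. = FALSE)
  if (gain == 0) return(stack)
  R <- gain / (1 - gain)
  Q <- 1 - gain
  out <- stack
  P <- initial_variance
  est <- stack[1, , ]
  for (t in 2:n) {
    K <- P / (P + R)
    est <- est + K * (stack[t, , ] - est)
    P <- (1 - K) * P + Q
    out[t, , ] <- est
  }
  out
}

#' Replace impulsive outlier pixels by the local median
#'
#' Per frame, each pixel whose value deviates from the median of its
#' `(2r+1)^2` neighborhood (edges replicated) by strictly more than
#' `threshold` is replaced by that median; bright and dark outliers are both
#' handled. Defaults (radius 1, threshold 100) match common practice for
#' intensified-camera hot pixels.
#'
#' @param stack Numeric array, time x height x width (a single frame may be
#'   passed as a 1 x h x w array).
#' @param radius_px Neighborhood half-width (>= 1). Default 1.
#' @param threshold Deviation beyond which a pixel is replaced (> 0; strict
#'   inequality, so a deviation exactly equal to the threshold is kept).
#'   Default 100.
#' @return Cleaned stack, same dimensions. Idempotent for fixed parameters.
#' @export
remove_outliers <- function(stack, radius_px = 1, threshold = 100) {
  check_stack(stack)
  if (radius_px < 1) stop("radius_px must be >= 1", call. = FALSE)
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  out <- stack
  for (t in seq_len(dim(stack)[1])) {
    frame <- stack[t, , ]
    med <- neighborhood_median(frame, radius_px)
    bad <- abs(frame - med) > threshold
    frame[bad] <- med[bad]
    out[t, , ] <- frame
  }
  out
}

# median over the (2r+1)^2 replicated-edge neighborhood of every pixel
neighborhood_median <- function(frame, r) {
  h <- nrow(frame); w <- ncol(frame)
  idx_r <- function(shift) pmin(pmax(seq_len(h) + shift, 1L), h)
  idx_c <- function(shift) pmin(pmax(seq_len(w) + shift, 1L), w)
  shifts <- expand.grid(dr = -r:r, dc = -r:r)
  stackmat <- vapply(
    seq_len(nrow(shifts)),
    function(k) as.vector(frame[idx_r(shifts$dr[k]), idx_c(shifts$dc[k])]),
    numeric(h * w)
  )
  matrix(apply(stackmat, 1, stats::median), h, w)
}

#' Per-frame background estimate from cell-free ROIs
#'
#' The background of each frame is the mean of the per-ROI mean gray values,
#' conventionally over four rectangular ROIs that contain no cells.
#'
#' @param stack Numeric array, time x height x width.
#' @param rois Data frame with 0-based half-open rectangles: columns `row0`,
#'   `col0`, `row1`, `col1` (pixel `(r, c)` is inside iff
#'   `row0 <= r < row1` and `col0 <= c < col1`).
#' @return Numeric vector, one background value per frame.
#' @export
estimate_background <- function(stack, rois) {
  check_stack(stack)
  rois <- tibble::as_tibble(rois)
  if (nrow(rois) == 0) stop("need at least one background ROI", call. = FALSE)
  h <- dim(stack)[2]; w <- dim(stack)[3]
  roi_means <- vapply(seq_len(nrow(rois)), function(i) {
    r <- rois[i, ]
    if (r$row1 <= r$row0 || r$col1 <= r$col0) {
      stop("empty background ROI", call. = FALSE)
    }
    if (r$row0 < 0 || r$col0 < 0 || r$row1 > h || r$col1 > w) {
      stop("background ROI outside frame bounds", call. = FALSE)
    }
    sub <- stack[, (r$row0 + 1):r$row1, (r$col0 + 1):r$col1, drop = FALSE]
    apply(sub, 1, mean)
  }, numeric(dim(stack)[1]))
  rowMeans(matrix(roi_means, nrow = dim(stack)[1]))
}

#' Track a moving bioluminescent spot through a stack
#'
#' Globally optimal dynamic-programming tracking: candidate positions in each
#' frame are local intensity maxima; a path may move at most `max_step_px`
#' pixels between consecutive frames and its score is
#' `sum(normalized intensity) - motion_penalty * sum(squared displacement)`.
#' The returned track maximizes this score over all feasible paths (global
#' optimum, not greedy), which keeps the tracker on dim cells that move and
#' oscillate at the same time. Immobile cells (e.g. manually chosen neuron
#' ROIs) are covered by [fixed_track()].
#'
#' @param stack Numeric array, time x height x width.
#' @param start_pos `c(row, col)`, 0-based, inside frame 1; the track is
#'   constrained to start within `max_step_px` of this position.
#' @param max_step_px Maximum per-frame displacement (px). Default 3.
#' @param motion_penalty Weight of the squared-displacement penalty relative
#'   to normalized intensity. Default 0.05.
#' @return A list of class `spot_track`: tibble `positions` (`frame`, `row`,
#'   `col`; 0-based integer pixel coordinates) and the path `score`.
#' @export
track_spot <- function(stack, start_pos, max_step_px = 3, motion_penalty = 0.05) {
  check_stack(stack)
  n <- dim(stack)[1]; h <- dim(stack)[2]; w <- dim(stack)[3]
  if (start_pos[1] < 0 || start_pos[1] > h - 1 ||
      start_pos[2] < 0 || start_pos[2] > w - 1) {
    stop("start_pos outside frame", call. = FALSE)
  }
  lo <- min(stack); hi <- max(stack)
  norm <- if (hi > lo) (stack - lo) / (hi - lo) else stack * 0

  cand <- vector("list", n)
  for (t in seq_len(n)) {
    cc <- local_maxima(norm[t, , ])
    # drop global-minimum plateaus (e.g. flat zero background)
    keep_c <- cc$intensity > min(norm[t, , ])
    if (any(keep_c)) cc <- cc[keep_c, , drop = FALSE]
    cand[[t]] <- cc
  }
  # frame 1: restrict to candidates within reach of the seed
  d0 <- (cand[[1]]$row - start_pos[1])^2 + (cand[[1]]$col - start_pos[2])^2
  keep <- d0 <= max_step_px^2
  if (!any(keep)) stop("tracking lost at frame 1: no candidate near start_pos",
                       call. = FALSE)
  cand[[1]] <- cand[[1]][keep, , drop = FALSE]

  score <- cand[[1]]$intensity
  back <- vector("list", n)
  for (t in 2:n) {
    cur <- cand[[t]]
    prev <- cand[[t - 1]]
    d2 <- outer(cur$row, prev$row, "-")^2 + outer(cur$col, prev$col, "-")^2
    trans <- sweep(-motion_penalty * d2, 2, score, "+")
    trans[d2 > max_step_px^2] <- -Inf
    best_prev <- apply(trans, 1, which.max)
    best_val <- trans[cbind(seq_len(nrow(cur)), best_prev)]
    feasible <- is.finite(best_val)
    if (!any(feasible)) {
      stop(sprintf("tracking lost at frame %d: no candidate within %g px",
                   t, max_step_px), call. = FALSE)
    }
    cand[[t]] <- cur[feasible, , drop = FALSE]
    score <- best_val[feasible] + cur$intensity[feasible]
    back[[t]] <- best_prev[feasible]
  }

  path_row <- integer(n); path_col <- integer(n)
  j <- which.max(score)
  final_score <- score[j]
  for (t in n:1) {
    path_row[t] <- cand[[t]]$row[j]
    path_col[t] <- cand[[t]]$col[j]
    if (t > 1) j <- back[[t]][j]
  }
  structure(
    list(
      positions = tibble::tibble(frame = seq_len(n), row = path_row,
                                 col = path_col),
      score = final_score
    ),
    class = "spot_track"
  )
}

# 8-neighborhood local maxima of one frame; 0-based coordinates
local_maxima <- function(frame) {
  h <- nrow(frame); w <- ncol(frame)
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- frame
  is_max <- matrix(TRUE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
    is_max <- is_max & (frame >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  tibble::tibble(row = idx[, 1] - 1L, col = idx[, 2] - 1L,
                 intensity = frame[idx])
}

#' Fixed-position track for immobile cells
#'
#' @param n_frames Number of frames.
#' @param pos `c(row, col)`, 0-based.
#' @return A `spot_track` whose position is constant.
#' @export
fixed_track <- function(n_frames, pos) {
  structure(
    list(
      positions = tibble::tibble(frame = seq_len(n_frames),
                                 row = rep(round(pos[1]), n_frames),
                                 col = rep(round(pos[2]), n_frames)),
      score = NA_real_
    ),
    class = "spot_track"
  )
}

#' Extract an intensity trace along a track
#'
#' Signal strength per frame is the mean gray value over the `(2r+1)^2`
#' window centered on the tracked pixel (default 3x3); windows are clipped
#' at frame borders (the mean is then over the in-frame pixels).
#'
#' @param stack Numeric array, time x height x width.
#' @param track A `spot_track`.
#' @param window_radius_px Window half-width (default 1, i.e. 3x3).
#' @param dt_h Hours per frame (default 0.5).
#' @param cell_id Label for the output trace.
#' @return A trace tibble: `cell_id`, `time_h`, `value`.
#' @export
extract_trace <- function(stack, track, window_radius_px = 1, dt_h = 0.5,
                          cell_id = "cell_01") {
  check_stack(stack)
  n <- dim(stack)[1]; h <- dim(stack)[2]; w <- dim(stack)[3]
  pos <- track$positions
  stopifnot(nrow(pos) == n)
  r <- window_radius_px
  vals <- vapply(seq_len(n), function(t) {
    r0 <- max(pos$row[t] - r, 0) + 1
    r1 <- min(pos$row[t] + r, h - 1) + 1
    c0 <- max(pos$col[t] - r, 0) + 1
    c1 <- min(pos$col[t] + r, w - 1) + 1
    mean(stack[t, r0:r1, c0:c1])
  }, numeric(1))
  tibble::tibble(cell_id = cell_id, time_h = (seq_len(n) - 1) * dt_h,
                 value = vals)
}

#' Viability quality control of a trace
#'
#' Excludes cells that die or stop cycling during the recording: a cell is
#' excluded if the mean signal of its final 24 h falls below
#' `min_final_fraction` of the mean of its first 24 h ("strong reduction"),
#' or if the peak picker finds no peak within the final `rhythm_window_h`
#' ("loss of rhythmicity"). Both thresholds are operational conventions and
#' are exposed as arguments.
#'
#' @param trace Trace tibble (`time_h`, `value`), at least 2 days long.
#' @param min_final_fraction Default 0.1.
#' @param rhythm_window_h Default 48.
#' @return A one-row tibble: `cell_id` (if present), `keep` (logical),
#'   `reason` (`"ok"`, `"strong reduction"` or `"loss of rhythmicity"`).
#' @export
viability_qc <- function(trace, min_final_fraction = 0.1, rhythm_window_h = 48) {
  span <- max(trace$time_h) - min(trace$time_h)
  if (span < 48) stop("trace must be at least 2 days long", call. = FALSE)
  first_day <- mean(trace$value[trace$time_h <= min(trace$time_h) + 24])
  last_day <- mean(trace$value[trace$time_h >= max(trace$time_h) - 24])
  id <- if ("cell_id" %in% names(trace)) trace$cell_id[1] else NA_character_
  if (last_day < min_final_fraction * first_day) {
    return(tibble::tibble(cell_id = id, keep = FALSE,
                          reason = "strong reduction"))
  }
  tail_tr <- trace[trace$time_h >= max(trace$time_h) - rhythm_window_h, ]
  pk <- tryCatch(pick_peaks(tail_tr), error = function(e) NULL)
  if (is.null(pk) || nrow(pk) == 0) {
    return(tibble::tibble(cell_id = id, keep = FALSE,
                          reason = "loss of rhythmicity"))
  }
  tibble::tibble(cell_id = id, keep = TRUE, reason = "ok")
}

check_stack <- function(stack) {
  if (!is.array(stack) || length(dim(stack)) != 3) {
    stop("stack must be a 3-D array (time x height x width)", call. = FALSE)
  }
  invisible(TRUE)
}
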