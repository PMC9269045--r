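# Cycle segmentation, 0-100% normalization, and harmonic (sum-of-sinusoid)
# least-squares smoothing of joint-angle trajectories.

#' Joint-angle trajectory
#'
#' @param angle numeric vector, joint angle in degrees, uniformly sampled.
#' @param sampling_rate sampling rate in Hz.
#' @param joint `"hip"` or `"knee"`.
#' @param side `"L"` or `"R"`.
#' @param events optional list with integer sample indices `hs` (heel strikes)
#'   and `to` (toe offs), each strictly increasing.
#' @return object of class `joint_trajectory`.
#' @export
joint_trajectory <- function(angle, sampling_rate, joint = "hip", side = "R",
                             events = NULL) {
  if (!all(is.finite(angle))) stop("angle series must be finite", call. = FALSE)
  stopifnot_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  if (!is.null(events)) {
    for (nm in c("hs", "to")) {
      ev <- events[[nm]]
      if (!is.null(ev) && any(diff(ev) <= 0))
        stop(sprintf("event indices '%s' must be strictly increasing", nm),
             call. = FALSE)
    }
  }
  structure(list(angle = as.numeric(angle), sampling_rate = sampling_rate,
                 joint = joint, side = side, events = events),
            class = "joint_trajectory")
}

#' Extract one joint's trajectory (with events) from a synthetic trial
#'
#' @param trial a [generate_trial()] object.
#' @param side `"L"` or `"R"`.
#' @param joint `"hip"` or `"knee"`.
#' @param keep_events attach the trial's ground-truth events (default TRUE).
#' @return a [joint_trajectory()].
#' @export
trial_trajectory <- function(trial, side, joint, keep_events = TRUE) {
  stopifnot(inherits(trial, "gait_trial"))
  s <- trial$sides[[side]]
  joint_trajectory(s[[joint]], trial$sampling_rate, joint = joint, side = side,
                   events = if (keep_events) list(hs = s$hs, to = s$to))
}

#' Segment a trajectory into gait cycles
#'
#' With events attached, cycles are consecutive heel-strike pairs. Without
#' events, heel strikes are detected as hip-angle local maxima (maximum hip
#' flexion closely precedes heel strike in level walking) separated by at
#' least half the dominant period, which is estimated from the first
#' off-origin peak of the autocorrelation function.
#'
#' @param traj a [joint_trajectory()].
#' @return data frame with columns `start`, `end` (sample indices of
#'   heel-strike to next heel-strike intervals), ordered, non-overlapping.
#' @export
segment_cycles <- function(traj) {
  stopifnot(inherits(traj, "joint_trajectory"))
  hs <- traj$events$hs
  if (is.null(hs)) hs <- detect_heel_strikes(traj$angle)
  if (length(hs) < 2L)
    stop("fewer than 2 heel strikes detectable; cannot segment", call. = FALSE)
  data.frame(start = hs[-length(hs)], end = hs[-1L])
}

detect_heel_strikes <- function(x) {
  n <- length(x)
  if (n < 8L || stats::sd(x) < 1e-9)
    stop("fewer than 2 heel strikes detectable; cannot segment", call. = FALSE)
  xc <- x - mean(x)
  lag_max <- min(n - 2L, max(16L, floor(n / 2)))
  ac <- stats::acf(xc, lag.max = lag_max, plot = FALSE,
                   demean = FALSE)$acf[, 1L, 1L]
  # first local maximum after the first zero crossing
  zc <- which(ac < 0)[1L]
  if (is.na(zc))
    stop("fewer than 2 heel strikes detectable; cannot segment", call. = FALSE)
  seg <- ac[(zc + 1L):length(ac)]
  if (length(seg) < 3L)
    stop("fewer than 2 heel strikes detectable; cannot segment", call. = FALSE)
  period <- zc + which.max(seg) - 1L
  min_sep <- max(4L, floor(period / 2))
  # local maxima (plateau-tolerant), then greedy pruning by height
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  ends <- c(if (x[1L] > x[2L]) 1L, if (x[n] > x[n - 1L]) n)
  cand <- sort(unique(c(cand, ends)))
  cand <- cand[order(-x[cand])]
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Normalized gait cycle
#'
#' One cycle resampled onto the inclusive 0--100% grid (101 points), with the
#' stance/swing boundary recorded as a percentage.
#'
#' @param angle numeric vector of exactly 101 angles (degrees).
#' @param stance_end_pct toe-off position in percent, strictly inside (0, 100).
#' @param joint,side labels carried along.
#' @return object of class `normalized_cycle`.
#' @export
normalized_cycle <- function(angle, stance_end_pct, joint = "hip", side = "R") {
  if (length(angle) != 101L)
    stop("a normalized cycle has exactly 101 points", call. = FALSE)
  if (!all(is.finite(angle))) stop("angle must be finite", call. = FALSE)
  if (stance_end_pct <= 0 || stance_end_pct >= 100)
    stop("'stance_end_pct' must lie strictly in (0, 100)", call. = FALSE)
  structure(list(angle = as.numeric(angle), stance_end_pct = stance_end_pct,
                 joint = joint, side = side),
            class = "normalized_cycle")
}

#' @export
print.normalized_cycle <- function(x, ...) {
  cat(sprintf("<normalized_cycle: %s %s, RoM %.2f deg, stance ends %.1f%%>\n",
              x$side, x$joint, diff(range(x$angle)), x$stance_end_pct))
  invisible(x)
}

#' Resample one cycle onto the 0--100% grid
#'
#' Linear-in-time interpolation of the samples in `interval` onto 101 evenly
#' spaced points; the stance/swing boundary is placed at
#' `100 * (toe_off - start) / (end - start)`.
#'
#' @param traj a [joint_trajectory()].
#' @param interval length-2 integer vector `(start, end)` sample indices.
#' @param toe_off toe-off sample index, strictly inside the interval.
#' @return a [normalized_cycle()].
#' @export
normalize_cycle <- function(traj, interval, toe_off) {
  stopifnot(inherits(traj, "joint_trajectory"))
  s <- interval[1L]; e <- interval[2L]
  if (s < 1L || e > length(traj$angle) || e <= s)
    stop("interval out of range", call. = FALSE)
  if (toe_off <= s || toe_off >= e)
    stop("'toe_off' must lie strictly inside the interval", call. = FALSE)
  xin <- seq(s, e)
  grid <- s + (e - s) * pct_grid() / 100
  ang <- stats::approx(xin, traj$angle[xin], xout = grid)$y
  normalized_cycle(ang, 100 * (toe_off - s) / (e - s),
                   joint = traj$joint, side = traj$side)
}

#' Harmonic (sum-of-sinusoid) least-squares fit of a cycle
#'
#' Ordinary least squares on the basis `{1, sin(2*pi*k*t/100),
#' cos(2*pi*k*t/100)}, k = 1..K` over the 101-point grid. The reconstruction
#' is the smoothed cycle; truncating at K removes riding waves and
#' measurement noise.
#'
#' @param cycle a [normalized_cycle()].
#' @param K number of harmonics, `1 <= K <= 49`.
#' @return list with `fit` (class `sinusoid_fit`: `mean_offset`, per-harmonic
#'   `amplitude` and `phase` in radians such that the curve is
#'   `mean_offset + sum a_k cos(2 pi k t/100 - c_k)`, and `residual_rms`) and
#'   `smoothed` (the reconstructed [normalized_cycle()]).
#' @export
fit_sinusoid_sum <- function(cycle, K = 6L) {
  stopifnot(inherits(cycle, "normalized_cycle"))
  K <- as.integer(K)
  if (K < 1L) stop("'K' must be >= 1", call. = FALSE)
  if (K > 49L)
    stop("'K' > 49 makes the design rank-deficient on 101 points", call. = FALSE)
  grid <- pct_grid()
  X <- harmonic_design(grid, K)
  qrX <- qr(X)
  beta <- qr.coef(qrX, cycle$angle)
  smooth <- drop(X %*% beta)
  res <- cycle$angle - smooth
  ac <- beta[1L + seq_len(K)]
  as_ <- beta[1L + K + seq_len(K)]
  fit <- structure(list(
    mean_offset = unname(beta[1L]),
    amplitude = unname(sqrt(ac^2 + as_^2)),
    phase = unname(atan2(as_, ac)),
    fundamental_period = 100,
    residual_rms = sqrt(mean(res^2)),
    K = K
  ), class = "sinusoid_fit")
  list(fit = fit,
       smoothed = normalized_cycle(smooth, cycle$stance_end_pct,
                                   joint = cycle$joint, side = cycle$side))
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  cat(sprintf("<sinusoid_fit: K = %d, offset %.2f deg, residual RMS %.4g deg>\n",
              x$K, x$mean_offset, x$residual_rms))
  invisible(x)
}

#' Cycle-normalize every cycle of a trajectory
#'
#' Segments the trajectory, attaches toe offs (from events when present,
#' otherwise at a given stance percentage), and normalizes each complete
#' cycle.
#'
#' @param traj a [joint_trajectory()].
#' @param default_stance_pct stance-end percent used when no toe-off events
#'   are available (default 60).
#' @return list of [normalized_cycle()] objects.
#' @export
normalize_all_cycles <- function(traj, default_stance_pct = 60) {
  iv <- segment_cycles(traj)
  to <- traj$events$to
  out <- list()
  for (i in seq_len(nrow(iv))) {
    s <- iv$start[i]; e <- iv$end[i]
    t_off <- if (!is.null(to)) {
      cand <- to[to > s & to < e]
      if (!length(cand)) next
      cand[1L]
    } else s + round(default_stance_pct / 100 * (e - s))
    out[[length(out) + 1L]] <- normalize_cycle(traj, c(s, e), t_off)
  }
  out
}

#' Pick the representative cycle of a trial
#'
#' The published analyses use one representative cycle per trial; here the
#' default rule is the cycle whose curve has minimal RMSE to the within-trial
#' mean curve.
#'
#' @param cycles list of [normalized_cycle()] objects on the same grid.
#' @return the selected [normalized_cycle()].
#' @export
select_representative_cycle <- function(cycles) {
  if (!length(cycles)) stop("no cycles supplied", call. = FALSE)
  if (length(cycles) == 1L) return(cycles[[1L]])
  mat <- vapply(cycles, function(c) c$angle, numeric(101L))
  m <- rowMeans(mat)
  rmse <- apply(mat, 2L, function(col) sqrt(mean((col - m)^2)))
  cycles[[which.min(rmse)]]
}
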