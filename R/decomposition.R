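# Decomposition index (DI) for the hip-knee pair: fraction of the gait cycle
# during which exactly one joint of the pair is paused (|angular velocity|
# below 5 deg/s) while the other moves; whole-cycle, stance and swing values.

#' Angular velocity of a normalized cycle
#'
#' Central finite differences on the 101-point grid, converted to deg/s via
#' the stride duration (grid spacing is 1% of a stride); one-sided
#' differences at the endpoints.
#'
#' @param cycle a [normalized_cycle()].
#' @param stride_duration stride duration in seconds (> 0).
#' @return numeric vector of angular velocities in deg/s (length 101), with
#'   attribute `stride_duration`.
#' @export
angular_velocity <- function(cycle, stride_duration) {
  stopifnot(inherits(cycle, "normalized_cycle"))
  stopifnot_scalar_number(stride_duration, "stride_duration", positive = TRUE)
  # d(angle)/d(pct) * 100 pct-per-stride / stride_duration
  omega <- central_diff(cycle$angle) * 100 / stride_duration
  attr(omega, "stride_duration") <- stride_duration
  omega
}

#' Pause mask from an angular-velocity series
#'
#' A joint is paused where its absolute angular velocity is strictly below
#' the threshold ("less than 5 deg/s"); at exactly the threshold it counts as
#' moving.
#'
#' @param omega numeric angular-velocity series, deg/s.
#' @param threshold pause threshold in deg/s (default 5, > 0).
#' @return logical vector, TRUE where paused.
#' @export
pause_mask <- function(omega, threshold = 5) {
  stopifnot_scalar_number(threshold, "threshold", positive = TRUE)
  abs(omega) < threshold
}

#' Decomposition index of a joint pair
#'
#' A grid point shows decomposition iff exactly one of the two joints is
#' paused (exclusive-or; both-paused is not decomposition). The whole-cycle
#' DI is the decomposed fraction of all points; stance and swing DIs use only
#' points within, and are normalized by the length of, the respective phase
#' window.
#'
#' @param mask_a,mask_b logical pause masks of equal length.
#' @param stance_end_pct stance/swing boundary in percent of the cycle.
#' @param pair,side,threshold labels stored in the result.
#' @return object of class `di_result` with fields `di_whole`, `di_stance`,
#'   `di_swing` (fractions in `[0, 1]`), `pair`, `side`, `threshold`.
#' @export
decomposition_index <- function(mask_a, mask_b, stance_end_pct,
                                pair = c("hip", "knee"), side = NA_character_,
                                threshold = 5) {
  if (length(mask_a) != length(mask_b))
    stop("pause masks have different lengths", call. = FALSE)
  n <- length(mask_a)
  if (n < 3L) stop("masks too short", call. = FALSE)
  dec <- xor(mask_a, mask_b)
  st <- window_index(n, stance_end_pct, "stance")
  sw <- window_index(n, stance_end_pct, "swing")
  if (!length(st) || !length(sw))
    stop("empty stance or swing window", call. = FALSE)
  structure(list(
    di_whole = mean(dec),
    di_stance = mean(dec[st]),
    di_swing = mean(dec[sw]),
    pair = pair, side = side, threshold = threshold
  ), class = "di_result")
}

#' @export
print.di_result <- function(x, ...) {
  cat(sprintf(
    "<di_result %s-%s side %s: whole %.3f, stance %.3f, swing %.3f (<%g deg/s)>\n",
    x$pair[1L], x$pair[2L], x$side, x$di_whole, x$di_stance, x$di_swing,
    x$threshold))
  invisible(x)
}

# Local linear-regression slope (Savitzky-Golay first derivative, order 1)
# over a centered window of `w` samples; per-sample units. A flat-plus-noise
# plateau keeps its near-zero slope (unlike a truncated harmonic fit, which
# cannot represent a plateau and rings through it), while true movement
# velocities pass unattenuated at gait frequencies.
slope_velocity <- function(x, w) {
  w <- max(5L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  n <- length(x)
  if (w >= n) w <- if (n %% 2L) n else n - 1L
  half <- (w - 1L) %/% 2L
  j <- seq(-half, half)
  kern <- rev(j / sum(j^2))        # filter() correlates with reversed kernel
  v <- stats::filter(x, kern, method = "convolution", sides = 2L)
  v <- as.numeric(v)
  # shrink the window near the edges
  for (i in which(is.na(v))) {
    h <- min(i - 1L, n - i, half)
    if (h < 1L) {
      v[i] <- if (i == 1L) x[2L] - x[1L] else x[n] - x[n - 1L]
    } else {
      jj <- seq(-h, h)
      v[i] <- sum(jj * x[i + jj]) / sum(jj^2)
    }
  }
  v
}

#' Hip-knee decomposition index of a trial side
#'
#' Works cycle-by-cycle on the time-domain samples between consecutive heel
#' strikes: angular velocities at the trial sampling rate, pause masks, XOR
#' rule, then averaging the per-cycle DIs. The stance/swing boundary comes
#' from the toe-off events.
#'
#' Velocity estimators: `"slope"` (default) is a local linear-regression
#' slope over `slope_window` seconds — it keeps pause plateaus at near-zero
#' velocity while suppressing measurement-noise chatter; `"raw"` is a plain
#' central difference (exact for noiseless data); `"harmonic"` differentiates
#' a K-harmonic fit of the cycle (kept for compatibility with
#' harmonic-smoothed preprocessing, but a truncated harmonic basis cannot
#' represent a hold plateau, so it underestimates DI on pause-rich gait).
#'
#' @param trial a [generate_trial()] or imported trial.
#' @param side `"L"` or `"R"`.
#' @param threshold pause threshold, deg/s (default 5).
#' @param method velocity estimator: `"slope"`, `"raw"` or `"harmonic"`.
#' @param slope_window window length in seconds for `method = "slope"`
#'   (default 0.2).
#' @param K harmonics used when `method = "harmonic"`.
#' @return a `di_result` (per-cycle DIs averaged), with the per-cycle values
#'   in attribute `per_cycle`.
#' @export
trial_di <- function(trial, side, threshold = 5,
                     method = c("slope", "raw", "harmonic"),
                     slope_window = 0.2, K = 10L) {
  stopifnot(inherits(trial, "gait_trial") || is.list(trial))
  method <- match.arg(method)
  s <- trial$sides[[side]]
  if (is.null(s)) stop("unknown side: ", side, call. = FALSE)
  fs <- trial$sampling_rate
  hs <- s$hs; to <- s$to
  if (length(hs) < 2L) stop("need at least one full cycle", call. = FALSE)
  rows <- matrix(NA_real_, nrow = length(hs) - 1L, ncol = 3L)
  for (k in seq_len(length(hs) - 1L)) {
    a <- hs[k]; b <- hs[k + 1L]
    t_off <- to[to > a & to < b]
    if (!length(t_off)) next
    idx <- seq(a, b)
    hip <- s$hip[idx]; knee <- s$knee[idx]
    if (method == "harmonic") {
      theta <- (idx - a) / (b - a) * 100
      X <- harmonic_design(theta, as.integer(K))
      qrX <- qr(X)
      hip <- drop(X %*% qr.coef(qrX, hip))
      knee <- drop(X %*% qr.coef(qrX, knee))
    }
    if (method == "slope") {
      w <- as.integer(round(slope_window * fs))
      v_hip <- slope_velocity(hip, w) * fs
      v_knee <- slope_velocity(knee, w) * fs
    } else {
      v_hip <- central_diff(hip) * fs
      v_knee <- central_diff(knee) * fs
    }
    se_pct <- 100 * (t_off[1L] - a) / (b - a)
    di <- decomposition_index(pause_mask(v_hip, threshold),
                              pause_mask(v_knee, threshold),
                              se_pct, side = side, threshold = threshold)
    rows[k, ] <- c(di$di_whole, di$di_stance, di$di_swing)
  }
  ok <- stats::complete.cases(rows)
  if (!any(ok)) stop("no complete cycles with toe-off events", call. = FALSE)
  res <- structure(list(
    di_whole = mean(rows[ok, 1L]),
    di_stance = mean(rows[ok, 2L]),
    di_swing = mean(rows[ok, 3L]),
    pair = c("hip", "knee"), side = side, threshold = threshold
  ), class = "di_result")
  attr(res, "per_cycle") <- rows[ok, , drop = FALSE]
  res
}

#' Tidy DI table for a cohort
#'
#' @param cohort named list of trials.
#' @param threshold pause threshold, deg/s.
#' @param method,slope_window passed to [trial_di()].
#' @return data frame: subject, side, role, di_whole, di_stance, di_swing,
#'   threshold_dps.
#' @export
cohort_di_summary <- function(cohort, threshold = 5, method = "slope",
                              slope_window = 0.2) {
  rows <- list()
  for (subj in names(cohort)) {
    trial <- cohort[[subj]]
    for (side in names(trial$sides)) {
      di <- trial_di(trial, side, threshold, method = method,
                     slope_window = slope_window)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subj, side = side,
        role = trial$profile$side_roles[[side]],
        di_whole = di$di_whole, di_stance = di$di_stance,
        di_swing = di$di_swing, threshold_dps = threshold,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
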