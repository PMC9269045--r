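# Synthetic gait generator: seeded multi-cycle trials (joint angles, thigh
# inertial channels, ground-truth events and pause windows) emulating the
# healthy / stroke / amputee group kinematics.

GRAVITY <- 9.80665

# --- harmonic base waveforms ------------------------------------------------

# Hip flexion from vertical: a positive-cosine harmonic stack. All-cosine
# positive coefficients put the global maximum exactly at 0% (heel strike),
# which the event-free segmenter relies on.
hip_base_coefs <- function(K) {
  rel <- c(1, 0.12, 0.05, 0.02)
  rel <- if (K <= length(rel)) rel[seq_len(K)] else c(rel, rep(0, K - length(rel)))
  list(a0 = 0, ac = rel, as = rep(0, K))
}

eval_harmonics <- function(coefs, theta_pct) {
  K <- length(coefs$ac)
  out <- rep(coefs$a0, length(theta_pct))
  for (k in seq_len(K)) {
    w <- 2 * pi * k * theta_pct / 100
    out <- out + coefs$ac[k] * cos(w) + coefs$as[k] * sin(w)
  }
  out
}

# circular distance on the 0-100 cycle
circ_dist_pct <- function(theta, center) {
  d <- abs(theta - center)
  pmin(d, 100 - d)
}

raised_cosine <- function(theta, center, halfwidth) {
  d <- circ_dist_pct(theta, center)
  ifelse(d <= halfwidth, 0.5 * (1 + cos(pi * d / halfwidth)), 0)
}

# Knee flexion: projection of a two-bump template (small stance-flexion bump,
# large swing-flexion peak placed mid-swing) onto the K-harmonic basis, so the
# generated curve is exactly a sum of sinusoids. Depends on the side's
# stance-end percentage so the swing peak tracks the swing window.
knee_base_coefs <- function(stance_end_pct, K) {
  theta <- seq(0, 100, by = 0.25)
  theta <- theta[-length(theta)]             # one full period, no duplicate
  se <- stance_end_pct
  template <- 0.30 * raised_cosine(theta, 0.30 * se, 0.55 * se) +
    raised_cosine(theta, se + 0.45 * (100 - se), 0.50 * (100 - se))
  X <- harmonic_design(theta, K)
  beta <- qr.coef(qr(X), template)
  list(a0 = beta[1L],
       ac = beta[1L + seq_len(K)],
       as = beta[1L + K + seq_len(K)])
}

harmonic_design <- function(theta_pct, K) {
  X <- matrix(1, nrow = length(theta_pct), ncol = 1L + 2L * K)
  for (k in seq_len(K)) {
    w <- 2 * pi * k * theta_pct / 100
    X[, 1L + k] <- cos(w)
    X[, 1L + K + k] <- sin(w)
  }
  X
}

# Scaled base curves for one side: closures over harmonic coefficients, with
# peak-to-peak amplitude equal to the profile RoM (to < 0.01 degrees; min/max
# located on a 0.02% grid). Hip oscillates around a flexion-biased zero
# (max = +0.6 RoM); knee minimum sits at 3 degrees of flexion.
base_cycle_curves <- function(profile, side) {
  K <- profile$harmonic_count
  se <- 100 * (1 - profile$swing_percentage[[side]])
  fine <- seq(0, 100, by = 0.02)
  out <- list()
  for (joint in c("hip", "knee")) {
    coefs <- if (joint == "hip") hip_base_coefs(K) else knee_base_coefs(se, K)
    vals <- eval_harmonics(coefs, fine)
    lo <- min(vals); hi <- max(vals)
    rom <- if (joint == "hip") profile$rom_hip[[side]] else profile$rom_knee[[side]]
    scale <- rom / (hi - lo)
    offset <- if (joint == "hip") 0.6 * rom - hi * scale else 3 - lo * scale
    out[[joint]] <- local({
      cf <- coefs; sc <- scale; of <- offset
      function(theta) eval_harmonics(cf, theta) * sc + of
    })
  }
  out$stance_end_pct <- se
  out
}

# --- pause time-warp --------------------------------------------------------

# Pauses are realized by warping cycle time: the warp speed r(p) is zero
# inside each pause window, one elsewhere, with cosine tapers of `taper_pct`
# just outside the window. The integral of r is renormalized separately over
# stance and swing, so event timing (and the swing percentage) is preserved
# and every value of the base curve is still visited (RoM conserved).
# Returns tau(p): sampled-cycle percent -> base-curve percent.
make_warp <- function(windows, stance_end_pct, taper_pct) {
  if (is.null(windows) || nrow(windows) == 0L) return(identity)
  se <- stance_end_pct
  # split windows straddling the stance/swing boundary
  rows <- list()
  for (i in seq_len(nrow(windows))) {
    s <- windows$start_pct[i]; e <- windows$end_pct[i]
    if (s < se && e > se) {
      rows[[length(rows) + 1L]] <- c(s, se)
      rows[[length(rows) + 1L]] <- c(se, e)
    } else rows[[length(rows) + 1L]] <- c(s, e)
  }
  win <- do.call(rbind, rows)

  grid <- seq(0, 100, by = 0.01)
  r <- rep(1, length(grid))
  for (i in seq_len(nrow(win))) {
    s <- win[i, 1L]; e <- win[i, 2L]
    inside <- grid >= s & grid <= e
    r[inside] <- 0
    pre <- grid >= s - taper_pct & grid < s
    r[pre] <- pmin(r[pre], 0.5 * (1 - cos(pi * (s - grid[pre]) / taper_pct)))
    post <- grid > e & grid <= e + taper_pct
    r[post] <- pmin(r[post], 0.5 * (1 - cos(pi * (grid[post] - e) / taper_pct)))
  }
  h <- grid[2L] - grid[1L]
  cum <- c(0, cumsum((r[-1L] + r[-length(r)]) / 2 * h))
  i_se <- which.min(abs(grid - se))
  stance_mass <- cum[i_se]
  swing_mass <- cum[length(cum)] - cum[i_se]
  if (stance_mass < 1e-6 * se || swing_mass < 1e-6 * (100 - se))
    stop("pause windows cover an entire stance or swing phase", call. = FALSE)
  tau_grid <- numeric(length(grid))
  tau_grid[seq_len(i_se)] <- se * cum[seq_len(i_se)] / stance_mass
  idx <- seq(i_se, length(grid))
  tau_grid[idx] <- se + (100 - se) * (cum[idx] - cum[i_se]) / swing_mass
  function(p) stats::approx(grid, tau_grid, xout = p, rule = 2)$y
}

# --- public generator -------------------------------------------------------

#' Generate one noiseless normalized gait cycle
#'
#' Evaluates the profile's harmonic base waveforms for one side on the
#' 101-point 0--100% grid. The hip curve is a stack of `harmonic_count`
#' stride-frequency harmonics with its maximum at heel strike; the knee curve
#' is the harmonic projection of a stance-flexion bump plus a swing-flexion
#' peak. Peak-to-peak amplitudes equal the profile RoMs. Pause windows and
#' noise are applied at the trial level, not here.
#'
#' @param profile a [make_profile()] object.
#' @param side `"L"` or `"R"`.
#' @param seed unused placeholder for interface stability; the cycle shape is
#'   fully determined by the profile and side.
#' @return list with elements `hip` and `knee`, each a [normalized_cycle()].
#' @export
generate_cycle <- function(profile, side = "R", seed = 0L) {
  stopifnot(inherits(profile, "gait_profile"), side %in% c("L", "R"))
  curves <- base_cycle_curves(profile, side)
  grid <- pct_grid()
  list(
    hip = normalized_cycle(curves$hip(grid), curves$stance_end_pct,
                           joint = "hip", side = side),
    knee = normalized_cycle(curves$knee(grid), curves$stance_end_pct,
                            joint = "knee", side = side)
  )
}

#' Generate a multi-cycle synthetic gait trial
#'
#' Concatenates `n_cycles` identical warped cycles per side at the profile
#' sampling rate, shifts the left limb by `phase_offset_between_limbs`,
#' realizes pause windows as time-warp holds (ground truth recorded), adds
#' Gaussian measurement noise, and derives thigh inertial channels (gyroscope
#' and a gravity-consistent 3-axis accelerometer at a 0.25 m sensor offset)
#' from the thigh segment angle, taken as hip flexion from vertical.
#'
#' @param profile a [make_profile()] object.
#' @param n_cycles number of gait cycles (>= 1).
#' @param seed integer seed; identical arguments give bit-identical trials.
#' @return an object of class `gait_trial`: sampling metadata, per-side angle
#'   and inertial series with heel-strike (`hs`) and toe-off (`to`) sample
#'   indices, the generating profile, and realized pause windows
#'   (`pause_truth`).
#' @export
generate_trial <- function(profile, n_cycles, seed = 1L) {
  stopifnot(inherits(profile, "gait_profile"))
  if (n_cycles < 1) stop("'n_cycles' must be >= 1", call. = FALSE)
  n_cycles <- as.integer(n_cycles)
  fs <- profile$sampling_rate
  spc <- max(8L, as.integer(round(profile$stride_duration * fs)))
  n <- n_cycles * spc + 1L
  off_samp <- as.integer(round(profile$phase_offset_between_limbs * spc))
  taper_pct <- 5 * 100 / spc                   # 5-sample taper in percent

  restore <- .Random.seed_guard(seed)
  on.exit(restore(), add = TRUE)

  sides <- list()
  pause_truth <- list()
  for (side in c("R", "L")) {
    curves <- base_cycle_curves(profile, side)
    ps <- profile$pause_spec
    ps <- ps[ps$side == side, , drop = FALSE]
    one <- list()
    for (joint in c("hip", "knee")) {
      w <- ps[ps$joint == joint, , drop = FALSE]
      tau <- make_warp(w, curves$stance_end_pct, taper_pct)
      p_cycle <- (seq_len(spc) - 1L) / spc * 100
      cyc <- curves[[joint]](tau(p_cycle))
      shift <- if (side == "L") off_samp else 0L
      idx <- ((seq_len(n) - 1L - shift) %% spc) + 1L
      one[[joint]] <- cyc[idx]
      if (nrow(w)) {
        for (i in seq_len(nrow(w))) {
          starts <- 1L + shift + (seq_len(n_cycles + 1L) - 2L) * spc +
            as.integer(round(w$start_pct[i] / 100 * spc))
          ends <- starts +
            as.integer(round((w$end_pct[i] - w$start_pct[i]) / 100 * spc))
          keep <- starts >= 1L & ends <= n
          if (any(keep))
            pause_truth[[length(pause_truth) + 1L]] <- data.frame(
              side = side, joint = joint,
              start_idx = starts[keep], end_idx = ends[keep],
              start_pct = w$start_pct[i], end_pct = w$end_pct[i],
              stringsAsFactors = FALSE)
        }
      }
    }
    # events
    shift <- if (side == "L") off_samp else 0L
    hs <- 1L + shift + (seq_len(n_cycles + 1L) - 1L) * spc
    hs <- hs[hs >= 1L & hs <= n]
    to_off <- as.integer(round(curves$stance_end_pct / 100 * spc))
    to <- hs + to_off
    to <- to[to <= n]
    one$hs <- hs
    one$to <- to
    one$stance_end_pct <- curves$stance_end_pct
    one$role <- profile$side_roles[[side]]
    sides[[side]] <- one
  }

  # thigh inertial channels from the noiseless thigh (hip) angle
  for (side in c("R", "L")) {
    th_deg <- sides[[side]]$hip
    gyro <- central_diff(th_deg) * fs                 # deg/s
    alpha <- central_diff(gyro) * fs                  # deg/s^2
    th <- th_deg * pi / 180
    om <- gyro * pi / 180
    al <- alpha * pi / 180
    r_off <- 0.25
    acc <- cbind(
      x = GRAVITY * cos(th) + r_off * om^2,           # along thigh, axial
      y = -GRAVITY * sin(th) + r_off * al,            # anterior tangential
      z = rep(0, length(th))
    )
    sides[[side]]$thigh_gyro <- gyro
    sides[[side]]$thigh_acc <- acc
  }

  # measurement noise (after ground-truth channels are derived)
  if (profile$noise_sd > 0) {
    for (side in c("R", "L")) {
      sides[[side]]$hip <- sides[[side]]$hip + stats::rnorm(n, 0, profile$noise_sd)
      sides[[side]]$knee <- sides[[side]]$knee + stats::rnorm(n, 0, profile$noise_sd)
      sides[[side]]$thigh_gyro <- sides[[side]]$thigh_gyro +
        stats::rnorm(n, 0, profile$noise_sd)
      sides[[side]]$thigh_acc <- sides[[side]]$thigh_acc +
        matrix(stats::rnorm(3L * n, 0, 0.05 * profile$noise_sd), ncol = 3L)
    }
  }

  structure(list(
    sampling_rate = fs,
    samples_per_cycle = spc,
    n_cycles = n_cycles,
    n_samples = n,
    time = (seq_len(n) - 1L) / fs,
    sides = sides,
    profile = profile,
    pause_truth = if (length(pause_truth)) do.call(rbind, pause_truth)
                  else NULL,
    seed = as.integer(seed)
  ), class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial: %s, %d cycles, %d samples @ %g Hz>\n",
              x$profile$group_label, x$n_cycles, x$n_samples, x$sampling_rate))
  invisible(x)
}

# second-order central differences, one-sided at the ends (per-sample units)
central_diff <- function(x) {
  n <- length(x)
  d <- numeric(n)
  if (n >= 3L) d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / 2
  d[1L] <- x[2L] - x[1L]
  d[n] <- x[n] - x[n - 1L]
  d
}

#' Build a cohort of synthetic subjects
#'
#' Applies lognormal inter-subject jitter to a group profile and generates one
#' trial per subject under deterministic per-subject seeds.
#'
#' @param group group label passed to [make_profile()].
#' @param n_subjects number of subjects.
#' @param n_cycles gait cycles per trial.
#' @param seed master seed.
#' @param overrides profile overrides applied before jittering.
#' @param jitter_sd log-scale inter-subject variability (default 0.05).
#' @return named list of `gait_trial` objects (`S1`, `S2`, ...).
#' @export
make_cohort <- function(group, n_subjects, n_cycles = 8L, seed = 1L,
                        overrides = list(), jitter_sd = 0.05) {
  base <- make_profile(group, overrides)
  out <- vector("list", n_subjects)
  names(out) <- paste0("S", seq_len(n_subjects))
  for (i in seq_len(n_subjects)) {
    pi_seed <- child_seed(seed, 2L * i)
    prof <- jitter_profile(base, pi_seed, sd = jitter_sd)
    out[[i]] <- generate_trial(prof, n_cycles, seed = child_seed(seed, 2L * i + 1L))
  }
  out
}
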