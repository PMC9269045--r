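#' Gait profiles for the synthetic generator
#'
#' A `gait_profile` bundles every parameter the synthetic gait generator
#' needs for one subject: walking speed, stride duration, per-side swing
#' percentage and hip/knee ranges of motion (RoM), the harmonic content of
#' the joint waveforms, pause windows (intervals of a cycle over which a
#' joint is held still), the phase offset between the two limbs, additive
#' measurement noise, and the sampling rate.
#'
#' Group defaults reproduce the published group means for healthy subjects,
#' stroke survivors and unilateral transfemoral amputees (speed, RoM_hip,
#' RoM_knee and swing-phase percentage per side). Quantities those summaries
#' do not report (stride duration, amputee speed, pause-window geometry) are
#' package defaults, documented in the methods vignette.
#'
#' @param group_label one of `"healthy"`, `"stroke"`, `"amputee"`.
#' @param overrides named list of profile fields to override. Per-side fields
#'   (`swing_percentage`, `rom_hip`, `rom_knee`) accept either a single value
#'   (applied to both sides) or a named vector with elements `L` and `R`.
#' @return an object of class `gait_profile`.
#' @examples
#' p <- make_profile("healthy")
#' p$speed            # 0.92 m/s
#' p$rom_hip[["R"]]   # 62.33 degrees
#' @export
make_profile <- function(group_label = c("healthy", "stroke", "amputee"),
                         overrides = list()) {
  group_label <- match.arg(group_label)
  defaults <- group_profile_defaults(group_label)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("'overrides' must be a fully named list", call. = FALSE)
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown))
      stop("unknown profile field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    for (nm in names(overrides)) {
      val <- overrides[[nm]]
      if (nm %in% c("swing_percentage", "rom_hip", "rom_knee") &&
          length(val) == 1L && is.null(names(val))) {
        val <- c(L = unname(val), R = unname(val))
      }
      defaults[[nm]] <- val
    }
  }
  validate_profile(structure(defaults, class = "gait_profile"))
}

# Published group means: speed (m/s), RoM_knee / RoM_hip (degrees) and swing
# percentage per side. Affected side is "L" by convention for patient groups.
# Stride durations are back-computed from speed and a group stride length
# (healthy 1.1 m; stroke 0.60 m; amputee 1.25 m) because cadence is not
# reported. Amputee speed is not reported either; 0.80 m/s is a typical
# self-selected transfemoral speed. Pause windows (given in percent of the
# cycle, per side and joint) are sized so that the decomposition index of the
# generated gait reproduces the group ordering: healthy < amputee < stroke,
# affected > sound.
group_profile_defaults <- function(group_label) {
  base <- list(
    group_label = group_label,
    side_roles = c(L = "sound", R = "sound"),
    speed = 0.92,
    stride_duration = 1.1 / 0.92,
    swing_percentage = c(L = 0.53, R = 0.53),
    rom_hip = c(L = 62.33, R = 62.33),
    rom_knee = c(L = 44.38, R = 44.38),
    harmonic_count = 4L,
    pause_spec = empty_pause_spec(),
    phase_offset_between_limbs = 0.5,
    noise_sd = 0.5,
    sampling_rate = 100
  )
  if (group_label == "stroke") {
    base$side_roles <- c(L = "affected", R = "sound")
    base$speed <- 0.18
    base$stride_duration <- 0.60 / 0.18
    base$swing_percentage <- c(L = 0.57, R = 0.70)
    base$rom_hip <- c(L = 41.42, R = 48.72)
    base$rom_knee <- c(L = 35.92, R = 39.37)
    # stance ends at 43% (L) / 30% (R); windows avoid the stance/swing
    # boundary and leave moving time in every phase
    base$pause_spec <- rbind(
      pause_window("L", "knee", 8, 28),   # affected stance
      pause_window("L", "knee", 60, 82),  # affected swing
      pause_window("R", "knee", 6, 18),   # sound stance
      pause_window("R", "knee", 45, 64)   # sound swing
    )
  } else if (group_label == "amputee") {
    base$side_roles <- c(L = "affected", R = "sound")
    base$speed <- 0.80
    base$stride_duration <- 1.25 / 0.80
    base$swing_percentage <- c(L = 0.54, R = 0.57)
    base$rom_hip <- c(L = 55.65, R = 59.52)
    base$rom_knee <- c(L = 42.80, R = 43.09)
    base$pause_spec <- rbind(
      pause_window("L", "knee", 6, 34),   # prosthetic-side stance
      pause_window("L", "knee", 58, 72),  # prosthetic-side swing
      pause_window("R", "knee", 10, 16)   # sound side: brief stance pause
    )
  }
  base
}

#' Pause-window row constructor
#'
#' @param side `"L"` or `"R"`.
#' @param joint `"hip"` or `"knee"`.
#' @param start_pct,end_pct window bounds in percent of the gait cycle,
#'   `0 <= start_pct < end_pct <= 100`.
#' @return one-row data frame suitable for a profile's `pause_spec`.
#' @export
pause_window <- function(side, joint, start_pct, end_pct) {
  data.frame(side = side, joint = joint,
             start_pct = start_pct, end_pct = end_pct,
             stringsAsFactors = FALSE)
}

empty_pause_spec <- function() {
  data.frame(side = character(), joint = character(),
             start_pct = numeric(), end_pct = numeric(),
             stringsAsFactors = FALSE)
}

validate_profile <- function(p) {
  for (nm in c("speed", "stride_duration", "sampling_rate"))
    stopifnot_scalar_number(p[[nm]], nm, positive = TRUE)
  stopifnot_scalar_number(p$noise_sd, "noise_sd")
  if (p$noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (!is.numeric(p$harmonic_count) || p$harmonic_count < 1)
    stop("'harmonic_count' must be >= 1", call. = FALSE)
  p$harmonic_count <- as.integer(p$harmonic_count)
  for (nm in c("swing_percentage", "rom_hip", "rom_knee")) {
    v <- p[[nm]]
    if (!all(c("L", "R") %in% names(v)))
      stop(sprintf("'%s' must have named elements L and R", nm), call. = FALSE)
  }
  if (any(p$swing_percentage <= 0 | p$swing_percentage >= 1))
    stop("'swing_percentage' must lie strictly in (0, 1)", call. = FALSE)
  if (any(p$rom_hip <= 0) || any(p$rom_knee <= 0))
    stop("ranges of motion must be > 0", call. = FALSE)
  if (p$phase_offset_between_limbs < 0 || p$phase_offset_between_limbs >= 1)
    stop("'phase_offset_between_limbs' must be in [0, 1)", call. = FALSE)
  ps <- p$pause_spec
  if (nrow(ps)) {
    if (any(ps$start_pct < 0 | ps$end_pct > 100 | ps$start_pct >= ps$end_pct))
      stop("pause windows must satisfy 0 <= start < end <= 100", call. = FALSE)
    key <- split(ps, paste(ps$side, ps$joint))
    for (g in key) {
      g <- g[order(g$start_pct), ]
      if (nrow(g) > 1L && any(g$start_pct[-1L] < g$end_pct[-nrow(g)]))
        stop("pause windows overlap for ", g$side[1L], " ", g$joint[1L],
             call. = FALSE)
    }
  }
  p
}

#' @export
print.gait_profile <- function(x, ...) {
  cat(sprintf("<gait_profile: %s>\n", x$group_label))
  cat(sprintf("  speed %.2f m/s, stride %.2f s, fs %g Hz, noise sd %.2f deg\n",
              x$speed, x$stride_duration, x$sampling_rate, x$noise_sd))
  for (s in c("L", "R")) {
    cat(sprintf("  %s (%s): RoM hip %.2f deg, knee %.2f deg, swing %.0f%%\n",
                s, x$side_roles[[s]], x$rom_hip[[s]], x$rom_knee[[s]],
                100 * x$swing_percentage[[s]]))
  }
  if (nrow(x$pause_spec))
    cat(sprintf("  %d pause window(s)\n", nrow(x$pause_spec)))
  invisible(x)
}

#' Apply inter-subject variability to a profile
#'
#' Multiplies speed, stride duration, swing percentages and RoMs by
#' independent lognormal(0, sd) factors under a subject-specific seed, so a
#' cohort of distinct but group-consistent subjects can be simulated.
#'
#' @param profile a `gait_profile`.
#' @param seed integer subject seed.
#' @param sd log-scale standard deviation of the jitter (default 0.05).
#' @return a new `gait_profile`.
#' @export
jitter_profile <- function(profile, seed, sd = 0.05) {
  stopifnot(inherits(profile, "gait_profile"))
  p <- profile
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  jit <- function(x) x * exp(stats::rnorm(length(x), 0, sd))
  p$speed <- jit(p$speed)
  p$stride_duration <- jit(p$stride_duration)
  sp <- jit(p$swing_percentage)
  sp <- pmin(pmax(sp, 0.05), 0.95)
  p$swing_percentage <- sp
  p$rom_hip <- jit(p$rom_hip)
  p$rom_knee <- jit(p$rom_knee)
  validate_profile(p)
}

# Seed-scoping helper: sets the RNG, returns a restorer closure.
.Random.seed_guard <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed) %% 2147483647L)
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}
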