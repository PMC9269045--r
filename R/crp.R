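# Continuous relative phase via the Hilbert analytic signal, and the
# CRP-comparison statistics (RMSE, PCC) over whole cycle, stance and swing.

#' Discrete Hilbert transform
#'
#' FFT-based periodic analytic-signal construction: the analytic signal has
#' the negative-frequency half of the spectrum zeroed and the positive half
#' doubled; its imaginary part is the Hilbert transform. With this sign
#' convention `hilbert_transform(cos) = sin`.
#'
#' @param x real numeric vector.
#' @return numeric vector, the Hilbert transform of `x`.
#' @export
hilbert_transform <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  analytic <- stats::fft(X * h, inverse = TRUE) / n
  Im(analytic)
}

#' Instantaneous phase of a normalized cycle
#'
#' The cycle is mean-centered; its discrete Hilbert transform `H` is computed
#' on the 101-point grid, and the phase is the four-quadrant arctangent
#' `atan2(H, x)` in degrees. (The two-quadrant arctan of H/x cannot represent
#' a full phase cycle; the four-quadrant form is the standard reading of the
#' Hilbert-phase method.) Phase is invariant to amplitude scaling and to
#' constant offsets.
#'
#' @param cycle a [normalized_cycle()].
#' @return object of class `phase_series`: `phi` (degrees in (-180, 180]),
#'   plus the source cycle's labels and stance boundary.
#' @export
analytic_phase <- function(cycle) {
  stopifnot(inherits(cycle, "normalized_cycle"))
  x <- cycle$angle - mean(cycle$angle)
  if (stats::sd(x) < 1e-12)
    stop("degenerate signal: zero variance, phase undefined", call. = FALSE)
  h <- hilbert_transform(x)
  phi <- wrap_angle(atan2(h, x) * 180 / pi)
  structure(list(phi = phi, joint = cycle$joint, side = cycle$side,
                 stance_end_pct = cycle$stance_end_pct),
            class = "phase_series")
}

#' Continuous relative phase between two phase series
#'
#' Pointwise phase difference `phi1 - phi2`, wrapped to (-180, 180].
#'
#' @param phi1,phi2 [analytic_phase()] objects on the same grid; by
#'   convention signal 1 is the hip (intralimb) or the sound/right limb
#'   (interlimb).
#' @return object of class `crp_series`: `crp` (degrees), `pair_label`,
#'   `stance_end_pct` (taken from `phi1`).
#' @export
crp <- function(phi1, phi2) {
  stopifnot(inherits(phi1, "phase_series"), inherits(phi2, "phase_series"))
  if (length(phi1$phi) != length(phi2$phi))
    stop("phase series are on different grids", call. = FALSE)
  structure(list(
    crp = angle_diff(phi1$phi, phi2$phi),
    pair_label = c(paste(phi1$side, phi1$joint, sep = "_"),
                   paste(phi2$side, phi2$joint, sep = "_")),
    stance_end_pct = phi1$stance_end_pct
  ), class = "crp_series")
}

#' @export
print.crp_series <- function(x, ...) {
  cat(sprintf("<crp_series: %s vs %s, mean %.1f deg>\n",
              x$pair_label[1L], x$pair_label[2L], mean(x$crp)))
  invisible(x)
}

window_index <- function(n, stance_end_pct, window) {
  pct <- seq(0, 100, length.out = n)
  switch(window,
         whole = seq_len(n),
         stance = which(pct <= stance_end_pct),
         swing = which(pct > stance_end_pct),
         stop("unknown window: ", window, call. = FALSE))
}

#' Compare two CRP curves (RMSE and PCC)
#'
#' Root-mean-square error uses the wrapped (smallest-angle) pointwise
#' difference; the Pearson correlation coefficient is computed on the raw
#' values. The window (`whole`, `stance` or `swing`) is resolved with the
#' first curve's stance boundary.
#'
#' @param c1,c2 [crp()] objects on the same grid.
#' @param window one of `"whole"`, `"stance"`, `"swing"`.
#' @return list with `rmse` (degrees), `pcc` (may be `NA` with a warning when
#'   either curve has zero variance in the window), `window`, `n_points`.
#' @export
crp_compare <- function(c1, c2, window = c("whole", "stance", "swing")) {
  stopifnot(inherits(c1, "crp_series"), inherits(c2, "crp_series"))
  window <- match.arg(window)
  if (length(c1$crp) != length(c2$crp))
    stop("CRP series are on different grids", call. = FALSE)
  idx <- window_index(length(c1$crp), c1$stance_end_pct, window)
  if (length(idx) < 3L)
    stop("window contains fewer than 3 grid points", call. = FALSE)
  a <- c1$crp[idx]; b <- c2$crp[idx]
  rmse <- sqrt(mean(angle_diff(a, b)^2))
  pcc <- if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) {
    warning("zero-variance CRP within window; PCC undefined", call. = FALSE)
    NA_real_
  } else stats::cor(a, b)
  list(rmse = rmse, pcc = pcc, window = window, n_points = length(idx))
}

#' Intralimb / interlimb CRP profile of one subject
#'
#' Intralimb pairing: CRP(hip, knee) within each side (hip is signal 1).
#' Interlimb pairing: CRP between corresponding joints of the two sides
#' (sound/right limb is signal 1), one series per joint, plus their pointwise
#' mean as the summary interlimb series (`inter_mean`).
#'
#' @param cycles nested list `cycles[[side]][[joint]]` of
#'   [normalized_cycle()] objects, sides `"L"`/`"R"`, joints `"hip"`/`"knee"`.
#' @param pairing `"intralimb"` or `"interlimb"`.
#' @param signal1_side which side is signal 1 for interlimb pairing; default
#'   the sound side if roles are attached, else `"R"`.
#' @param side_roles optional named vector mapping side to
#'   `"sound"`/`"affected"`.
#' @return named list of `crp_series`.
#' @export
subject_crp_profile <- function(cycles, pairing = c("intralimb", "interlimb"),
                                signal1_side = NULL, side_roles = NULL) {
  pairing <- match.arg(pairing)
  if (pairing == "intralimb") {
    out <- list()
    for (side in names(cycles)) {
      cs <- cycles[[side]]
      if (is.null(cs$hip) || is.null(cs$knee))
        stop("intralimb pairing needs hip and knee for side ", side,
             call. = FALSE)
      out[[side]] <- crp(analytic_phase(cs$hip), analytic_phase(cs$knee))
    }
    return(out)
  }
  if (!all(c("L", "R") %in% names(cycles)))
    stop("interlimb pairing needs both sides", call. = FALSE)
  if (is.null(signal1_side)) {
    signal1_side <- if (!is.null(side_roles)) {
      snd <- names(side_roles)[side_roles == "sound"]
      if (length(snd)) snd[1L] else "R"
    } else "R"
  }
  other <- setdiff(c("L", "R"), signal1_side)
  out <- list()
  for (joint in intersect(names(cycles[[signal1_side]]), names(cycles[[other]]))) {
    out[[joint]] <- crp(analytic_phase(cycles[[signal1_side]][[joint]]),
                        analytic_phase(cycles[[other]][[joint]]))
  }
  if (!length(out)) stop("no common joints between sides", call. = FALSE)
  out$inter_mean <- structure(list(
    crp = circular_mean_rows(vapply(out, `[[`,
                                    numeric(length(out[[1L]]$crp)), "crp")),
    pair_label = c("inter", "mean"),
    stance_end_pct = out[[1L]]$stance_end_pct
  ), class = "crp_series")
  out
}

# pointwise circular mean (degrees) of the columns of a matrix; robust to
# wraparound at +/-180 (where a plain arithmetic mean of wrapped values fails)
circular_mean_rows <- function(mat) {
  rad <- mat * pi / 180
  wrap_angle(atan2(rowMeans(sin(rad)), rowMeans(cos(rad))) * 180 / pi)
}

#' Pointwise mean CRP curve across subjects
#'
#' Circular (vector-averaged) pointwise mean, used as the healthy reference
#' curve against which patient CRP deviations are summarized. The circular
#' mean is essential for interlimb curves, which sit near the +/-180 degree
#' wrap point.
#'
#' @param crp_list list of `crp_series` on the same grid.
#' @return a `crp_series` whose stance boundary is the mean of the inputs'.
#' @export
mean_crp <- function(crp_list) {
  if (!length(crp_list)) stop("empty CRP list", call. = FALSE)
  mat <- vapply(crp_list, `[[`, numeric(length(crp_list[[1L]]$crp)), "crp")
  structure(list(
    crp = circular_mean_rows(mat),
    pair_label = c("reference", "mean"),
    stance_end_pct = mean(vapply(crp_list, `[[`, numeric(1L), "stance_end_pct"))
  ), class = "crp_series")
}

#' Smoothed, cycle-normalized joint curves of one trial
#'
#' Convenience chain used by the pipeline: segment, normalize, pick the
#' representative cycle, harmonic-smooth; returns `cycles[[side]][[joint]]`
#' ready for [subject_crp_profile()].
#'
#' With `align = "own"` each side is segmented on its own heel strikes, as
#' intralimb (within-limb) analyses require. With `align = "reference"` both
#' sides are normalized over the *reference side's* gait cycles, putting the
#' limbs on a common time base so the interlimb phase offset (nominally half
#' a cycle) is retained in the CRP.
#'
#' @param trial a [generate_trial()] or imported trial.
#' @param K harmonics for smoothing (default 6).
#' @param use_events use attached ground-truth events (default TRUE).
#' @param align `"own"` or `"reference"` (see Details).
#' @param reference_side reference side for `align = "reference"`; defaults
#'   to the sound side when roles are known, else `"R"`.
#' @return nested list of smoothed [normalized_cycle()] objects.
#' @export
trial_cycles <- function(trial, K = 6L, use_events = TRUE,
                         align = c("own", "reference"),
                         reference_side = NULL) {
  align <- match.arg(align)
  out <- list()
  if (align == "own") {
    for (side in names(trial$sides)) {
      for (joint in c("hip", "knee")) {
        traj <- trial_trajectory(trial, side, joint, keep_events = use_events)
        cyc <- select_representative_cycle(normalize_all_cycles(traj))
        out[[side]][[joint]] <- fit_sinusoid_sum(cyc, K)$smoothed
      }
    }
    return(out)
  }
  if (is.null(reference_side)) {
    roles <- trial$profile$side_roles
    reference_side <- if (!is.null(roles) && any(roles == "sound"))
      names(roles)[roles == "sound"][1L] else "R"
  }
  ref_traj <- trial_trajectory(trial, reference_side, "hip",
                               keep_events = use_events)
  iv <- segment_cycles(ref_traj)
  to <- trial$sides[[reference_side]]$to
  for (side in names(trial$sides)) {
    for (joint in c("hip", "knee")) {
      traj <- trial_trajectory(trial, side, joint, keep_events = FALSE)
      cycles <- list()
      for (i in seq_len(nrow(iv))) {
        s <- iv$start[i]; e <- iv$end[i]
        t_off <- if (!is.null(to) && use_events) {
          cand <- to[to > s & to < e]
          if (!length(cand)) next
          cand[1L]
        } else s + round(0.6 * (e - s))
        cycles[[length(cycles) + 1L]] <- normalize_cycle(traj, c(s, e), t_off)
      }
      cyc <- select_representative_cycle(cycles)
      out[[side]][[joint]] <- fit_sinusoid_sum(cyc, K)$smoothed
    }
  }
  out
}

#' Tidy CRP summary of a cohort against a reference
#'
#' For every subject, computes intralimb (per side) and interlimb CRP series
#' and their deviation (RMSE, and PCC) from the matching reference curves,
#' over whole cycle, stance and swing.
#'
#' @param cohort named list of trials ([make_cohort()]).
#' @param reference list of reference `crp_series` as produced by
#'   [reference_crp()]; when NULL, deviations are computed between the two
#'   sides' intralimb series instead of against a healthy reference.
#' @param K smoothing harmonics.
#' @return data frame: subject, pairing, pair_label, window, rmse_deg, pcc.
#' @export
cohort_crp_summary <- function(cohort, reference = NULL, K = 6L) {
  rows <- list()
  for (subj in names(cohort)) {
    trial <- cohort[[subj]]
    roles <- trial$profile$side_roles
    intra <- subject_crp_profile(trial_cycles(trial, K = K, align = "own"),
                                 "intralimb")
    inter <- subject_crp_profile(
      trial_cycles(trial, K = K, align = "reference"),
      "interlimb", side_roles = roles)
    series <- c(
      stats::setNames(intra, paste0("intra_", names(intra))),
      list(inter_mean = inter$inter_mean)
    )
    for (nm in names(series)) {
      ref <- if (!is.null(reference)) reference[[nm]] else NULL
      cmp_to <- if (!is.null(ref)) ref else next
      for (win in c("whole", "stance", "swing")) {
        cc <- crp_compare(series[[nm]], cmp_to, win)
        role <- if (grepl("^intra_", nm)) roles[[sub("^intra_", "", nm)]] else "both"
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subj, pairing = nm, role = role, window = win,
          rmse_deg = cc$rmse, pcc = cc$pcc, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Reference CRP curves from a (healthy) cohort
#'
#' Computes each subject's intralimb and summary interlimb CRP series and
#' averages them pointwise, yielding the reference set used for patient
#' CRP-deviation summaries.
#'
#' @param cohort named list of trials.
#' @param K smoothing harmonics.
#' @return named list of `crp_series`: `intra_L`, `intra_R`, `inter_mean`.
#' @export
reference_crp <- function(cohort, K = 6L) {
  acc <- list(intra_L = list(), intra_R = list(), inter_mean = list())
  for (trial in cohort) {
    intra <- subject_crp_profile(trial_cycles(trial, K = K, align = "own"),
                                 "intralimb")
    inter <- subject_crp_profile(
      trial_cycles(trial, K = K, align = "reference"),
      "interlimb", side_roles = trial$profile$side_roles)
    acc$intra_L[[length(acc$intra_L) + 1L]] <- intra$L
    acc$intra_R[[length(acc$intra_R) + 1L]] <- intra$R
    acc$inter_mean[[length(acc$inter_mean) + 1L]] <- inter$inter_mean
  }
  lapply(acc, mean_crp)
}
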