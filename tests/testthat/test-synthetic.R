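test_that("generated cycles hit the profile RoM and place peaks correctly", {
  for (group in c("healthy", "stroke", "amputee")) {
    p <- quiet_profile(group)
    for (side in c("L", "R")) {
      cyc <- generate_cycle(p, side)
      expect_lt(abs(diff(range(cyc$hip$angle)) - p$rom_hip[[side]]), 0.1)
      expect_lt(abs(diff(range(cyc$knee$angle)) - p$rom_knee[[side]]), 0.1)
      # hip maximum at heel strike (0%), knee swing peak inside swing
      expect_equal(which.max(cyc$hip$angle), 1L)
      peak_pct <- grid101[which.max(cyc$knee$angle)]
      expect_gt(peak_pct, cyc$knee$stance_end_pct)
      expect_lt(peak_pct, 100)
    }
  }
})

test_that("cycle generation is deterministic and exactly harmonic", {
  p <- quiet_profile()
  expect_identical(generate_cycle(p, "R"), generate_cycle(p, "R"))
  # a harmonic_count-K cycle refits exactly with K harmonics
  for (K in c(1L, 4L)) {
    pk <- quiet_profile(harmonic_count = K)
    for (joint in c("hip", "knee")) {
      fit <- fit_sinusoid_sum(generate_cycle(pk, "L")[[joint]], K)
      expect_lt(fit$fit$residual_rms, 1e-6)
    }
  }
  # harmonic_count = 1 hip curve is a pure fundamental
  f1 <- fit_sinusoid_sum(generate_cycle(quiet_profile(harmonic_count = 1), "R")$hip, 3)
  expect_lt(f1$fit$residual_rms, 1e-9)
  expect_lt(max(f1$fit$amplitude[2:3]), 1e-9)
})

test_that("trials are deterministic, RoM-conserving and event-consistent", {
  p <- quiet_profile("stroke")
  t1 <- generate_trial(p, 4, seed = 9)
  t2 <- generate_trial(p, 4, seed = 9)
  expect_identical(t1, t2)
  spc <- t1$samples_per_cycle
  for (side in c("L", "R")) {
    s <- t1$sides[[side]]
    expect_true(all(diff(s$hs) == spc))
    # alternating events: every toe-off strictly between consecutive strikes
    for (k in seq_len(length(s$hs) - 1L)) {
      inside <- s$to[s$to > s$hs[k] & s$to < s$hs[k + 1L]]
      expect_length(inside, 1L)
    }
    # per-cycle RoM conservation at zero noise (pauses present on stroke L/R)
    for (k in seq_len(length(s$hs) - 1L)) {
      idx <- s$hs[k]:(s$hs[k + 1L] - 1L)
      expect_lt(abs(diff(range(s$hip[idx])) - p$rom_hip[[side]]), 0.1)
      expect_lt(abs(diff(range(s$knee[idx])) - p$rom_knee[[side]]), 0.1)
    }
    # swing fraction matches the profile within one sample
    swing <- (s$hs[2L] - s$to[1L]) / (s$hs[2L] - s$hs[1L])
    expect_lt(abs(swing - p$swing_percentage[[side]]), 1 / spc + 1e-12)
  }
  # contralateral limb is offset by half a stride
  expect_equal(t1$sides$L$hs[1L] - t1$sides$R$hs[1L], round(spc / 2))
  expect_error(generate_trial(p, 0), "n_cycles")
})

test_that("with no pauses the hip-knee pair pauses only near angle extrema", {
  p <- quiet_profile()
  tr <- generate_trial(p, 3, seed = 1)
  s <- tr$sides$R
  fs <- tr$sampling_rate
  v_hip <- abs(diff(s$hip)) * fs
  moving <- which(v_hip >= 5)
  # velocity zero crossings sit within 2 samples of extrema of the angle
  paused <- which(v_hip < 5)
  ext <- sort(c(which(diff(sign(diff(s$hip))) != 0) + 1L, 1L, length(s$hip)))
  dist_to_ext <- vapply(paused, function(i) min(abs(ext - i)), numeric(1))
  expect_lte(max(dist_to_ext), 2L)
  expect_gt(length(moving), 0.8 * length(v_hip))
})

test_that("cohorts are seeded and subject-distinct", {
  c1 <- make_cohort("healthy", 3, n_cycles = 2, seed = 5)
  c2 <- make_cohort("healthy", 3, n_cycles = 2, seed = 5)
  expect_identical(c1, c2)
  expect_false(identical(c1$S1$profile, c1$S2$profile))
})
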