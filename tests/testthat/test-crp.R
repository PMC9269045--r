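test_that("Hilbert phase follows the analytic cos/sin pair", {
  # discrete transform of cos is sin (interior points)
  x <- cos(2 * pi * grid101 / 100)
  h <- hilbert_transform(x - mean(x))
  expect_lt(max(abs(h[6:96] - sin(2 * pi * grid101 / 100)[6:96])), 0.05)
  ph <- analytic_phase(normalized_cycle(x, 50))
  # phase advances ~+90 degrees over a quarter period
  expect_equal(wrap_angle(ph$phi[26] - ph$phi[1]), 90, tolerance = 2.5)
  # amplitude and offset invariance
  ph3 <- analytic_phase(normalized_cycle(3 * x + 7, 50))
  expect_equal(ph$phi, ph3$phi, tolerance = 1e-9)
  expect_error(analytic_phase(normalized_cycle(rep(2, 101), 50)), "degenerate")
})

test_that("CRP of identical signals is zero and pair swap flips the sign", {
  p1 <- analytic_phase(sine_cycle(amp = 30))
  p2 <- analytic_phase(sine_cycle(amp = 12, phase = 1.1))
  expect_true(all(crp(p1, p1)$crp == 0))
  c12 <- crp(p1, p2)
  c21 <- crp(p2, p1)
  expect_equal(wrap_angle(c12$crp + c21$crp), rep(0, 101), tolerance = 1e-9)
})

test_that("imposed single-harmonic lags are recovered away from the endpoints", {
  for (lag in c(0.1, 0.25, 0.4)) {
    c_lag <- crp(analytic_phase(sine_cycle()),
                 analytic_phase(sine_cycle(phase = 2 * pi * lag)))
    dev <- abs(wrap_angle(c_lag$crp[6:96] - 360 * lag))
    expect_lt(mean(dev), 2)
  }
})

test_that("crp_compare matches hand computation and degenerates gracefully", {
  a <- toy_crp(c(0, 10, 20, 10, 0))
  b <- toy_crp(c(0, 20, 40, 20, 0))
  cc <- crp_compare(a, b)
  expect_equal(cc$rmse, sqrt((0 + 100 + 400 + 100 + 0) / 5), tolerance = 1e-12)
  expect_equal(cc$pcc, 1, tolerance = 1e-12)
  # identity and constant shift
  expect_equal(crp_compare(a, a)$rmse, 0)
  shifted <- toy_crp(a$crp + 10)
  expect_equal(crp_compare(shifted, a)$rmse, 10, tolerance = 1e-12)
  expect_equal(crp_compare(shifted, a)$pcc, 1, tolerance = 1e-12)
  # zero-variance window: PCC flagged NA, RMSE still returned
  flat <- toy_crp(rep(5, 5))
  expect_warning(cc2 <- crp_compare(flat, a), "PCC undefined")
  expect_true(is.na(cc2$pcc))
  expect_gt(cc2$rmse, 0)
  expect_error(crp_compare(toy_crp(1:3), toy_crp(1:4)), "different grids")
})

test_that("stance/swing windows are resolved from the first curve's boundary", {
  set.seed(3)
  vals <- rnorm(101, sd = 20)
  a <- toy_crp(vals, stance_end = 40)
  b <- toy_crp(rev(vals), stance_end = 40)
  whole <- crp_compare(a, b, "whole")
  st <- crp_compare(a, b, "stance")
  sw <- crp_compare(a, b, "swing")
  expect_equal(st$n_points + sw$n_points, whole$n_points)
  expect_equal(st$n_points, sum(grid101 <= 40))
})

test_that("subject CRP profiles follow the pairing conventions", {
  p <- quiet_profile()
  tr <- generate_trial(p, 4, seed = 6)
  own <- trial_cycles(tr, align = "own")
  intra <- subject_crp_profile(own, "intralimb")
  expect_named(intra, c("R", "L"), ignore.order = TRUE)
  expect_identical(intra$L$pair_label, c("L_hip", "L_knee"))  # hip = signal 1
  # interlimb on a common time base: half-cycle offset of a single-harmonic
  # hip waveform gives a constant 180-degree CRP away from the endpoints
  p1 <- quiet_profile(harmonic_count = 1)
  tr1 <- generate_trial(p1, 4, seed = 6)
  refc <- trial_cycles(tr1, align = "reference")
  inter <- subject_crp_profile(refc, "interlimb", side_roles = p1$side_roles)
  expect_named(inter, c("hip", "knee", "inter_mean"), ignore.order = TRUE)
  dev180 <- abs(wrap_angle(inter$hip$crp[6:96] - 180))
  expect_lt(mean(dev180), 2)
  # both limbs identical (zero offset) -> interlimb CRP identically ~0
  p0 <- quiet_profile(phase_offset_between_limbs = 0)
  tr0 <- generate_trial(p0, 4, seed = 6)
  inter0 <- subject_crp_profile(trial_cycles(tr0, align = "reference"),
                                "interlimb", side_roles = p0$side_roles)
  expect_lt(max(abs(inter0$hip$crp)), 1e-6)
})

test_that("circular mean CRP is wraparound-safe", {
  near_pi <- list(toy_crp(rep(179, 101)), toy_crp(rep(-179, 101)))
  m <- mean_crp(near_pi)
  expect_equal(abs(m$crp[1]), 180, tolerance = 1e-9)
})
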