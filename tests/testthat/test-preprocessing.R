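test_that("segmentation uses events when present and detects them otherwise", {
  p <- quiet_profile()
  tr <- generate_trial(p, 5, seed = 2)
  truth <- tr$sides$R$hs
  with_ev <- segment_cycles(trial_trajectory(tr, "R", "hip"))
  expect_equal(with_ev$start, truth[-length(truth)])
  expect_equal(with_ev$end, truth[-1L])
  # events stripped: hip-maxima detection recovers ground truth within 2 samples
  blind <- segment_cycles(trial_trajectory(tr, "R", "hip", keep_events = FALSE))
  expect_equal(nrow(blind), nrow(with_ev))
  expect_lte(max(abs(blind$start - with_ev$start)), 2L)
  # degenerate input
  expect_error(segment_cycles(joint_trajectory(rep(1, 200), 100)),
               "heel strikes")
})

test_that("normalization is identity on 101-sample cycles and places toe off", {
  x <- sin(2 * pi * (0:100) / 100) * 20
  traj <- joint_trajectory(x, 100)
  nc <- normalize_cycle(traj, c(1L, 101L), 51L)
  expect_equal(nc$angle, x)
  expect_equal(nc$stance_end_pct, 50)
  expect_error(normalize_cycle(traj, c(1L, 101L), 101L), "toe_off")
  # resampling a pure sinusoid stays within 0.05 degrees of the analytic curve
  n <- 137
  tt <- seq(0, 1, length.out = n)
  traj2 <- joint_trajectory(10 * sin(2 * pi * tt), n - 1)
  nc2 <- normalize_cycle(traj2, c(1L, n), 60L)
  expect_lt(max(abs(nc2$angle - 10 * sin(2 * pi * grid101 / 100))), 0.05)
})

test_that("harmonic fitting recovers exact basis members", {
  # exact fundamental
  f <- fit_sinusoid_sum(sine_cycle(amp = 10), 3)
  expect_equal(f$fit$amplitude[1L], 10, tolerance = 1e-6)
  expect_lt(max(f$fit$amplitude[2:3]), 1e-6)
  expect_lt(f$fit$residual_rms, 1e-6)
  # constant curve: intercept only
  fc <- fit_sinusoid_sum(normalized_cycle(rep(5, 101), 50), 2)
  expect_equal(fc$fit$mean_offset, 5)
  expect_lt(max(fc$fit$amplitude), 1e-9)
  expect_error(fit_sinusoid_sum(sine_cycle(), 50), "rank-deficient")
  expect_error(fit_sinusoid_sum(sine_cycle(), 0), "K")
})

test_that("harmonic smoothing is an idempotent projection with nested residuals", {
  set.seed(7)
  noisy <- normalized_cycle(10 * sin(2 * pi * grid101 / 100) +
                              3 * cos(6 * pi * grid101 / 100) +
                              rnorm(101), 47)
  once <- fit_sinusoid_sum(noisy, 4)
  twice <- fit_sinusoid_sum(once$smoothed, 4)
  expect_lt(max(abs(once$smoothed$angle - twice$smoothed$angle)), 1e-9)
  # residual never increases with K
  res <- vapply(1:10, function(K) fit_sinusoid_sum(noisy, K)$fit$residual_rms,
                numeric(1))
  expect_true(all(diff(res) <= 1e-12))
})

test_that("normalization preserves extrema of band-limited cycles", {
  p <- quiet_profile()
  tr <- generate_trial(p, 3, seed = 4)
  traj <- trial_trajectory(tr, "R", "knee")
  cycles <- normalize_all_cycles(traj)
  for (nc in cycles) {
    expect_lt(abs(diff(range(nc$angle)) - p$rom_knee[["R"]]), 0.1)
  }
  # representative-cycle rule returns a member of the list
  rep_c <- select_representative_cycle(cycles)
  expect_true(any(vapply(cycles, identical, logical(1), rep_c)))
})
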