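test_that("angular velocity has correct magnitude and unit scaling", {
  const <- normalized_cycle(rep(10, 101), 50)
  expect_true(all(angular_velocity(const, 1.2) == 0))
  a <- 30; T_s <- 1.25
  cyc <- sine_cycle(amp = a)
  om <- angular_velocity(cyc, T_s)
  expect_equal(max(abs(om)), 2 * pi * a / T_s, tolerance = 0.02 * 2 * pi * a / T_s)
  expect_equal(angular_velocity(cyc, 2 * T_s), om / 2,
               ignore_attr = TRUE)
  expect_error(angular_velocity(cyc, 0), "stride_duration")
})

test_that("pause mask applies a strict threshold", {
  expect_true(pause_mask(4.999))
  expect_false(pause_mask(5))
  expect_false(any(pause_mask(c(-10, 10, 50))))
  expect_error(pause_mask(1, threshold = 0))
})

test_that("decomposition index follows the exclusive-or rule", {
  n <- 101L
  move <- rep(FALSE, n)          # moving = not paused
  pause <- rep(TRUE, n)
  # both moving, both paused -> 0
  expect_equal(decomposition_index(move, move, 60)$di_whole, 0)
  expect_equal(decomposition_index(pause, pause, 60)$di_whole, 0)
  # A paused on 30 interior points while B moves
  a <- move; a[11:40] <- TRUE
  di <- decomposition_index(a, move, 60)
  expect_equal(di$di_whole, 30 / 101, tolerance = 0.01)
  # symmetry under mask swap
  expect_equal(decomposition_index(move, a, 60)$di_whole, di$di_whole)
  expect_error(decomposition_index(a, move[-1], 60), "length")
})

test_that("stance and swing DIs are normalized by their phase durations", {
  n <- 101L
  move <- rep(FALSE, n)
  a <- move; a[1:20] <- TRUE          # pause entirely within stance (<=50%)
  di <- decomposition_index(a, move, 50)
  n_st <- sum(grid101 <= 50)
  expect_equal(di$di_stance, 20 / n_st)
  expect_equal(di$di_swing, 0)
  expect_equal(di$di_whole, 20 / n)
})

test_that("enlarging a one-sided pause never decreases DI", {
  n <- 101L
  move <- rep(FALSE, n)
  last <- -1
  for (w in c(5, 15, 30, 60)) {
    a <- move; a[10 + seq_len(w)] <- TRUE
    di <- decomposition_index(a, move, 60)$di_whole
    expect_gte(di, last)
    last <- di
  }
})

test_that("an imposed knee pause is recovered from a generated trial", {
  # 30%-of-cycle knee pause placed where the hip keeps moving
  p <- quiet_profile(pause_spec = pause_window("L", "knee", 55, 85))
  tr <- generate_trial(p, 6, seed = 3)
  di <- trial_di(tr, "L", method = "raw")
  expect_lt(abs(di$di_whole - 0.30), 0.02)
  # the slope estimator recovers the same pause from noisy data within the
  # blur of its 0.2 s window
  pn <- make_profile("healthy",
                     overrides = list(pause_spec = pause_window("L", "knee", 55, 85)))
  tn <- generate_trial(pn, 6, seed = 3)
  din <- trial_di(tn, "L")
  expect_gt(din$di_whole, 0.12)
  expect_lt(din$di_whole, 0.35)
  # harmonic-fit velocities cannot represent the hold plateau
  dih <- trial_di(tr, "L", method = "harmonic", K = 10)
  expect_lt(dih$di_whole, di$di_whole)
})

test_that("stroke trials show higher DI on the affected side", {
  ok <- 0L
  n_rep <- 30L
  for (r in seq_len(n_rep)) {
    co <- make_cohort("stroke", 1, n_cycles = 5, seed = 4000 + r)
    di <- cohort_di_summary(co)
    ok <- ok + (di$di_whole[di$role == "affected"] >=
                  di$di_whole[di$role == "sound"])
  }
  expect_gte(ok, ceiling(0.9 * n_rep))
})
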