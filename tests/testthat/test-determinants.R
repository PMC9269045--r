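test_that("VIF and condition indices flag collinearity", {
  set.seed(11)
  n <- 60
  # centered, orthogonalized predictors -> VIF exactly 1
  raw <- scale(matrix(rnorm(n * 3), n, 3), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(raw))
  d <- as.data.frame(Q)
  names(d) <- paste0("x", 1:3)
  diag1 <- collinearity_diagnostics(d, names(d))
  expect_equal(diag1$vif, rep(1, 3), tolerance = 1e-6)
  expect_false(any(diag1$flagged))
  # duplicated column -> infinite VIF, flagged
  d$x4 <- d$x1
  diag2 <- collinearity_diagnostics(d, paste0("x", 1:4))
  expect_true(all(is.infinite(diag2$vif[c(1, 4)])))
  expect_true(all(diag2$flagged[c(1, 4)]))
  # near-collinearity -> VIF > 10 for the pair
  d2 <- data.frame(x1 = rnorm(n))
  d2$x2 <- d2$x1 + rnorm(n, 0, 0.01 * sd(d2$x1))
  d2$x3 <- rnorm(n)
  diag3 <- collinearity_diagnostics(d2, c("x1", "x2", "x3"))
  expect_true(all(diag3$vif[1:2] > 10))
  expect_lt(diag3$vif[3], 10)
  expect_gt(max(attr(diag3, "condition_indices")), 10)
})

test_that("stepwise recovers a dominant predictor and honors trivial cases", {
  # exact single-predictor relationship
  d <- data.frame(x1 = seq_len(20))
  d$y <- d$x1
  # exact fit: lm's summary legitimately warns about a perfect fit
  sw <- suppressWarnings(stepwise_select(d, "y", "x1"))
  expect_identical(sw$selected, "x1")
  expect_equal(sw$r_squared, 1)
  # pure noise may select nothing: empty model is a valid, non-error result
  set.seed(21)
  d2 <- data.frame(matrix(rnorm(40 * 3), 40, 3))
  names(d2) <- paste0("x", 1:3)
  d2$y <- rnorm(40)
  sw2 <- stepwise_select(d2, "y", paste0("x", 1:3), alpha_enter = 1e-6)
  expect_length(sw2$selected, 0)
  expect_equal(sw2$r_squared, 0)
})

test_that("true predictor is always recovered; false entries match the
           binomial rate implied by alpha_enter", {
  n_rep <- 100L
  hit <- 0L; exact <- 0L
  for (r in seq_len(n_rep)) {
    set.seed(5000 + r)
    n <- 40
    d <- as.data.frame(matrix(rnorm(n * 6), n, 6))
    names(d) <- paste0("x", 1:6)
    d$y <- 3 * d$x1 + rnorm(n, 0, 0.1 * sd(3 * d$x1))
    sw <- stepwise_select(d, "y", paste0("x", 1:6))
    hit <- hit + ("x1" %in% sw$selected)
    exact <- exact + identical(sw$selected, "x1")
  }
  expect_equal(hit, n_rep)
  # exact-selection rate ~ 0.9^5 = 0.59 at alpha 0.1 (five independent noise
  # candidates each enter with p ~ U(0,1)); assert a generous band around it
  expect_gt(exact, 0.40 * n_rep)
  expect_lt(exact, 0.80 * n_rep)
})

test_that("pure-noise responses yield empty models at the analytic rate", {
  n_rep <- 200L
  empty <- 0L
  for (r in seq_len(n_rep)) {
    set.seed(7000 + r)
    d <- as.data.frame(matrix(rnorm(40 * 6), 40, 6))
    names(d) <- paste0("x", 1:6)
    d$y <- rnorm(40)
    empty <- empty + (length(stepwise_select(d, "y", paste0("x", 1:6))$selected) == 0L)
  }
  expect_gte(empty, 0.40 * n_rep)
})

test_that("selection is invariant to linear rescaling of predictors", {
  set.seed(31)
  d <- as.data.frame(matrix(rnorm(40 * 4), 40, 4))
  names(d) <- paste0("x", 1:4)
  d$y <- 2 * d$x2 - d$x4 + rnorm(40, 0, 0.3)
  s1 <- stepwise_select(d, "y", paste0("x", 1:4))
  d2 <- d
  d2$x2 <- d$x2 * 1000
  d2$x4 <- d$x4 / 500
  s2 <- stepwise_select(d2, "y", paste0("x", 1:4))
  expect_identical(s1$selected, s2$selected)
  expect_equal(s1$r_squared, s2$r_squared, tolerance = 1e-9)
})

test_that("refitting the selected model reproduces coefficients and R2", {
  set.seed(41)
  d <- as.data.frame(matrix(rnorm(50 * 5), 50, 5))
  names(d) <- paste0("x", 1:5)
  d$y <- 1 + 2 * d$x1 + 0.5 * d$x3 + rnorm(50, 0, 0.2)
  sw <- stepwise_select(d, "y", paste0("x", 1:5))
  refit <- lm(as.formula(paste("y ~", paste(sw$selected, collapse = "+"))), d)
  expect_equal(sort(names(coef(refit))), sort(names(sw$coefficients)))
  expect_equal(unname(coef(refit)[names(sw$coefficients)]),
               unname(sw$coefficients), tolerance = 1e-12)
  expect_equal(summary(refit)$r.squared, sw$r_squared, tolerance = 1e-12)
})

test_that("a RoM-driven synthetic response is traced back to RoM_knee", {
  n_rep <- 30L
  found <- 0L
  for (r in seq_len(n_rep)) {
    profs <- lapply(seq_len(24), function(i)
      jitter_profile(make_profile("stroke"), 9000 + 50 * r + i, sd = 0.12))
    ft <- data.frame(
      di_stance = vapply(profs, function(p) runif(1, 0.3, 0.6), numeric(1)),
      di_swing = vapply(profs, function(p) runif(1, 0.1, 0.4), numeric(1)),
      swing_percentage = vapply(profs, function(p) p$swing_percentage[["L"]], numeric(1)),
      rom_hip = vapply(profs, function(p) p$rom_hip[["L"]], numeric(1)),
      rom_knee = vapply(profs, function(p) p$rom_knee[["L"]], numeric(1)),
      speed = vapply(profs, function(p) p$speed, numeric(1)))
    set.seed(9000 + r)
    ft$crp_rmse <- 90 - 1.2 * ft$rom_knee + rnorm(24, 0, 0.15 * sd(1.2 * ft$rom_knee))
    sw <- stepwise_select(ft, "crp_rmse", setdiff(names(ft), "crp_rmse"))
    found <- found + ("rom_knee" %in% sw$selected)
  }
  expect_gte(found, ceiling(0.9 * n_rep))
})
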