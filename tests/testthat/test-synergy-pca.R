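test_that("channel specs define the documented input sets", {
  ih <- channel_spec("interlimb_hip")
  expect_length(ih$input_channels, 4L)
  expect_identical(ih$target_channel, "hip_deg")
  il <- channel_spec("intralimb_knee")
  expect_length(il$input_channels, 4L)
  expect_true(all(grepl("thigh", il$input_channels)))
  expect_false(il$target_channel %in% il$input_channels)
})

test_that("datasets assemble the right channels and guard normalization", {
  cohort <- make_cohort("healthy", 3, n_cycles = 2, seed = 1)
  ds <- build_dataset(cohort, channel_spec("interlimb_hip"), target_side = "L")
  expect_length(ds$subjects, 3L)
  expect_equal(ncol(ds$subjects$S1$X), 4L)
  expect_equal(nrow(ds$subjects$S1$X), length(ds$subjects$S1$y))
  # interlimb inputs come from the contralateral (R) side
  expect_equal(ds$subjects$S1$X[, 1L], cohort$S1$sides$R$hip)
  expect_equal(ds$subjects$S1$y, cohort$S1$sides$L$hip)
  st <- normalization_stats(ds, c("S1", "S2"))
  dn <- apply_normalization(ds, st)
  expect_true(dn$normalized)
  expect_warning(dn2 <- apply_normalization(dn, st), "already normalized")
  expect_identical(dn2$subjects, dn$subjects)
  # training-subject statistics: pooled S1+S2 inputs have mean 0, sd 1
  Z <- rbind(dn$subjects$S1$X, dn$subjects$S2$X)
  expect_equal(colMeans(Z), rep(0, 4), ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(apply(Z, 2, sd), rep(1, 4), ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("PCA-CLME reconstructs exact linear couplings and stays affine", {
  ds <- make_synergy_cohort(4, "linear", "hip", n_cycles = 3, seed = 5)
  model <- fit_pca_clme(ds$subjects[1:3], variance_target = 1.0)
  # loadings orthonormal
  expect_equal(crossprod(model$loadings), diag(model$k), tolerance = 1e-9)
  pred <- predict(model, ds$subjects[[4L]]$X)
  expect_lt(sqrt(mean((pred - ds$subjects[[4L]]$y)^2)), 1e-6)
  # prediction at the training input mean equals the training target mean
  d <- nrow(model$input_block)
  mu_x <- model$center[seq_len(d)]
  expect_equal(predict(model, matrix(mu_x, 1)), model$center[d + 1L],
               ignore_attr = TRUE, tolerance = 1e-9)
  # linearity: doubling the input deviation doubles the output deviation
  x1 <- ds$subjects[[4L]]$X[10, , drop = FALSE]
  dev1 <- predict(model, x1) - predict(model, matrix(mu_x, 1))
  x2 <- sweep(sweep(x1, 2, mu_x, "-") * 2, 2, mu_x, "+")
  dev2 <- predict(model, x2) - predict(model, matrix(mu_x, 1))
  expect_equal(dev2, 2 * dev1, tolerance = 1e-9)
  expect_error(predict(model, ds$subjects[[4L]]$X[, 1:3]), "channels")
})

test_that("variance target 1 retains the full rank on generic data", {
  set.seed(9)
  subj <- lapply(1:3, function(i)
    list(X = matrix(rnorm(300 * 4), 300, 4), y = rnorm(300)))
  m <- fit_pca_clme(subj, variance_target = 1.0)
  expect_equal(m$k, 5L)
  expect_error(fit_pca_clme(subj[1]), "training subjects")
})

test_that("PCA affine equivariance: shifting targets shifts predictions", {
  ds <- make_synergy_cohort(4, "linear", "knee", n_cycles = 2, seed = 8)
  train <- ds$subjects[1:3]
  shifted <- lapply(train, function(s) { s$y <- s$y + 25; s })
  m0 <- fit_pca_clme(train, 1.0)
  m1 <- fit_pca_clme(shifted, 1.0)
  X <- ds$subjects[[4L]]$X
  expect_equal(predict(m1, X), predict(m0, X) + 25, tolerance = 1e-6)
})

test_that("white-noise targets are not fit by the PCA model", {
  worst <- -Inf
  for (r in 1:20) {
    ds <- make_synergy_cohort(4, "noise", "hip", n_cycles = 2, seed = 300 + r)
    rep_ <- loso_evaluate(ds, "pca", config = list(variance_target = 0.95),
                          seed = r)
    worst <- max(worst, rep_$means[["r2"]])
  }
  expect_lte(worst, 0.05)
})

test_that("regression metrics match brute-force formula evaluation", {
  set.seed(13)
  for (r in 1:1000) {
    n <- sample(5:50, 1)
    pred <- rnorm(n, sd = 10)
    truth <- rnorm(n, sd = 10)
    m <- regression_metrics(pred, truth)
    expect_equal(m$rmse, sqrt(sum((pred - truth)^2) / n), tolerance = 1e-10)
    expect_equal(m$mae, sum(abs(pred - truth)) / n, tolerance = 1e-10)
    num <- sum((pred - mean(pred)) * (truth - mean(truth)))
    den <- sqrt(sum((pred - mean(pred))^2) * sum((truth - mean(truth))^2))
    expect_equal(m$pearson, num / den, tolerance = 1e-10)
    expect_equal(m$r2, 1 - sum((pred - truth)^2) /
                   sum((truth - mean(truth))^2), tolerance = 1e-10)
    expect_gte(m$rmse, m$mae)
  }
})

test_that("LOSO produces one session per subject plus means", {
  ds <- make_synergy_cohort(5, "linear", "hip", n_cycles = 2, seed = 17)
  rep_ <- loso_evaluate(ds, "pca", config = list(variance_target = 1.0), seed = 2)
  expect_equal(nrow(rep_$sessions), 5L)
  expect_setequal(rep_$sessions$subject, names(ds$subjects))
  expect_equal(rep_$means[["rmse"]], mean(rep_$sessions$rmse))
  expect_lt(rep_$means[["rmse"]], 1e-6)
  expect_error(loso_evaluate(
    structure(list(subjects = ds$subjects[1:2], spec = ds$spec),
              class = "sequence_dataset"), "pca"), "3 subjects")
})
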