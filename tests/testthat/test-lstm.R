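test_that("gate equations reproduce hand evaluation for constructed weights", {
  # all-zero weights, output bias beta: f=i=o=sigmoid(0)=0.5, g=tanh(0)=0,
  # s=0, h=tanh(0)*0.5=0, y = Wy h + by = beta at every step
  w <- init_lstm_weights(3, 1, seed = 1)
  for (nm in names(w)) w[[nm]][] <- 0
  w$by <- 3.25
  X <- matrix(rnorm(30), 10, 3)
  expect_equal(lstm_forward(w, X), rep(3.25, 10))

  # one step, one unit, input weight only on the candidate and input gate:
  # s1 = tanh(w1g*x) * sigmoid(w1i*x), h1 = tanh(s1) * sigmoid(0)
  w2 <- init_lstm_weights(1, 1, seed = 1)
  for (nm in names(w2)) w2[[nm]][] <- 0
  w2$W1g[] <- 0.7; w2$W1i[] <- 0.3; w2$Wy[] <- 2; w2$by <- -1
  x <- 1.4
  s1 <- tanh(0.7 * x) * plogis(0.3 * x)
  h1 <- tanh(s1) * plogis(0)
  expect_equal(lstm_forward(w2, matrix(x, 1, 1))[1], 2 * h1 - 1,
               tolerance = 1e-12)
  # two steps with nonzero forget bias: s2 = g2*i2 + s1*f2
  w2$bf[] <- 0.5
  x2 <- c(1.4, -0.6)
  f2 <- plogis(0.5); i_ <- plogis(0.3 * x2); g_ <- tanh(0.7 * x2)
  s1b <- g_[1] * i_[1]                      # f enters only via s(t-1)
  s2 <- g_[2] * i_[2] + s1b * f2
  h2 <- tanh(s2) * plogis(0)
  out <- lstm_forward(w2, matrix(x2, 2, 1))
  expect_equal(out[2], 2 * h2 - 1, tolerance = 1e-12)
})

test_that("hidden state stays bounded by construction", {
  w <- init_lstm_weights(2, 6, seed = 3)
  X <- matrix(rnorm(400, sd = 5), 200, 2)
  # run forward and check |y| <= sum|Wy| + |by| (since |h| <= 1 elementwise)
  y <- lstm_forward(w, X)
  expect_true(all(abs(y) <= sum(abs(w$Wy)) + abs(w$by) + 1e-12))
})

test_that("training is deterministic and learns a constant target", {
  set.seed(2)
  train <- list(list(X = matrix(rnorm(400), 200, 2), y = rep(0, 200)))
  cfg <- lstm_config(hidden = 8, epochs = 20, window = 100, seed = 5)
  m1 <- fit_lstm(train, cfg)
  m2 <- fit_lstm(train, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_lt(max(abs(predict(m1, train[[1]]$X))), 0.5)
})

test_that("a non-finite loss aborts training with learning-rate guidance", {
  set.seed(4)
  X <- matrix(rnorm(200), 100, 2)
  X[50, 1] <- NaN          # poisons the forward pass -> non-finite loss
  train <- list(list(X = X, y = rnorm(100)))
  expect_error(
    fit_lstm(train, lstm_config(hidden = 4, epochs = 5, window = 50, seed = 1)),
    "learning_rate")
})

test_that("a linear map across subjects is learned to a few percent of RoM", {
  ds <- make_synergy_cohort(5, "linear", "hip", n_cycles = 3, seed = 23)
  rep_ <- loso_evaluate(ds, "lstm", config = lstm_config(), seed = 23)
  rom <- diff(range(unlist(lapply(ds$subjects, `[[`, "y"))))
  expect_lt(rep_$means[["rmse"]], 0.05 * rom)
  expect_gt(rep_$means[["pearson"]], 0.99)
})
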