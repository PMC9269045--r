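# R interface to the compiled forget-gate LSTM: configuration, weight
# initialization, training, prediction.

#' LSTM training configuration
#'
#' Defaults follow the published model where stated (50 hidden neurons, one
#' output neuron, 50 training epochs); the remaining choices (Adam at 1e-3,
#' mean-squared-error loss, 200-sample training windows, internal target
#' standardization) are package defaults documented in the methods vignette.
#'
#' @param hidden hidden-layer size.
#' @param epochs training epochs.
#' @param learning_rate Adam step size.
#' @param window training-window length in samples; sequences are segmented
#'   into non-overlapping windows for truncated backpropagation through time.
#' @param seed integer seed for weight initialization.
#' @return object of class `lstm_config`.
#' @export
lstm_config <- function(hidden = 50L, epochs = 50L, learning_rate = 1e-3,
                        window = 200L, seed = 1L) {
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 learning_rate = learning_rate, window = as.integer(window),
                 seed = as.integer(seed)),
            class = "lstm_config")
}

#' Initialize LSTM weights
#'
#' Uniform(-1/sqrt(hidden), 1/sqrt(hidden)) initialization of all gate and
#' output weights, drawn with R's RNG under the given seed (so training is
#' bit-reproducible).
#'
#' @param n_inputs number of input channels.
#' @param hidden hidden size.
#' @param seed integer seed.
#' @return named list of weight matrices/vectors (`W1f`, `W2f`, `bf`, ...,
#'   `Wy`, `by`) matching the gate equations.
#' @export
init_lstm_weights <- function(n_inputs, hidden, seed = 1L) {
  restore <- .Random.seed_guard(seed)
  on.exit(restore(), add = TRUE)
  r <- 1 / sqrt(hidden)
  m <- function(nr, nc) matrix(stats::runif(nr * nc, -r, r), nr, nc)
  w <- list()
  for (gate in c("f", "i", "o", "g")) {
    w[[paste0("W1", gate)]] <- m(hidden, n_inputs)
    w[[paste0("W2", gate)]] <- m(hidden, hidden)
    w[[paste0("b", gate)]] <- rep(0, hidden)
  }
  w$bf <- rep(1, hidden)        # open forget gates at the start of training
  w$Wy <- matrix(stats::runif(hidden, -r, r), 1L, hidden)
  w$by <- 0
  w
}

#' Fit the LSTM synergy model
#'
#' Sequence-to-sequence regression of the target joint angle on the input
#' channels, minimizing mean squared error with Adam over truncated-BPTT
#' windows. The target is standardized internally with training statistics
#' (predictions are returned in degrees); inputs are used as given, so
#' z-normalize them with training-subject statistics first (as
#' [loso_evaluate()] does).
#'
#' @param train list of `list(X, y)` per training subject, or a
#'   `sequence_dataset` (all subjects used).
#' @param config an [lstm_config()].
#' @return object of class `lstm_synergy`: trained `weights`, `config`,
#'   target statistics, `loss_history` (standardized-scale MSE per epoch).
#' @export
fit_lstm <- function(train, config = lstm_config()) {
  if (inherits(train, "sequence_dataset")) train <- train$subjects
  if (!length(train)) stop("need >= 1 training subject", call. = FALSE)
  stopifnot(inherits(config, "lstm_config"))
  ys <- unlist(lapply(train, `[[`, "y"))
  mu_y <- mean(ys)
  sd_y <- stats::sd(ys)
  if (!is.finite(sd_y) || sd_y < 1e-12) sd_y <- 1
  Xs <- list(); Ys <- list()
  for (s in train) {
    n <- nrow(s$X)
    starts <- seq(1L, n, by = config$window)
    for (st in starts) {
      en <- min(st + config$window - 1L, n)
      if (en - st + 1L < max(8L, config$window %/% 4L)) next
      Xs[[length(Xs) + 1L]] <- s$X[st:en, , drop = FALSE]
      Ys[[length(Ys) + 1L]] <- (s$y[st:en] - mu_y) / sd_y
    }
  }
  if (!length(Xs)) stop("no training windows; sequences too short",
                        call. = FALSE)
  w0 <- init_lstm_weights(ncol(Xs[[1L]]), config$hidden, config$seed)
  fit <- lstm_train_cpp(Xs, Ys, w0, config$epochs, config$learning_rate)
  if (isTRUE(fit$diverged))
    stop("LSTM training diverged (non-finite loss); lower 'learning_rate' ",
         "in lstm_config()", call. = FALSE)
  structure(list(weights = fit$weights, config = config,
                 target_mean = mu_y, target_sd = sd_y,
                 n_inputs = ncol(Xs[[1L]]),
                 loss_history = fit$loss_history),
            class = "lstm_synergy")
}

#' @export
print.lstm_synergy <- function(x, ...) {
  cat(sprintf(
    "<lstm_synergy: %d inputs -> %d hidden -> 1, %d epochs, final loss %.4g>\n",
    x$n_inputs, x$config$hidden, x$config$epochs,
    x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' Predict with a fitted LSTM synergy model
#'
#' Runs the gate equations stepwise over the full input sequence with zero
#' initial hidden and cell state, then de-standardizes to degrees.
#'
#' @param object a [fit_lstm()] model.
#' @param newdata input matrix (time x channels) or `list(X = ...)`.
#' @param ... unused.
#' @return numeric vector of predicted angles (degrees).
#' @export
predict.lstm_synergy <- function(object, newdata, ...) {
  X <- if (is.list(newdata) && !is.null(newdata$X)) newdata$X else newdata
  X <- as.matrix(X)
  if (ncol(X) != object$n_inputs)
    stop("input has ", ncol(X), " channels; model expects ",
         object$n_inputs, call. = FALSE)
  z <- lstm_forward(object$weights, X)
  z * object$target_sd + object$target_mean
}

#' Raw LSTM forward pass
#'
#' Evaluates the gate equations with the given weights over a sequence,
#' starting from zero hidden and cell state; no scaling is applied. Exposed
#' so hand-constructed weights can be checked directly against the
#' closed-form gate algebra.
#'
#' @param weights weight list as produced by [init_lstm_weights()].
#' @param X input matrix (time x channels).
#' @return numeric vector of raw outputs.
#' @export
lstm_forward <- function(weights, X) {
  as.numeric(lstm_forward_cpp(weights, as.matrix(X)))
}
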