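# Interlimb / intralimb synergy estimation: dataset construction, the
# PCA-subspace linear reconstruction (complementary limb motion estimation),
# evaluation metrics and the leave-one-subject-out protocol.

#' Channel specification for a synergy estimation task
#'
#' Three tasks are supported. Interlimb tasks estimate one limb's hip or knee
#' angle from the contralateral limb's hip and knee angles and angular
#' velocities (4 input channels). The intralimb task estimates the knee angle
#' from the ipsilateral thigh IMU: angular velocity plus 3-axis acceleration
#' (4 input channels).
#'
#' @param task `"interlimb_hip"`, `"interlimb_knee"` or `"intralimb_knee"`.
#' @return object of class `channel_spec` with `input_channels` (ordered) and
#'   `target_channel`.
#' @export
channel_spec <- function(task = c("interlimb_hip", "interlimb_knee",
                                  "intralimb_knee")) {
  task <- match.arg(task)
  spec <- switch(task,
    interlimb_hip = list(
      input_channels = c("hip_deg", "knee_deg", "hip_vel_dps", "knee_vel_dps"),
      target_channel = "hip_deg"),
    interlimb_knee = list(
      input_channels = c("hip_deg", "knee_deg", "hip_vel_dps", "knee_vel_dps"),
      target_channel = "knee_deg"),
    intralimb_knee = list(
      input_channels = c("thigh_gyro_dps", "thigh_acc_x", "thigh_acc_y",
                         "thigh_acc_z"),
      target_channel = "knee_deg"))
  structure(c(list(task = task), spec), class = "channel_spec")
}

trial_channel <- function(trial, side, channel) {
  s <- trial$sides[[side]]
  fs <- trial$sampling_rate
  switch(channel,
         hip_deg = s$hip,
         knee_deg = s$knee,
         hip_vel_dps = central_diff(s$hip) * fs,
         knee_vel_dps = central_diff(s$knee) * fs,
         thigh_gyro_dps = s$thigh_gyro,
         thigh_acc_x = s$thigh_acc[, "x"],
         thigh_acc_y = s$thigh_acc[, "y"],
         thigh_acc_z = s$thigh_acc[, "z"],
         stop("missing channel: ", channel, call. = FALSE))
}

#' Build a per-subject sequence dataset for a synergy task
#'
#' Assembles the input matrix (time x channels, in `spec` order) and target
#' series for every subject. For interlimb tasks the inputs come from the
#' side contralateral to `target_side`; for the intralimb task inputs and
#' target share `target_side`. Channels are left on their native scales;
#' z-normalization statistics are computed from training subjects only at
#' fit/evaluation time (see [loso_evaluate()]), and the target is always kept
#' in degrees.
#'
#' @param trials named list of trials ([make_cohort()]).
#' @param spec a [channel_spec()].
#' @param target_side side whose joint angle is estimated (default `"L"`).
#' @return object of class `sequence_dataset`: `subjects` (named list of
#'   `list(X, y)`), `spec`, `sampling_rate`, `normalized = FALSE`.
#' @export
build_dataset <- function(trials, spec, target_side = "L") {
  stopifnot(inherits(spec, "channel_spec"))
  input_side <- if (startsWith(spec$task, "interlimb"))
    setdiff(c("L", "R"), target_side) else target_side
  subjects <- lapply(trials, function(trial) {
    X <- vapply(spec$input_channels,
                function(ch) trial_channel(trial, input_side, ch),
                numeric(trial$n_samples))
    y <- trial_channel(trial, target_side, spec$target_channel)
    if (nrow(X) != length(y)) stop("input/target length mismatch", call. = FALSE)
    list(X = X, y = y)
  })
  structure(list(subjects = subjects, spec = spec,
                 sampling_rate = trials[[1L]]$sampling_rate,
                 normalized = FALSE, norm_stats = NULL),
            class = "sequence_dataset")
}

#' @export
print.sequence_dataset <- function(x, ...) {
  cat(sprintf("<sequence_dataset: %s, %d subjects, %d channels%s>\n",
              x$spec$task, length(x$subjects), length(x$spec$input_channels),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Per-channel normalization statistics from a subject subset
#'
#' @param ds a [build_dataset()] object.
#' @param subject_ids subjects whose pooled samples define the statistics
#'   (training subjects only, so held-out subjects are normalized with
#'   statistics they did not contribute to).
#' @return list with `mean` and `sd` per input channel.
#' @export
normalization_stats <- function(ds, subject_ids = names(ds$subjects)) {
  X <- do.call(rbind, lapply(ds$subjects[subject_ids], `[[`, "X"))
  s <- apply(X, 2L, stats::sd)
  s[s < 1e-12] <- 1
  list(mean = colMeans(X), sd = s)
}

#' Apply z-normalization to a dataset's input channels
#'
#' Guarded: a dataset that is already normalized is returned unchanged with a
#' warning, so statistics are never applied twice. The target stays in
#' degrees.
#'
#' @param ds a [build_dataset()] object.
#' @param stats statistics from [normalization_stats()].
#' @return a normalized `sequence_dataset`.
#' @export
apply_normalization <- function(ds, stats) {
  if (isTRUE(ds$normalized)) {
    warning("dataset already normalized; statistics not re-applied",
            call. = FALSE)
    return(ds)
  }
  ds$subjects <- lapply(ds$subjects, function(s) {
    s$X <- sweep(sweep(s$X, 2L, stats$mean, "-"), 2L, stats$sd, "/")
    s
  })
  ds$normalized <- TRUE
  ds$norm_stats <- stats
  ds
}

# Moore-Penrose pseudo-inverse via SVD
pinv <- function(A, tol = NULL) {
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * max(s$d) * .Machine$double.eps
  pos <- s$d > tol
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Fit a PCA-subspace linear synergy model (complementary limb motion
#' estimation)
#'
#' Samples of the stacked vector `[inputs; target]` pooled over the training
#' subjects are mean-centered and eigendecomposed. The number of retained
#' components `k` is the smallest count whose eigenvalues reach
#' `variance_target` of the total variance (components with numerically zero
#' eigenvalues are never retained, so `variance_target = 1` keeps the full
#' numerical rank). Prediction composes the target-block loadings with the
#' pseudo-inverse of the input-block loadings applied to mean-centered
#' inputs — an affine map; an exactly linear input-target coupling lies
#' inside the retained subspace and is reconstructed exactly.
#'
#' @param train list of `list(X, y)` per training subject, or a
#'   `sequence_dataset` (all of whose subjects are used).
#' @param variance_target retained-variance fraction in (0, 1] (default
#'   0.95).
#' @return object of class `pca_clme`: `center`, `loadings`, `k`,
#'   `input_block`, `target_block`, `operator` (1 x d), `variance_explained`.
#' @export
fit_pca_clme <- function(train, variance_target = 0.95) {
  if (inherits(train, "sequence_dataset")) train <- train$subjects
  if (length(train) < 2L) stop("need >= 2 training subjects", call. = FALSE)
  Z <- do.call(rbind, lapply(train, function(s) cbind(s$X, s$y)))
  d <- ncol(Z) - 1L
  if (nrow(Z) <= ncol(Z))
    stop("need more time samples than channels", call. = FALSE)
  mu <- colMeans(Z)
  Zc <- sweep(Z, 2L, mu, "-")
  C <- crossprod(Zc) / (nrow(Z) - 1L)
  eig <- eigen(C, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  tol <- max(ev) * 1e-12
  nonzero <- which(ev > tol)
  cum <- cumsum(ev[nonzero]) / sum(ev)
  k <- nonzero[min(which(cum >= min(variance_target, cum[length(cum)])))]
  U <- eig$vectors[, seq_len(k), drop = FALSE]
  Ux <- U[seq_len(d), , drop = FALSE]          # input block (d x k)
  Uy <- U[d + 1L, , drop = FALSE]              # target block (1 x k)
  op <- Uy %*% pinv(Ux)                        # 1 x d
  structure(list(center = mu, loadings = U, k = k,
                 input_block = Ux, target_block = Uy, operator = op,
                 variance_explained = sum(ev[seq_len(k)]) / sum(ev)),
            class = "pca_clme")
}

#' @export
print.pca_clme <- function(x, ...) {
  cat(sprintf("<pca_clme: k = %d components, %.1f%% variance>\n",
              x$k, 100 * x$variance_explained))
  invisible(x)
}

#' Predict a target joint angle from input kinematics
#'
#' @param object a [fit_pca_clme()] model.
#' @param newdata input matrix (time x channels, in the fitted channel
#'   order), or a `list(X = ...)`.
#' @param ... unused.
#' @return numeric vector of predicted target angles (degrees).
#' @export
predict.pca_clme <- function(object, newdata, ...) {
  X <- if (is.list(newdata) && !is.null(newdata$X)) newdata$X else newdata
  X <- as.matrix(X)
  d <- nrow(object$input_block)
  if (ncol(X) != d)
    stop("input has ", ncol(X), " channels; model expects ", d, call. = FALSE)
  mu_x <- object$center[seq_len(d)]
  mu_y <- object$center[d + 1L]
  drop(sweep(X, 2L, mu_x, "-") %*% t(object$operator)) + mu_y
}

#' Regression metrics for angle estimation
#'
#' @param pred,truth numeric vectors (degrees).
#' @return list: `rmse`, `mae`, `pearson`, `r2` (coefficient of
#'   determination, `1 - SS_res / SS_tot`).
#' @export
regression_metrics <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch", call. = FALSE)
  err <- pred - truth
  ss_tot <- sum((truth - mean(truth))^2)
  list(rmse = sqrt(mean(err^2)),
       mae = mean(abs(err)),
       pearson = if (stats::sd(pred) < 1e-12 || stats::sd(truth) < 1e-12)
         NA_real_ else stats::cor(pred, truth),
       r2 = 1 - sum(err^2) / ss_tot)
}

#' Leave-one-subject-out evaluation of a synergy model
#'
#' One session per subject: the model is fitted on all other subjects
#' (inputs z-normalized with statistics from those training subjects only;
#' the held-out subject is normalized with the same statistics) and evaluated
#' on the held-out subject in degrees. Session seeds fan out deterministically
#' from the master seed, so the whole report is reproducible.
#'
#' @param ds a [build_dataset()] object (raw, not pre-normalized).
#' @param model_kind `"pca"` or `"lstm"`.
#' @param config for `"pca"`, optional `variance_target`; for `"lstm"`, a
#'   [lstm_config()].
#' @param seed master seed.
#' @return object of class `evaluation_report`: `sessions` data frame (one
#'   row per held-out subject: rmse, mae, pearson, r2) and `means`.
#' @export
loso_evaluate <- function(ds, model_kind = c("pca", "lstm"), config = list(),
                          seed = 1L) {
  stopifnot(inherits(ds, "sequence_dataset"))
  model_kind <- match.arg(model_kind)
  ids <- names(ds$subjects)
  if (length(ids) < 3L) stop("need >= 3 subjects for LOSO", call. = FALSE)
  rows <- list()
  for (j in seq_along(ids)) {
    held <- ids[j]
    train_ids <- setdiff(ids, held)
    stats <- normalization_stats(ds, train_ids)
    dsn <- apply_normalization(ds, stats)
    train <- dsn$subjects[train_ids]
    test <- dsn$subjects[[held]]
    model <- tryCatch({
      if (model_kind == "pca") {
        vt <- if (!is.null(config$variance_target)) config$variance_target else 0.95
        fit_pca_clme(train, variance_target = vt)
      } else {
        cfg <- if (inherits(config, "lstm_config")) config else
          do.call(lstm_config, config)
        cfg$seed <- child_seed(seed, j)
        fit_lstm(train, cfg)
      }
    }, error = function(e)
      stop("session for held-out subject '", held, "' failed: ",
           conditionMessage(e), call. = FALSE))
    pred <- stats::predict(model, test$X)
    m <- regression_metrics(pred, test$y)
    rows[[j]] <- data.frame(subject = held, rmse = m$rmse, mae = m$mae,
                            pearson = m$pearson, r2 = m$r2,
                            stringsAsFactors = FALSE)
  }
  sessions <- do.call(rbind, rows)
  means <- colMeans(sessions[, c("rmse", "mae", "pearson", "r2")])
  structure(list(sessions = sessions, means = means,
                 model_kind = model_kind, task = ds$spec$task, seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report: %s on %s, %d sessions>\n",
              x$model_kind, x$task, nrow(x$sessions)))
  print(x$sessions, row.names = FALSE, digits = 4)
  cat(sprintf("mean: rmse %.4g, mae %.4g, pearson %.4g, r2 %.4g\n",
              x$means["rmse"], x$means["mae"], x$means["pearson"],
              x$means["r2"]))
  invisible(x)
}

#' Synthetic cohorts with a known input-target coupling
#'
#' Builds an interlimb-style dataset from a jittered healthy cohort and then
#' replaces the target with a constructed function of the inputs, so the
#' recoverable structure is known exactly:
#' \describe{
#'   \item{linear}{target is an exact affine combination of the raw input
#'     channels (plus optional Gaussian noise) — recoverable by any linear
#'     estimator.}
#'   \item{nonlinear}{target is the corresponding contralateral joint angle
#'     passed through a soft saturation (tanh) with a gait-phase-dependent
#'     gain — outside any static linear model's reach, but learnable from
#'     temporal context.}
#'   \item{noise}{target is white noise, independent of the inputs.}
#' }
#'
#' @param n_subjects number of subjects.
#' @param coupling `"linear"`, `"nonlinear"` or `"noise"`.
#' @param target_joint `"hip"` or `"knee"` (selects the task and, for the
#'   nonlinear coupling, the transformed channel).
#' @param n_cycles cycles per subject.
#' @param seed master seed.
#' @param target_noise_sd additive target noise in degrees (default 0).
#' @return a `sequence_dataset`.
#' @export
make_synergy_cohort <- function(n_subjects = 8L,
                                coupling = c("linear", "nonlinear", "noise"),
                                target_joint = c("hip", "knee"),
                                n_cycles = 6L, seed = 1L,
                                target_noise_sd = 0) {
  coupling <- match.arg(coupling)
  target_joint <- match.arg(target_joint)
  cohort <- make_cohort("healthy", n_subjects, n_cycles = n_cycles, seed = seed)
  spec <- channel_spec(paste0("interlimb_", target_joint))
  ds <- build_dataset(cohort, spec, target_side = "L")
  restore <- .Random.seed_guard(child_seed(seed, 911L))
  on.exit(restore(), add = TRUE)
  w <- c(0.6, -0.35, 0.04, -0.02)
  src_col <- if (target_joint == "hip") 1L else 2L
  for (i in seq_along(ds$subjects)) {
    s <- ds$subjects[[i]]
    n <- nrow(s$X)
    trial <- cohort[[i]]
    y <- switch(coupling,
      linear = 10 + drop(s$X %*% w),
      nonlinear = {
        src <- s$X[, src_col]
        z <- (src - mean(src)) / stats::sd(src)
        spc <- trial$samples_per_cycle
        phase <- ((seq_len(n) - 1L) %% spc) / spc
        25 * tanh(1.5 * z) * (1 + 0.5 * sin(2 * pi * phase)) + 20
      },
      noise = stats::rnorm(n, 0, 10))
    if (target_noise_sd > 0) y <- y + stats::rnorm(n, 0, target_noise_sd)
    ds$subjects[[i]]$y <- y
  }
  ds
}
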