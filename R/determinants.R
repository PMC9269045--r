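# Kinematic determinants of disturbed synergy: collinearity diagnostics
# (VIF, condition indices) followed by bidirectional partial-F stepwise
# multiple linear regression at significance level 0.1.

#' Collinearity diagnostics for a candidate predictor set
#'
#' Variance-inflation factors are computed by regressing each predictor on
#' the others (VIF = 1 / (1 - R^2)); condition indices come from the singular
#' values of the unit-length-scaled predictor matrix (intercept column
#' included, Belsley-style).
#'
#' @param data data frame holding the predictors.
#' @param predictors character vector of predictor column names.
#' @return data frame with columns `predictor`, `vif`, `flagged`
#'   (`vif > 10` or infinite), with the condition indices in attribute
#'   `condition_indices`.
#' @export
collinearity_diagnostics <- function(data, predictors) {
  if (length(predictors) < 1L) stop("no predictors given", call. = FALSE)
  X <- as.matrix(data[, predictors, drop = FALSE])
  if (any(!is.finite(X))) stop("missing values in predictors", call. = FALSE)
  n <- nrow(X)
  if (n < length(predictors) + 2L)
    stop("need at least predictors + 2 rows", call. = FALSE)
  vif <- vapply(seq_along(predictors), function(j) {
    y <- X[, j]
    if (stats::sd(y) < 1e-12) return(Inf)
    if (length(predictors) == 1L) return(1)
    others <- X[, -j, drop = FALSE]
    fit <- stats::lm.fit(cbind(1, others), y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1L))
  Xs <- cbind(intercept = 1, X)
  Xs <- sweep(Xs, 2L, sqrt(colSums(Xs^2)), "/")
  sv <- svd(Xs, nu = 0L, nv = 0L)$d
  ci <- max(sv) / sv
  out <- data.frame(predictor = predictors, vif = vif,
                    flagged = !is.finite(vif) | vif > 10,
                    stringsAsFactors = FALSE)
  attr(out, "condition_indices") <- ci
  out
}

#' Bidirectional stepwise selection by partial-F tests
#'
#' Classical stepwise multiple linear regression: at each step the candidate
#' whose partial-F p-value (equivalently, the t-test of its coefficient in
#' the augmented OLS model) is smallest enters if it is `<= alpha_enter`;
#' then any retained predictor whose p-value exceeds `alpha_remove` is
#' removed (worst first). Iteration stops when no change occurs. Ties break
#' deterministically by predictor column order. Constant predictors (infinite
#' VIF) are excluded up front; perfectly collinear candidates (those whose
#' coefficient is inestimable given the current model) are skipped.
#'
#' @param data data frame with response and predictors.
#' @param response response column name.
#' @param predictors candidate predictor column names.
#' @param alpha_enter,alpha_remove entry/removal significance levels
#'   (default 0.1 each).
#' @param drop_collinear exclude predictors flagged by
#'   [collinearity_diagnostics()] (VIF > 10) before selection (default FALSE:
#'   flagged predictors are reported but kept as candidates).
#' @return object of class `stepwise_result`: `selected` (entry order),
#'   `coefficients`, `steps` (data frame of actions and p-values),
#'   `r_squared`, `model` (the final `lm`), `diagnostics`.
#' @export
stepwise_select <- function(data, response, predictors,
                            alpha_enter = 0.1, alpha_remove = 0.1,
                            drop_collinear = FALSE) {
  stopifnot(response %in% names(data), all(predictors %in% names(data)))
  diag <- collinearity_diagnostics(data, predictors)
  candidates <- predictors[is.finite(diag$vif)]
  if (drop_collinear) candidates <- predictors[!diag$flagged]
  y <- data[[response]]
  if (any(!is.finite(y))) stop("missing values in response", call. = FALSE)

  selected <- character(0)
  steps <- list()
  coef_p <- function(vars) {
    # p-values of each term's t test in the OLS fit y ~ vars
    f <- stats::as.formula(paste(response, "~",
                                 paste(c("1", vars), collapse = "+")))
    fit <- stats::lm(f, data = data)
    s <- summary(fit)$coefficients
    list(fit = fit, p = s[, 4L], est = s[, 1L])
  }
  repeat {
    changed <- FALSE
    # entry scan
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      pvals <- rep(NA_real_, length(pool))
      for (j in seq_along(pool)) {
        cand <- pool[j]
        fit <- coef_p(c(selected, cand))
        if (cand %in% rownames(summary(fit$fit)$coefficients) &&
            !is.na(fit$p[cand]))
          pvals[j] <- fit$p[cand]
      }
      ok <- which(!is.na(pvals) & pvals <= alpha_enter)
      if (length(ok)) {
        best <- ok[which.min(pvals[ok])]   # first minimum = column order
        selected <- c(selected, pool[best])
        steps[[length(steps) + 1L]] <- data.frame(
          action = "enter", predictor = pool[best], p_value = pvals[best],
          stringsAsFactors = FALSE)
        changed <- TRUE
      }
    }
    # removal scan
    if (length(selected)) {
      fit <- coef_p(selected)
      p <- fit$p[selected]
      worst <- which.max(p)
      if (!is.na(p[worst]) && p[worst] > alpha_remove) {
        steps[[length(steps) + 1L]] <- data.frame(
          action = "remove", predictor = selected[worst],
          p_value = unname(p[worst]), stringsAsFactors = FALSE)
        selected <- selected[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  final <- coef_p(selected)
  r2 <- if (length(selected)) summary(final$fit)$r.squared else 0
  structure(list(
    selected = selected,
    coefficients = stats::coef(final$fit),
    steps = if (length(steps)) do.call(rbind, steps) else
      data.frame(action = character(), predictor = character(),
                 p_value = numeric()),
    r_squared = r2,
    model = final$fit,
    diagnostics = diag,
    alpha_enter = alpha_enter, alpha_remove = alpha_remove
  ), class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat("<stepwise_result>\n  selected:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)",
      sprintf("\n  R^2 = %.3f\n", x$r_squared))
  invisible(x)
}

#' Subject-level feature table for determinant analysis
#'
#' Joins each subject-side's CRP-deviation summary (response) with its DI,
#' RoM, swing-percentage and speed predictors, mirroring the candidate set
#' used for the determinant analysis (DI_sw, DI_sta, percentage, ROM_hip,
#' ROM_knee, speed).
#'
#' @param cohort named list of trials.
#' @param reference reference CRP set from [reference_crp()].
#' @param pairing `"intralimb"` (one row per subject-side) or `"interlimb"`
#'   (one row per subject).
#' @param window CRP window for the response (`"whole"`, `"stance"`,
#'   `"swing"`).
#' @param K smoothing harmonics.
#' @return data frame with columns `crp_rmse` (response), `di_stance`,
#'   `di_swing`, `rom_hip`, `rom_knee`, `swing_percentage`, `speed`, plus
#'   labels.
#' @export
build_feature_table <- function(cohort, reference,
                                pairing = c("intralimb", "interlimb"),
                                window = "whole", K = 6L) {
  pairing <- match.arg(pairing)
  crp_tab <- cohort_crp_summary(cohort, reference, K = K)
  di_tab <- cohort_di_summary(cohort)
  rows <- list()
  for (subj in names(cohort)) {
    prof <- cohort[[subj]]$profile
    if (pairing == "intralimb") {
      for (side in c("L", "R")) {
        resp <- crp_tab[crp_tab$subject == subj &
                          crp_tab$pairing == paste0("intra_", side) &
                          crp_tab$window == window, "rmse_deg"]
        di <- di_tab[di_tab$subject == subj & di_tab$side == side, ]
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subj, side = side, role = prof$side_roles[[side]],
          crp_rmse = resp, di_stance = di$di_stance, di_swing = di$di_swing,
          rom_hip = prof$rom_hip[[side]], rom_knee = prof$rom_knee[[side]],
          swing_percentage = prof$swing_percentage[[side]],
          speed = prof$speed, stringsAsFactors = FALSE)
      }
    } else {
      resp <- crp_tab[crp_tab$subject == subj &
                        crp_tab$pairing == "inter_mean" &
                        crp_tab$window == window, "rmse_deg"]
      di <- di_tab[di_tab$subject == subj, ]
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subj, side = "both", role = "both",
        crp_rmse = resp,
        di_stance = mean(di$di_stance), di_swing = mean(di$di_swing),
        rom_hip = mean(unlist(prof$rom_hip)),
        rom_knee = mean(unlist(prof$rom_knee)),
        swing_percentage = mean(unlist(prof$swing_percentage)),
        speed = prof$speed, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
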