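#' Area under the ROC curve (Mann-Whitney form)
#'
#' `AUC = P(score_presence > score_absence) + 0.5 P(tie)` over all
#' presence-absence pairs, equivalent to trapezoidal ROC integration. 1 is
#' a perfect fit; 0.5 is no better than chance. Invariant under strictly
#' monotone transforms of the scores.
#'
#' @param estimates Numeric scores (missing values dropped pairwise with
#'   their response).
#' @param y Binary response aligned with `estimates`.
#' @return AUC in \[0, 1\].
#' @export
npmr_auc <- function(estimates, y) {
  keep <- !is.na(estimates)
  estimates <- estimates[keep]
  y <- y[keep]
  check_response(y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC needs scored points in both classes", call. = FALSE)
  }
  r <- rank(estimates, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated coefficient of determination (xR2)
#'
#' `xR2 = 1 - sum((y - p_hat)^2) / sum((y - mean(y))^2)` computed from
#' leave-one-out estimates; at most 1, no lower bound. Missing estimates
#' contribute at the naive probability (same convention as the logB
#' likelihood).
#'
#' @param estimates Leave-one-out probability estimates.
#' @param y Binary response.
#' @return xR2 (<= 1).
#' @export
cross_r2 <- function(estimates, y) {
  check_response(y)
  if (length(estimates) != length(y)) {
    stop("estimates and y lengths differ", call. = FALSE)
  }
  ybar <- mean(y)
  sst <- sum((y - ybar)^2)
  if (sst == 0) stop("zero response variance", call. = FALSE)
  p <- ifelse(is.na(estimates), ybar, estimates)
  1 - sum((y - p)^2) / sst
}

#' Sensitivity of the response to one predictor (Q)
#'
#' Each training point's value of `predictor` is nudged by +/- 5% of the
#' predictor's observed range and the (non-leave-one-out) estimate is
#' recomputed. `q_raw` is the mean absolute response change over points and
#' both directions, as a proportion of the response range; `q` divides by
#' the nudge fraction, so `q = 1` means the response shifts one-for-one
#' with the predictor in range-relative units. Predictors that are not
#' model terms have Q = 0 by construction. Sensitivities are evaluated on
#' the original, un-tuned model.
#'
#' @param fit An `npmr_fit`.
#' @param predictor Predictor name (need not be a model term).
#' @param nudge Nudge size as a fraction of the predictor range
#'   (default 0.05).
#' @return Tibble with `predictor`, `q`, `q_raw`.
#' @export
sensitivity_q <- function(fit, predictor, nudge = 0.05) {
  data <- fit$data
  if (!predictor %in% names(data)) {
    stop("unknown predictor: ", predictor, call. = FALSE)
  }
  if (!predictor %in% fit$model$terms$predictor) {
    return(tibble::tibble(predictor = predictor, q = 0, q_raw = 0))
  }
  rng <- diff(range(data[[predictor]], na.rm = TRUE))
  y_rng <- diff(range(data$y))
  base <- predict(fit)
  deltas <- vapply(c(-1, 1), function(sgn) {
    nd <- data
    nd[[predictor]] <- nd[[predictor]] + sgn * nudge * rng
    pert <- predict(fit, newdata = nd)
    mean(abs(pert - base), na.rm = TRUE)
  }, numeric(1))
  q_raw <- mean(deltas) / y_rng
  tibble::tibble(predictor = predictor, q = q_raw / nudge, q_raw = q_raw)
}

#' Mean residuals by response class
#'
#' Residual is `y - p_hat`; means are reported separately for presence
#' (y = 1) and absence (y = 0) points, so sparse presences with low
#' estimates yield large positive presence residuals and small negative
#' absence residuals.
#'
#' @param estimates Probability estimates (missing values contribute at the
#'   naive probability).
#' @param y Binary response.
#' @return Tibble with `mean_residual_presence`, `mean_residual_absence`.
#' @export
mean_residuals <- function(estimates, y) {
  check_response(y)
  p <- ifelse(is.na(estimates), mean(y), estimates)
  r <- y - p
  tibble::tibble(
    mean_residual_presence = if (any(y == 1)) mean(r[y == 1]) else NA_real_,
    mean_residual_absence = if (any(y == 0)) mean(r[y == 0]) else NA_real_
  )
}

#' Full evaluation report for a fitted model
#'
#' Scores the model's leave-one-out estimates on its training data: logB,
#' AUC, xR2, per-term sensitivity Q, and mean residuals by class.
#'
#' @param fit An `npmr_fit`.
#' @return One-row tibble (class counts, logB, auc, xr2, residual means)
#'   with a `q` list-column holding the per-term sensitivity tibble.
#' @export
evaluate_npmr <- function(fit) {
  d <- fit$diagnostics
  est <- d$loo_estimates
  y <- fit$data$y
  q <- dplyr::bind_rows(lapply(fit$model$terms$predictor, function(p) {
    sensitivity_q(fit, p)
  }))
  dplyr::bind_cols(
    tibble::tibble(
      n_presence = sum(y == 1), n_absence = sum(y == 0),
      logB = d$logB, auc = npmr_auc(ifelse(is.na(est), d$naive_p, est), y),
      xr2 = cross_r2(est, y)
    ),
    mean_residuals(est, y),
    tibble::tibble(q = list(q))
  )
}

#' Validate a fitted model on an external point set
#'
#' Applies the model (non-leave-one-out, against its training data) to an
#' independent presence-absence sample and scores the predictions with
#' AUC, xR2 and class residual means. Validation ids must be disjoint from
#' the training ids.
#'
#' @param fit An `npmr_fit` whose training data has an `id` column.
#' @param validation Occurrence tibble with `id`, `y` and the model's
#'   predictor columns.
#' @return One-row tibble as [evaluate_npmr()] (without logB/Q, which are
#'   training-data quantities).
#' @export
external_validate <- function(fit, validation) {
  if ("id" %in% names(fit$data) && "id" %in% names(validation) &&
    length(intersect(fit$data$id, validation$id)) > 0) {
    stop("validation ids overlap training ids", call. = FALSE)
  }
  check_response(validation$y)
  if (!any(validation$y == 1) || !any(validation$y == 0)) {
    stop("validation set needs both classes", call. = FALSE)
  }
  est <- predict(fit, newdata = validation)
  p0 <- fit$diagnostics$naive_p
  scored <- ifelse(is.na(est), p0, est)
  dplyr::bind_cols(
    tibble::tibble(
      n_presence = sum(validation$y == 1),
      n_absence = sum(validation$y == 0),
      auc = npmr_auc(scored, validation$y),
      xr2 = cross_r2(scored, validation$y),
      n_unestimable = sum(is.na(est))
    ),
    mean_residuals(scored, validation$y)
  )
}
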