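#' Multiplicative Gaussian kernel weights
#'
#' The weight an observation contributes to a target point is the product
#' over model terms of Gaussian kernels in predictor space,
#' `w = prod_j exp(-(x_j - t_j)^2 / (2 sigma_j^2))`. Weights below 1e-12 are
#' truncated to 0 for numerical stability. A missing predictor value on
#' either side yields `NA` (the observation is excluded from estimation).
#'
#' @param target Matrix (m x k) or vector of target predictor values.
#' @param obs Matrix (n x k) or vector of observation predictor values.
#' @param tolerances Numeric vector of per-term kernel tolerances (sigma),
#'   all > 0, in predictor units.
#' @return An m x n weight matrix.
#' @export
kernel_weight <- function(target, obs, tolerances) {
  if (any(!is.finite(tolerances)) || any(tolerances <= 0)) {
    stop("kernel tolerances must be positive", call. = FALSE)
  }
  target <- rbind(target)
  obs <- rbind(obs)
  stopifnot(ncol(target) == ncol(obs), ncol(obs) == length(tolerances))
  w <- matrix(1, nrow(target), nrow(obs))
  for (j in seq_along(tolerances)) {
    d <- outer(target[, j], obs[, j], `-`)
    w <- w * exp(-d^2 / (2 * tolerances[j]^2))
  }
  w[!is.na(w) & w < 1e-12] <- 0
  w
}

# internal: weight matrix of data against itself for a term set
weights_matrix <- function(data, terms) {
  X <- as.matrix(data[terms$predictor])
  storage.mode(X) <- "double"
  kernel_weight(X, X, terms$tolerance)
}

#' Construct an NPMR model specification
#'
#' @param terms Tibble (or data frame) with columns `predictor` (character)
#'   and `tolerance` (positive kernel sigma in predictor units). May have
#'   zero rows: the empty model is the naive constant model.
#' @param min_avg_neighborhood Minimum average neighborhood size N*, as a
#'   fraction of N (default 0.05).
#' @param min_local_weight Minimum summed kernel weight for a valid local
#'   estimate, in expected-observation equivalents (default 1).
#' @return An object of class `npmr_model`.
#' @export
npmr_model <- function(terms, min_avg_neighborhood = 0.05,
                       min_local_weight = 1) {
  terms <- tibble::as_tibble(terms)
  if (nrow(terms) > 0) {
    stopifnot(
      all(c("predictor", "tolerance") %in% names(terms)),
      !anyDuplicated(terms$predictor),
      all(terms$tolerance > 0)
    )
  }
  stopifnot(min_avg_neighborhood > 0, min_avg_neighborhood < 1)
  structure(
    list(
      terms = terms,
      min_avg_neighborhood = min_avg_neighborhood,
      min_local_weight = min_local_weight
    ),
    class = "npmr_model"
  )
}

#' Naive occurrence model
#'
#' The constant model predicting, for every point, the average frequency of
#' occurrence `sum(y)/N`. It is the baseline of the logB likelihood ratio.
#'
#' @param data Occurrence tibble with binary column `y`.
#' @return A single probability.
#' @export
naive_model <- function(data) {
  check_response(data$y)
  mean(data$y)
}

check_response <- function(y) {
  if (length(y) < 1 || !all(y %in% c(0, 1))) {
    stop("response y must be binary 0/1", call. = FALSE)
  }
  invisible(y)
}

#' Local mean occurrence estimates
#'
#' Kernel-weighted local means `p_hat = sum(w_i y_i) / sum(w_i)`. With
#' `loo = TRUE` each point's own observation is excluded before averaging
#' (leave-one-out / jackknife estimates, the basis of cross-validated model
#' selection). Points whose summed neighborhood weight falls below the
#' model's `min_local_weight` get `NA` (unestimable); estimates are always
#' inside the observed response range.
#'
#' @param data Training occurrence tibble (`y` plus predictor columns).
#' @param model An [npmr_model()].
#' @param newdata Optional tibble of target points; default the training
#'   points themselves.
#' @param loo Exclude each training point from its own neighborhood
#'   (only meaningful when targets are the training points).
#' @return Numeric vector of probabilities (with `NA` for unestimable
#'   points), with attribute `nstar` = average neighborhood size.
#' @export
npmr_estimate <- function(data, model, newdata = NULL, loo = FALSE) {
  check_response(data$y)
  if (nrow(model$terms) == 0) {
    n_out <- if (is.null(newdata)) nrow(data) else nrow(newdata)
    p <- rep(naive_model(data), n_out)
    attr(p, "nstar") <- if (loo) nrow(data) - 1 else nrow(data)
    return(p)
  }
  preds <- model$terms$predictor
  missing_cols <- setdiff(preds, names(data))
  if (length(missing_cols) > 0) {
    stop("missing predictor column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE)
  }
  Xobs <- as.matrix(data[preds])
  storage.mode(Xobs) <- "double"
  if (is.null(newdata)) {
    Xt <- Xobs
  } else {
    Xt <- as.matrix(newdata[preds])
    storage.mode(Xt) <- "double"
  }
  w <- kernel_weight(Xt, Xobs, model$terms$tolerance)
  # excluded observations (missing predictors) carry no weight
  w[is.na(w)] <- 0
  if (loo) {
    stopifnot(is.null(newdata))
    diag(w) <- 0
  }
  sw <- rowSums(w)
  p <- as.numeric(w %*% data$y) / sw
  # local-mean bound: mathematically inside the observed response range,
  # clamp away summation-order ulp noise
  p <- pmin(pmax(p, min(data$y)), max(data$y))
  p[sw < model$min_local_weight] <- NA_real_
  attr(p, "nstar") <- mean(sw)
  p
}

#' Leave-one-out estimates for every training point
#'
#' @inheritParams npmr_estimate
#' @return As [npmr_estimate()] with `loo = TRUE`.
#' @export
loo_estimates <- function(data, model) {
  stopifnot(nrow(data) >= 2)
  npmr_estimate(data, model, loo = TRUE)
}

#' Binary log10 likelihood
#'
#' `sum_i [y_i log10(p_i) + (1 - y_i) log10(1 - p_i)]` with estimates
#' clamped to `[eps, 1 - eps]`. Points with missing estimates contribute at
#' the naive probability, keeping model and naive likelihoods on the same N
#' so logB stays comparable.
#'
#' @param estimates Probability vector (may contain `NA`).
#' @param y Binary response of the same length.
#' @param naive_p Probability substituted for missing estimates.
#' @param eps Clamp bound (default 1e-6).
#' @return log10 likelihood (a non-positive number).
#' @export
log_likelihood_binary <- function(estimates, y, naive_p = mean(y),
                                  eps = 1e-6) {
  if (length(estimates) != length(y)) {
    stop("estimates and y lengths differ", call. = FALSE)
  }
  p <- ifelse(is.na(estimates), naive_p, estimates)
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(y * log10(p) + (1 - y) * log10(1 - p))
}

#' Cross-validated fit statistic logB and diagnostics
#'
#' logB is the log10 likelihood ratio of the model's leave-one-out
#' estimates against the naive constant model; positive values indicate
#' improvement over the naive baseline. Also reports the average
#' neighborhood size N* (mean over points of the summed leave-one-out
#' kernel weights), the per-sample-unit variant `logB_per_n`, and whether
#' the model satisfies its minimum-neighborhood constraint
#' (`N* >= min_avg_neighborhood * N`); infeasible models are excluded from
#' selection.
#'
#' @inheritParams npmr_estimate
#' @return A list of class `npmr_diagnostics`: `loo_estimates`, `logB`,
#'   `logB_per_n`, `loglik_model`, `loglik_naive`, `nstar`,
#'   `n_unestimable`, `feasible`, `naive_p`, `n`.
#' @export
npmr_logB <- function(data, model) {
  n <- nrow(data)
  p0 <- naive_model(data)
  est <- loo_estimates(data, model)
  ll_model <- log_likelihood_binary(est, data$y, naive_p = p0)
  ll_naive <- log_likelihood_binary(rep(p0, n), data$y, naive_p = p0)
  nstar <- attr(est, "nstar")
  structure(
    list(
      loo_estimates = as.numeric(est),
      logB = ll_model - ll_naive,
      logB_per_n = (ll_model - ll_naive) / n,
      loglik_model = ll_model,
      loglik_naive = ll_naive,
      nstar = nstar,
      n_unestimable = sum(is.na(est)),
      feasible = nstar >= model$min_avg_neighborhood * n,
      naive_p = p0,
      n = n
    ),
    class = "npmr_diagnostics"
  )
}

#' Fit an NPMR model with fixed terms
#'
#' Binds a model specification to a training dataset and computes its
#' cross-validated diagnostics. Use [free_search()] to choose the terms and
#' tolerances themselves.
#'
#' @param data Occurrence tibble: `id` (unique), `y` (0/1, both classes
#'   present for a meaningful fit) and predictor columns.
#' @param terms Term tibble as for [npmr_model()].
#' @param ... Passed to [npmr_model()].
#' @return Object of class `npmr_fit`: the model, the training data, and
#'   diagnostics.
#' @export
npmr_fit <- function(data, terms, ...) {
  model <- npmr_model(terms, ...)
  if ("id" %in% names(data) && anyDuplicated(data$id)) {
    stop("duplicate point ids", call. = FALSE)
  }
  diag <- npmr_logB(data, model)
  structure(
    list(model = model, data = data, diagnostics = diag),
    class = "npmr_fit"
  )
}

#' @export
print.npmr_fit <- function(x, ...) {
  cat("NPMR fit (local mean, Gaussian kernels)\n")
  n1 <- sum(x$data$y == 1)
  cat(sprintf(
    "  n = %d (%d presence / %d absence), naive p = %.4g\n",
    x$diagnostics$n, n1, x$diagnostics$n - n1, x$diagnostics$naive_p
  ))
  if (nrow(x$model$terms) == 0) {
    cat("  empty model (naive constant)\n")
  } else {
    for (i in seq_len(nrow(x$model$terms))) {
      cat(sprintf(
        "  %-14s tolerance = %.6g\n",
        x$model$terms$predictor[i], x$model$terms$tolerance[i]
      ))
    }
  }
  cat(sprintf(
    "  logB = %.4g   N* = %.3g   unestimable = %d\n",
    x$diagnostics$logB, x$diagnostics$nstar, x$diagnostics$n_unestimable
  ))
  invisible(x)
}

#' Predict occurrence probabilities from a fitted NPMR model
#'
#' Non-leave-one-out local mean estimates against the full training data.
#'
#' @param object An `npmr_fit`.
#' @param newdata Tibble with the model's predictor columns; default the
#'   training points.
#' @param ... Unused.
#' @return Numeric vector of probabilities (`NA` where the neighborhood is
#'   insufficient).
#' @export
predict.npmr_fit <- function(object, newdata = NULL, ...) {
  as.numeric(npmr_estimate(object$data, object$model, newdata = newdata))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the terms of an NPMR fit
#'
#' @param x An `npmr_fit`.
#' @param ... Unused.
#' @return Tibble with `predictor`, `tolerance` and `tolerance_frac`
#'   (tolerance as a fraction of the predictor's observed training range).
#' @method tidy npmr_fit
#' @export
tidy.npmr_fit <- function(x, ...) {
  t <- x$model$terms
  if (nrow(t) == 0) {
    return(tibble::tibble(
      predictor = character(), tolerance = numeric(),
      tolerance_frac = numeric()
    ))
  }
  rng <- vapply(t$predictor, function(p) diff(range(x$data[[p]], na.rm = TRUE)),
    numeric(1))
  tibble::tibble(
    predictor = t$predictor,
    tolerance = t$tolerance,
    tolerance_frac = t$tolerance / rng
  )
}

#' One-row summary of an NPMR fit
#'
#' @param x An `npmr_fit`.
#' @param ... Unused.
#' @return Tibble with n, class counts, naive p, logB, logB_per_n,
#'   log-likelihoods, N*, unestimable count and feasibility.
#' @method glance npmr_fit
#' @export
glance.npmr_fit <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(
    n = d$n,
    n_presence = sum(x$data$y == 1),
    n_absence = sum(x$data$y == 0),
    n_terms = nrow(x$model$terms),
    naive_p = d$naive_p,
    logB = d$logB,
    logB_per_n = d$logB_per_n,
    loglik_model = d$loglik_model,
    loglik_naive = d$loglik_naive,
    nstar = d$nstar,
    n_unestimable = d$n_unestimable,
    feasible = d$feasible
  )
}

#' Plot leave-one-out estimates of an NPMR fit by response class
#'
#' @param object An `npmr_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot npmr_fit
#' @export
autoplot.npmr_fit <- function(object, ...) {
  df <- tibble::tibble(
    class = factor(ifelse(object$data$y == 1, "presence", "absence"),
      levels = c("absence", "presence")),
    estimate = object$diagnostics$loo_estimates
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$estimate)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3) +
    ggplot2::geom_hline(
      yintercept = object$diagnostics$naive_p, linetype = "dashed"
    ) +
    ggplot2::labs(
      y = "leave-one-out estimated probability", x = NULL,
      caption = "dashed line: naive occurrence frequency"
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
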