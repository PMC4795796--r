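#' Map occurrence probabilities over predictor grids
#'
#' Evaluates a fitted NPMR model at every grid cell (non-leave-one-out
#' local mean against the full training data). Cells missing any model
#' predictor, or whose summed neighborhood weight is below the model's
#' minimum, become NODATA (`NA`). By the local-mean bound no cell can
#' exceed the largest training estimate.
#'
#' @param fit An `npmr_fit`.
#' @param grid Tidy cell table with `lon`, `lat` and a column for every
#'   model predictor (e.g. the output of [derive_predictors()] on climate
#'   grids).
#' @return Tibble `lon`, `lat`, `prob` of class `npmr_prob_grid`, carrying
#'   the input's `grid_meta` attribute if present.
#' @export
predict_grid <- function(fit, grid) {
  preds <- fit$model$terms$predictor
  missing_cols <- setdiff(preds, names(grid))
  if (length(missing_cols) > 0) {
    stop("predictor grid(s) missing: ", paste(missing_cols, collapse = ", "),
      call. = FALSE)
  }
  prob <- rep(NA_real_, nrow(grid))
  ok <- if (length(preds) > 0) {
    stats::complete.cases(grid[preds])
  } else {
    rep(TRUE, nrow(grid))
  }
  if (any(ok)) {
    prob[ok] <- predict(fit, newdata = grid[ok, , drop = FALSE])
  }
  out <- tibble::tibble(lon = grid$lon, lat = grid$lat, prob = prob)
  attr(out, "grid_meta") <- attr(grid, "grid_meta")
  class(out) <- c("npmr_prob_grid", class(out))
  out
}

#' Apply a lower display threshold to a probability grid
#'
#' Cells with probability below `floor` become NODATA; all others pass
#' through unchanged. Used to trim low-probability fringe when matching
#' mapped output to known population distributions (the published maps use
#' a floor of 0.135).
#'
#' @param prob_grid Output of [predict_grid()].
#' @param floor Threshold in \[0, 1\].
#' @return The thresholded grid.
#' @export
apply_display_floor <- function(prob_grid, floor) {
  stopifnot(floor >= 0, floor <= 1)
  prob_grid$prob[!is.na(prob_grid$prob) & prob_grid$prob < floor] <- NA_real_
  prob_grid
}

#' Single-predictor response curve
#'
#' Fits a fresh one-term NPMR model on the named predictor (tolerance
#' chosen by [free_search()] restricted to that predictor) and evaluates
#' it over a grid of predictor values, giving the estimated
#' probability-of-occurrence profile along that single climate axis.
#' Alternatively (`partial = TRUE`) evaluates an existing multi-term fit
#' along the predictor with all other terms held at their training means.
#'
#' @param data Occurrence tibble (ignored when `partial = TRUE` and `fit`
#'   given).
#' @param predictor Predictor column name.
#' @param n_grid Number of evenly spaced evaluation values across the
#'   predictor's observed range (default 200).
#' @param partial Evaluate `fit` marginally instead of refitting one term.
#' @param fit Existing `npmr_fit` (required when `partial = TRUE`).
#' @param ... Passed to [free_search()] in refit mode.
#' @return Tibble `value`, `prob` of class `npmr_curve`; attribute
#'   `tolerance` gives the selected one-term tolerance in refit mode.
#' @export
response_curve <- function(data, predictor, n_grid = 200, partial = FALSE,
                           fit = NULL, ...) {
  if (partial) {
    stopifnot(inherits(fit, "npmr_fit"))
    data <- fit$data
  }
  if (!predictor %in% names(data)) {
    stop("unknown predictor: ", predictor, call. = FALSE)
  }
  rng <- range(data[[predictor]], na.rm = TRUE)
  if (diff(rng) == 0) stop("predictor has zero range", call. = FALSE)
  values <- seq(rng[1], rng[2], length.out = n_grid)
  if (partial) {
    nd <- tibble::as_tibble(lapply(
      stats::setNames(fit$model$terms$predictor, fit$model$terms$predictor),
      function(p) rep(mean(data[[p]], na.rm = TRUE), n_grid)
    ))
    nd[[predictor]] <- values
    prob <- predict(fit, newdata = nd)
    tol <- fit$model$terms$tolerance[fit$model$terms$predictor == predictor]
  } else {
    search <- free_search(data, predictor, ...)
    if (nrow(search$fit$model$terms) == 0) {
      # no tolerance beats the naive model: flat curve at the naive p
      prob <- rep(naive_model(data), n_grid)
      tol <- NA_real_
    } else {
      nd <- tibble::tibble(!!predictor := values)
      prob <- predict(search$fit, newdata = nd)
      tol <- search$fit$model$terms$tolerance[1]
    }
  }
  out <- tibble::tibble(value = values, prob = prob)
  attr(out, "predictor") <- predictor
  attr(out, "tolerance") <- tol
  class(out) <- c("npmr_curve", class(out))
  out
}

#' Classify a probability grid into equal-interval bins
#'
#' Bins span `[0, max probability]` in `n_bins` equal intervals (the
#' convention of the published category maps, which report the maximum
#' value alongside).
#'
#' @param prob_grid Output of [predict_grid()].
#' @param n_bins Number of bins (default 10).
#' @return The grid with an integer `bin` column (1 = lowest); attribute
#'   `max_prob` records the maximum used.
#' @export
bin_probabilities <- function(prob_grid, n_bins = 10) {
  stopifnot(n_bins >= 1)
  pmax_val <- max(prob_grid$prob, na.rm = TRUE)
  breaks <- seq(0, pmax_val, length.out = n_bins + 1)
  bin <- findInterval(prob_grid$prob, breaks, rightmost.closed = TRUE,
    all.inside = TRUE)
  prob_grid$bin <- as.integer(bin)
  attr(prob_grid, "max_prob") <- pmax_val
  prob_grid
}

#' Plot a probability-of-occurrence grid
#'
#' @param object An `npmr_prob_grid`.
#' @param ... Unused.
#' @return A ggplot raster map.
#' @method autoplot npmr_prob_grid
#' @export
autoplot.npmr_prob_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lon, .data$lat,
    fill = .data$prob)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90",
      limits = c(0, NA), name = "P(occurrence)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "longitude", y = "latitude")
}

#' Plot a single-predictor response curve
#'
#' @param object An `npmr_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot npmr_curve
#' @export
autoplot.npmr_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$value, .data$prob)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = attr(object, "predictor") %||% "predictor value",
      y = "estimated P(occurrence)"
    ) +
    ggplot2::ylim(0, NA)
}

#' @importFrom rlang %||%
NULL
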