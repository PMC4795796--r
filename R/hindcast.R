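#' Substitute one model term with another predictor
#'
#' Removes a term (typically elevation, whose relationship with climate is
#' not stable across glacial cycles) and adds a replacement predictor whose
#' tolerance is re-optimized by grid search while all retained tolerances
#' stay fixed. The refitted model's contemporary diagnostics come back with
#' it, so the substitution can be revalidated before projecting onto
#' paleoclimate grids.
#'
#' @param fit An `npmr_fit` containing `remove` among its terms.
#' @param remove Name of the term to delete (e.g. `"ELEV"`).
#' @param replacement Name of the replacement predictor; must be a column
#'   of the training data (and derivable from paleoclimate normals, e.g.
#'   `"MTWM"` or `"BIO4"`).
#' @param tol_grid Tolerance grid as fractions of the replacement's
#'   observed range.
#' @return A new `npmr_fit` with the substituted term.
#' @export
substitute_predictor <- function(fit, remove, replacement,
                                 tol_grid = seq(0.05, 1, by = 0.05)) {
  terms <- fit$model$terms
  if (!remove %in% terms$predictor) {
    stop("term to remove not in model: ", remove, call. = FALSE)
  }
  data <- fit$data
  if (!replacement %in% names(data)) {
    stop("replacement predictor not in data: ", replacement, call. = FALSE)
  }
  kept <- terms[terms$predictor != remove, , drop = FALSE]
  rng <- diff(range(data[[replacement]], na.rm = TRUE))
  if (rng == 0) stop("replacement predictor has zero range", call. = FALSE)
  best <- NULL
  for (frac in tol_grid) {
    cand <- dplyr::bind_rows(kept, tibble::tibble(
      predictor = replacement, tolerance = frac * rng
    ))
    f <- npmr_fit(data, cand,
      min_avg_neighborhood = fit$model$min_avg_neighborhood,
      min_local_weight = fit$model$min_local_weight
    )
    if (f$diagnostics$feasible &&
      (is.null(best) || f$diagnostics$logB > best$diagnostics$logB + 1e-12)) {
      best <- f
    }
  }
  if (is.null(best)) {
    stop("no feasible tolerance found for ", replacement, call. = FALSE)
  }
  best
}

#' Append extra absence locations to an occurrence dataset
#'
#' Used to extend the absence sample into regions whose contemporary
#' climate resembles in-range glacial climate (e.g. the eastern Great
#' Plains block added before hindcasting the Rocky Mountain variety).
#' The naive occurrence probability is implicitly recomputed by any
#' subsequent fit.
#'
#' @param data Occurrence tibble with `id`, `y`.
#' @param extra_points Tibble of absence points (`y` must be 0 if present)
#'   with `id` disjoint from `data`.
#' @return The concatenated tibble.
#' @export
augment_absences <- function(data, extra_points) {
  if (nrow(extra_points) == 0) return(data)
  if ("y" %in% names(extra_points)) {
    stopifnot(all(extra_points$y == 0))
  } else {
    extra_points$y <- 0L
  }
  if ("id" %in% names(data) && "id" %in% names(extra_points) &&
    length(intersect(data$id, extra_points$id)) > 0) {
    stop("id collision between data and extra points", call. = FALSE)
  }
  dplyr::bind_rows(data, extra_points)
}

#' Project a model onto paleoclimate predictor grids
#'
#' Applies [predict_grid()] with identical estimator semantics to
#' (typically coarser) paleoclimate grids: the model remains fitted on
#' contemporary climate, and only the cell predictor values change. The
#' output is a pure function of (model, training data, grids).
#'
#' @param fit An `npmr_fit` (after any [substitute_predictor()] /
#'   [augment_absences()] steps).
#' @param paleo_grid Tidy cell table with all model predictors derived
#'   from the paleoclimate normals.
#' @return An `npmr_prob_grid`.
#' @export
project_lgm <- function(fit, paleo_grid) {
  predict_grid(fit, paleo_grid)
}
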