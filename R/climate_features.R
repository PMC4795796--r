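#' @importFrom rlang := .data
#' @importFrom tibble tibble
NULL

# month lengths of a 365-day climatological year and mid-month Julian days
MONTH_DAYS <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
MONTH_MID <- cumsum(MONTH_DAYS) - MONTH_DAYS / 2
MONTH_END <- cumsum(MONTH_DAYS)
MONTH_START <- MONTH_END - MONTH_DAYS

month_cols <- function(prefix) sprintf("%s_%02d", prefix, 1:12)

#' Derive bioclimatic predictors from monthly climate normals
#'
#' Computes the candidate predictor set used for climate niche modelling
#' from 12 monthly mean temperatures (`tmean_01..tmean_12`, deg C), monthly
#' precipitation totals (`prec_01..prec_12`, mm), optional monthly minimum
#' temperatures (`tmin_01..tmin_12`, deg C), elevation (`elev`, m) and a
#' topographic ruggedness index (`tri`). Derived columns:
#'
#' * `LogMAP`, `LogGSP` -- log10 of annual and growing-season (Apr-Sep)
#'   precipitation (mm)
#' * `MTCM`, `MTWM` -- mean temperature of the coldest / warmest month
#' * `SUMP` (Jul-Aug), `WINP` (Nov-Feb) -- seasonal precipitation (mm)
#' * `DD5`, `GSDD5`, `MMINDD0` -- degree-day sums (see
#'   [derive_degree_days()])
#' * `SDAY` -- Julian day of the last spring freeze (see [derive_sday()])
#' * `PRATIO` = GSP/MAP; `SMRPB` = (Jul+Aug+Sep)/(Apr+May+Jun) precipitation
#' * `SDI` = sqrt(GSDD5)/GSP; `SHMI` = MTWM/log10(Jul-Sep precipitation)
#' * `TDIFF_LogGSP` = (MTWM - MTCM)/LogGSP
#' * `ELEV`, `TRI` copied from `elev`/`tri`; `TRIX` (see [compute_trix()])
#'
#' Ratios or logs whose denominator/argument is non-positive are flagged
#' missing (`NA`) with a warning; infinities are never emitted. Arguments of
#' SHMI's log below 1 mm are floored at 1.0001 mm to keep the index finite.
#' Degree-day and freeze-date columns already present in `cells` are kept
#' (pre-computed surfaces take precedence) unless `recompute = TRUE`.
#'
#' @param cells Tibble with the monthly normal columns described above plus
#'   optionally `elev`, `tri`, `lon`, `lat`.
#' @param study_bounds Numeric `c(west, east)` longitude extent used by the
#'   TRIX longitude rescale; default the range of `cells$lon`.
#' @param recompute If `TRUE`, recompute DD5/GSDD5/MMINDD0/SDAY even when
#'   already present.
#' @return `cells` with predictor columns appended.
#' @export
derive_predictors <- function(cells, study_bounds = NULL, recompute = FALSE) {
  tmean <- as.matrix(cells[month_cols("tmean")])
  prec <- as.matrix(cells[month_cols("prec")])
  if (any(prec < 0, na.rm = TRUE)) stop("negative monthly precipitation", call. = FALSE)
  has_tmin <- all(month_cols("tmin") %in% names(cells))
  tmin <- if (has_tmin) as.matrix(cells[month_cols("tmin")]) else NULL

  map <- rowSums(prec)
  gsp <- rowSums(prec[, 4:9, drop = FALSE])
  sump <- rowSums(prec[, 7:8, drop = FALSE])
  winp <- rowSums(prec[, c(11, 12, 1, 2), drop = FALSE])
  prec_jas <- rowSums(prec[, 7:9, drop = FALSE])
  prec_amj <- rowSums(prec[, 4:6, drop = FALSE])
  mtcm <- apply(tmean, 1, min)
  mtwm <- apply(tmean, 1, max)

  log_pos <- function(x, what) {
    bad <- !is.na(x) & x <= 0
    if (any(bad)) {
      warning(sum(bad), " cell(s) with non-positive ", what,
        "; flagged missing", call. = FALSE)
    }
    ifelse(x > 0, log10(x), NA_real_)
  }
  ratio_pos <- function(num, den, what) {
    bad <- !is.na(den) & den <= 0
    if (any(bad)) {
      warning(sum(bad), " cell(s) with non-positive ", what,
        " denominator; flagged missing", call. = FALSE)
    }
    ifelse(den > 0, num / den, NA_real_)
  }

  out <- cells
  need_dd <- recompute ||
    !all(c("DD5", "GSDD5", "MMINDD0", "SDAY") %in% names(cells))
  if (need_dd) {
    dd <- derive_degree_days(cells)
    sday <- derive_sday(cells)
    out$DD5 <- dd$DD5
    out$MMINDD0 <- dd$MMINDD0
    out$SDAY <- sday
    out$GSDD5 <- derive_gsdd5(tmean, tmin, sday)
  }

  out$LogMAP <- log_pos(map, "annual precipitation")
  out$LogGSP <- log_pos(gsp, "growing-season precipitation")
  out$MTCM <- mtcm
  out$MTWM <- mtwm
  out$SUMP <- sump
  out$WINP <- winp
  out$PRATIO <- ratio_pos(gsp, map, "PRATIO")
  out$SMRPB <- ratio_pos(prec_jas, prec_amj, "SMRPB")
  out$SDI <- ratio_pos(sqrt(pmax(out$GSDD5, 0)), gsp, "SDI")
  out$SHMI <- mtwm / log10(pmax(prec_jas, 1.0001))
  # TDIFF/LogGSP: undefined where GSP <= 1 mm (LogGSP <= 0)
  out$TDIFF_LogGSP <- ifelse(!is.na(out$LogGSP) & out$LogGSP > 0,
    (mtwm - mtcm) / out$LogGSP, NA_real_)
  if ("elev" %in% names(cells)) out$ELEV <- cells$elev
  if ("tri" %in% names(cells)) {
    out$TRI <- cells$tri
    if ("lon" %in% names(cells)) {
      if (is.null(study_bounds)) study_bounds <- range(cells$lon)
      if (diff(study_bounds) > 0) {
        out$TRIX <- compute_trix(cells$tri, cells$lon, study_bounds)
      } else {
        # a single longitude gives no extent to rescale over
        out$TRIX <- NA_real_
      }
    }
  }
  out
}

#' Degree-day sums from monthly normals
#'
#' Month-length accumulation: `DD5 = sum_m days_m * max(0, tmean_m - 5)` and
#' `MMINDD0 = sum_m days_m * max(0, -tmin_m)`. These approximate the
#' pre-computed degree-day surfaces the source climate products distribute;
#' supply those directly (columns `DD5`/`MMINDD0`) when available.
#'
#' @param cells Tibble with `tmean_01..12` and optionally `tmin_01..12`.
#' @return Tibble with columns `DD5` and `MMINDD0` (`NA` when tmin absent).
#' @export
derive_degree_days <- function(cells) {
  tmean <- as.matrix(cells[month_cols("tmean")])
  dd5 <- as.numeric(pmax(tmean - 5, 0) %*% MONTH_DAYS)
  if (all(month_cols("tmin") %in% names(cells))) {
    tmin <- as.matrix(cells[month_cols("tmin")])
    mmindd0 <- as.numeric(pmax(-tmin, 0) %*% MONTH_DAYS)
  } else {
    mmindd0 <- rep(NA_real_, nrow(cells))
  }
  tibble(DD5 = dd5, MMINDD0 = mmindd0)
}

# continuous Julian day where daily tmin (linear between mid-month anchors)
# last crosses 0 upward within anchors [from, to]; NA if never crosses
last_upcross <- function(tmin, from, to) {
  cross <- NA_real_
  for (m in from:(to - 1)) {
    a <- tmin[m]; b <- tmin[m + 1]
    if (!is.na(a) && !is.na(b) && a < 0 && b >= 0) {
      cross <- MONTH_MID[m] + (0 - a) / (b - a) * (MONTH_MID[m + 1] - MONTH_MID[m])
    }
  }
  cross
}

#' Julian day of the last spring freeze
#'
#' Daily minimum temperatures are approximated by linear interpolation of
#' the monthly `tmin` normals anchored at mid-month. `SDAY` is the Julian
#' day (floor of the continuous crossing) on which the interpolated daily
#' minimum last rises through 0 deg C during January-July. If `tmin` never
#' drops below 0, `SDAY = 1` (no spring freeze); if it stays below 0 through
#' all of January-July, `SDAY` is flagged missing.
#'
#' @param cells Tibble with `tmin_01..12`.
#' @return Numeric vector of Julian days.
#' @export
derive_sday <- function(cells) {
  if (!all(month_cols("tmin") %in% names(cells))) {
    return(rep(NA_real_, nrow(cells)))
  }
  tmin <- as.matrix(cells[month_cols("tmin")])
  vapply(seq_len(nrow(tmin)), function(i) {
    tm <- tmin[i, ]
    if (anyNA(tm)) return(NA_real_)
    spring <- tm[1:7]
    if (all(spring >= 0)) return(1)
    if (all(spring < 0)) return(NA_real_)
    # freezes that persist past July leave no spring crossing: flagged NA
    floor(last_upcross(tm, 1L, 7L))
  }, numeric(1))
}

# GSDD5: degree-days > 5 accumulated over the frost-free window
# [SDAY, first autumn freeze), monthly terms prorated by the fraction of
# each month inside the window
derive_gsdd5 <- function(tmean, tmin, sday) {
  n <- nrow(tmean)
  if (is.null(tmin)) return(rep(NA_real_, n))
  vapply(seq_len(n), function(i) {
    s <- sday[i]
    if (is.na(s)) return(NA_real_)
    tm <- tmin[i, ]
    # first autumn downward crossing of 0 after mid-July; else year end
    fday <- 365
    for (m in 7:11) {
      a <- tm[m]; b <- tm[m + 1]
      if (!is.na(a) && !is.na(b) && a >= 0 && b < 0) {
        fday <- MONTH_MID[m] + (a - 0) / (a - b) * (MONTH_MID[m + 1] - MONTH_MID[m])
        break
      }
    }
    if (fday <= s) return(0)
    frac_overlap <- pmax(0, pmin(MONTH_END, fday) - pmax(MONTH_START, s)) / MONTH_DAYS
    sum(frac_overlap * MONTH_DAYS * pmax(tmean[i, ] - 5, 0))
  }, numeric(1))
}

#' Longitude-weighted topographic ruggedness (TRIX)
#'
#' Multiplies the ruggedness index by a "converted longitude" factor that
#' rescales longitude linearly to \[1, 2\] across the study extent, west to
#' east, so equal ruggedness scores higher toward the eastern range margin.
#' Longitudes outside the extent are clamped to its bounds with a warning.
#'
#' @param tri Non-negative ruggedness index.
#' @param lon Longitude, decimal degrees.
#' @param study_bounds `c(west, east)` extent of the longitude rescale.
#' @return `tri * (1 + (lon - west)/(east - west))`.
#' @export
compute_trix <- function(tri, lon, study_bounds) {
  stopifnot(length(study_bounds) == 2, study_bounds[2] > study_bounds[1])
  if (any(tri < 0, na.rm = TRUE)) stop("tri must be non-negative", call. = FALSE)
  out_of_range <- !is.na(lon) & (lon < study_bounds[1] | lon > study_bounds[2])
  if (any(out_of_range)) {
    warning(sum(out_of_range), " longitude(s) outside study bounds clamped",
      call. = FALSE)
    lon <- pmin(pmax(lon, study_bounds[1]), study_bounds[2])
  }
  scaling <- 1 + (lon - study_bounds[1]) / diff(study_bounds)
  tri * scaling
}

#' Temperature seasonality (bio4 convention)
#'
#' Standard deviation of the 12 monthly mean temperatures multiplied by 100,
#' using the population form (divide by 12). Set `sample_sd = TRUE` for the
#' n-1 variant.
#'
#' @param cells Tibble with `tmean_01..12`.
#' @param sample_sd Use the sample (n-1) standard deviation instead.
#' @return Numeric vector.
#' @export
temperature_seasonality <- function(cells, sample_sd = FALSE) {
  tmean <- as.matrix(cells[month_cols("tmean")])
  vapply(seq_len(nrow(tmean)), function(i) {
    x <- tmean[i, ]
    mu <- mean(x)
    v <- sum((x - mu)^2) / (if (sample_sd) 11 else 12)
    100 * sqrt(v)
  }, numeric(1))
}
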