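#' Read an ESRI ASCII grid into a tidy cell table
#'
#' Parses the six-line ESRI ASCII (`.asc`) header and the row-major value
#' matrix that follows, returning one row per cell with cell-center
#' coordinates. `NODATA` cells are kept with `NA` values so that a
#' write/read round trip preserves the full grid.
#'
#' @param path Path to a `.asc` file.
#' @param value Name for the value column (default `"value"`).
#' @return A tibble with columns `lon`, `lat` and the value column, carrying
#'   a `grid_meta` attribute (ncols, nrows, xll, yll, cellsize, nodata).
#'   Registration is cell-center, CRS is assumed geographic WGS84.
#' @export
read_ascii_grid <- function(path, value = "value") {
  lines <- readLines(path, n = 6L)
  kv <- strsplit(trimws(lines), "\\s+")
  hdr <- stats::setNames(
    vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
    tolower(vapply(kv, `[[`, character(1), 1))
  )
  n_hdr <- sum(names(hdr) %in%
    c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter", "yllcenter",
      "cellsize", "nodata_value"))
  vals <- scan(path, what = numeric(), skip = n_hdr, quiet = TRUE)
  ncols <- as.integer(hdr[["ncols"]])
  nrows <- as.integer(hdr[["nrows"]])
  stopifnot(length(vals) == ncols * nrows)
  cs <- hdr[["cellsize"]]
  xll <- if ("xllcorner" %in% names(hdr)) hdr[["xllcorner"]] else hdr[["xllcenter"]] - cs / 2
  yll <- if ("yllcorner" %in% names(hdr)) hdr[["yllcorner"]] else hdr[["yllcenter"]] - cs / 2
  nodata <- if ("nodata_value" %in% names(hdr)) hdr[["nodata_value"]] else -9999
  vals[vals == nodata] <- NA_real_
  # file order is top row first
  out <- tibble::tibble(
    lon = rep(xll + (seq_len(ncols) - 0.5) * cs, times = nrows),
    lat = rep(yll + (nrows:1 - 0.5) * cs, each = ncols),
    !!value := vals
  )
  attr(out, "grid_meta") <- list(
    ncols = ncols, nrows = nrows, xll = xll, yll = yll,
    cellsize = cs, nodata = nodata
  )
  out
}

#' Write one column of a tidy cell table as an ESRI ASCII grid
#'
#' The inverse of [read_ascii_grid()]. The table must cover a complete
#' regular lon/lat lattice (NA cells allowed; written as `NODATA`).
#'
#' @param grid Tibble with `lon`, `lat` and the value column.
#' @param path Output path.
#' @param value Column to write.
#' @param nodata NODATA sentinel (default -9999).
#' @param digits Significant digits for values (default 6).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, value = "value", nodata = -9999,
                             digits = 6) {
  lons <- sort(unique(grid$lon))
  lats <- sort(unique(grid$lat))
  cs_x <- if (length(lons) > 1) min(diff(lons)) else 1
  cs_y <- if (length(lats) > 1) min(diff(lats)) else cs_x
  if (abs(cs_x - cs_y) > 1e-9 * max(cs_x, cs_y)) {
    stop("grid cells are not square; cannot write ESRI ASCII", call. = FALSE)
  }
  ncols <- length(lons)
  nrows <- length(lats)
  if (nrow(grid) != ncols * nrows) {
    stop("grid does not cover a complete regular lattice", call. = FALSE)
  }
  m <- matrix(nodata, nrow = nrows, ncol = ncols)
  ci <- match(grid$lon, lons)
  ri <- nrows + 1L - match(grid$lat, lats) # top row first
  v <- grid[[value]]
  v <- ifelse(is.na(v), nodata, signif(v, digits))
  m[cbind(ri, ci)] <- v
  hdr <- c(
    sprintf("ncols         %d", ncols),
    sprintf("nrows         %d", nrows),
    sprintf("xllcorner     %.10g", lons[1] - cs_x / 2),
    sprintf("yllcorner     %.10g", lats[1] - cs_y / 2),
    sprintf("cellsize      %.10g", cs_x),
    sprintf("NODATA_value  %d", as.integer(nodata))
  )
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Attach grid-cell values to points by nearest-cell lookup
#'
#' Each point is assigned the value of the grid cell whose center is
#' nearest in lon/lat. Points that land on cells where any requested
#' column is `NA` (NODATA) are dropped with a message reporting the count.
#'
#' @param points Tibble with `lon`, `lat`.
#' @param grid Tidy cell table (one row per cell) with `lon`, `lat` and
#'   value columns; must be a regular lattice.
#' @param cols Character vector of grid columns to extract; default all
#'   non-coordinate columns.
#' @return `points` with the extracted columns appended.
#' @export
extract_at_points <- function(points, grid, cols = NULL) {
  if (is.null(cols)) cols <- setdiff(names(grid), c("lon", "lat"))
  lons <- sort(unique(grid$lon))
  lats <- sort(unique(grid$lat))
  ci <- findInterval(points$lon, c(-Inf, lons[-1] - diff(lons) / 2))
  ri <- findInterval(points$lat, c(-Inf, lats[-1] - diff(lats) / 2))
  key <- paste(lons[ci], lats[ri])
  idx <- match(key, paste(grid$lon, grid$lat))
  vals <- grid[idx, cols, drop = FALSE]
  keep <- stats::complete.cases(vals)
  if (any(!keep)) {
    message(sum(!keep), " point(s) on NODATA or off-grid cells dropped")
  }
  dplyr::bind_cols(points[keep, , drop = FALSE], vals[keep, , drop = FALSE])
}
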