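# great-circle distance in km, haversine on a 6371 km sphere
dist_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
    r = 6371) # km
}

# all-new-vs-kept minimum distance check used by the greedy samplers
min_dist_to_set <- function(lon, lat, set_lon, set_lat) {
  if (length(set_lon) == 0) return(Inf)
  min(dist_km(lon, lat, set_lon, set_lat))
}

#' Randomly place background points with a minimum separation
#'
#' Draws uniform random points on the non-NODATA cells of a mask grid
#' (uniform within each selected cell), accepting a point only if it lies
#' at least `min_sep` km (great-circle) from every point already accepted.
#' Errors, reporting the achieved count, if `n` points cannot be placed
#' within the retry budget.
#'
#' @param mask Tidy cell table (`lon`, `lat`, one value column); cells with
#'   `NA` in the value column are excluded.
#' @param n Number of points.
#' @param min_sep Minimum pairwise separation in km (default 1).
#' @param seed Integer seed; the draw is a pure function of (mask, n,
#'   min_sep, seed).
#' @param max_tries Retry budget as a multiple of `n` (default 200).
#' @return Tibble with `id`, `lon`, `lat`.
#' @export
sample_background <- function(mask, n, min_sep = 1, seed,
                              max_tries = 200) {
  stopifnot(min_sep > 0, n >= 1)
  value_col <- setdiff(names(mask), c("lon", "lat"))[1]
  cells <- mask[!is.na(mask[[value_col]]), c("lon", "lat")]
  if (nrow(cells) == 0) stop("mask has no usable cells", call. = FALSE)
  lons <- sort(unique(mask$lon))
  cs <- if (length(lons) > 1) min(diff(lons)) else 0
  withr::with_seed(seed, {
    kept_lon <- numeric(0)
    kept_lat <- numeric(0)
    tries <- 0L
    while (length(kept_lon) < n && tries < max_tries * n) {
      tries <- tries + 1L
      i <- sample.int(nrow(cells), 1)
      lon <- cells$lon[i] + stats::runif(1, -cs / 2, cs / 2)
      lat <- cells$lat[i] + stats::runif(1, -cs / 2, cs / 2)
      if (min_dist_to_set(lon, lat, kept_lon, kept_lat) >= min_sep) {
        kept_lon <- c(kept_lon, lon)
        kept_lat <- c(kept_lat, lat)
      }
    }
    if (length(kept_lon) < n) {
      stop("could only place ", length(kept_lon), " of ", n,
        " points at min_sep = ", min_sep, " km", call. = FALSE)
    }
    tibble::tibble(id = seq_len(n), lon = kept_lon, lat = kept_lat)
  })
}

#' Label points by agreement of two binary masks
#'
#' A point is a presence only when both vegetation masks are positive at
#' its cell, an absence only when both are non-positive; points where the
#' masks disagree are dropped with a message. This mirrors building a
#' presence/absence response from two independently mapped distribution
#' products.
#'
#' @param points Tibble with `lon`, `lat`.
#' @param species_mask,secondary_mask Tidy cell tables with one 0/1 value
#'   column each; must share the same lattice.
#' @return `points` with a `y` column; disagreeing points removed.
#' @export
label_by_mask_agreement <- function(points, species_mask, secondary_mask) {
  if (nrow(species_mask) != nrow(secondary_mask) ||
    !isTRUE(all.equal(species_mask$lon, secondary_mask$lon)) ||
    !isTRUE(all.equal(species_mask$lat, secondary_mask$lat))) {
    stop("masks are not aligned", call. = FALSE)
  }
  v1 <- setdiff(names(species_mask), c("lon", "lat"))[1]
  v2 <- setdiff(names(secondary_mask), c("lon", "lat"))[1]
  a <- extract_at_points(points, species_mask, v1)
  names(a)[names(a) == v1] <- "m1"
  a <- extract_at_points(a, secondary_mask, v2)
  names(a)[names(a) == v2] <- "m2"
  agree_pres <- a$m1 > 0 & a$m2 > 0
  agree_abs <- a$m1 <= 0 & a$m2 <= 0
  dropped <- sum(!(agree_pres | agree_abs))
  if (dropped > 0) message(dropped, " point(s) with mask disagreement dropped")
  out <- a[agree_pres | agree_abs, , drop = FALSE]
  out$y <- as.integer(out$m1 > 0)
  out$m1 <- out$m2 <- NULL
  out
}

# haplotype -> variety alignment: 1,5,8,9,10 are Pacific (P), the rest
# Rocky Mountain (S)
HAPLOTYPE_VARIETY <- c(
  `1` = "P", `2` = "S", `3` = "S", `4` = "S", `5` = "P",
  `6` = "S", `7` = "S", `8` = "P", `9` = "P", `10` = "P"
)

#' Assign a variety to each presence by nearest haplotype sample
#'
#' Each presence point is labeled with the variety (`"P"` Pacific or `"S"`
#' Rocky Mountain) of its nearest sampled haplotype location
#' (great-circle), under the alignment of haplotypes 1, 5, 8, 9, 10 with
#' var. ponderosa and 2, 3, 4, 6, 7 with var. scopulorum. Exact distance
#' ties go to `"P"` and are reported with a message.
#'
#' @param presences Tibble with `lon`, `lat`.
#' @param haplotype_points Tibble with `lon`, `lat`, `haplotype` (1-10).
#' @return `presences` with a `variety` column.
#' @export
assign_variety <- function(presences, haplotype_points) {
  hp <- haplotype_points[haplotype_points$haplotype %in% 1:10, ]
  stopifnot(nrow(hp) > 0)
  hv <- HAPLOTYPE_VARIETY[as.character(hp$haplotype)]
  n_ties <- 0L
  variety <- vapply(seq_len(nrow(presences)), function(i) {
    d <- dist_km(presences$lon[i], presences$lat[i], hp$lon, hp$lat)
    dmin <- min(d)
    vs <- unique(hv[d == dmin])
    if (length(vs) > 1) {
      n_ties <<- n_ties + 1L
      "P"
    } else {
      vs
    }
  }, character(1))
  if (n_ties > 0) message(n_ties, " equidistant tie(s) resolved to P")
  presences$variety <- variety
  presences
}

#' Spatially thin points to a minimum separation
#'
#' Greedy maximal thinning in record order: a point is kept iff it lies at
#' least `min_sep` km from every point already kept. The kept set is
#' maximal (every dropped point is within `min_sep` of a kept one) and
#' deterministic for a fixed record order.
#'
#' @param points Tibble with `lon`, `lat`.
#' @param min_sep Minimum separation in km (default 1).
#' @return The kept subset of `points`.
#' @export
thin_points <- function(points, min_sep = 1) {
  stopifnot(min_sep > 0)
  kept <- logical(nrow(points))
  kept_lon <- numeric(0)
  kept_lat <- numeric(0)
  for (i in seq_len(nrow(points))) {
    if (min_dist_to_set(points$lon[i], points$lat[i],
      kept_lon, kept_lat) >= min_sep) {
      kept[i] <- TRUE
      kept_lon <- c(kept_lon, points$lon[i])
      kept_lat <- c(kept_lat, points$lat[i])
    }
  }
  points[kept, , drop = FALSE]
}

#' Assemble the presence/absence dataset for one haplotype model
#'
#' Presences are the (spatially thinned) sample locations of haplotype `h`.
#' Absences are every sampled location of the *other* variety's haplotypes
#' whose `exclude` list does not name `h`, plus `n_abs` seeded-random
#' non-ponderosa background absences. Locations of the same variety's
#' other haplotypes are neither presences nor absences.
#'
#' @param h Haplotype number, 1-10.
#' @param haplotype_points Tibble with `lon`, `lat`, `haplotype` (0 rows
#'   allowed for haplotype 0 = non-ponderosa) and list-column `exclude`.
#' @param background_absences Tibble of candidate absence points
#'   (`lon`, `lat`), at least `n_abs` rows.
#' @param n_abs Number of random background absences to add
#'   (default 3000).
#' @param seed Integer seed for the background subsample.
#' @param thin_sep Thinning separation for presences in km (default 1);
#'   `NULL` to skip thinning.
#' @return Occurrence tibble with `id`, `lon`, `lat`, `y` and a `source`
#'   column (`"haplotype"`, `"other_variety"`, `"background"`).
#' @export
build_haplotype_dataset <- function(h, haplotype_points, background_absences,
                                    n_abs = 3000, seed, thin_sep = 1) {
  stopifnot(h %in% 1:10, nrow(background_absences) >= n_abs)
  hp <- haplotype_points[haplotype_points$haplotype %in% 1:10, ]
  if (!"exclude" %in% names(hp)) hp$exclude <- vector("list", nrow(hp))
  pres <- hp[hp$haplotype == h, ]
  if (nrow(pres) == 0) stop("no presences for haplotype ", h, call. = FALSE)
  if (!is.null(thin_sep)) pres <- thin_points(pres, thin_sep)
  my_var <- HAPLOTYPE_VARIETY[[as.character(h)]]
  other <- hp[HAPLOTYPE_VARIETY[as.character(hp$haplotype)] != my_var, ]
  excluded <- vapply(other$exclude, function(e) h %in% e, logical(1))
  other <- other[!excluded, ]
  bg <- withr::with_seed(seed, {
    background_absences[sample.int(nrow(background_absences), n_abs), ]
  })
  out <- dplyr::bind_rows(
    tibble::tibble(lon = pres$lon, lat = pres$lat, y = 1L,
      source = "haplotype"),
    tibble::tibble(lon = other$lon, lat = other$lat, y = 0L,
      source = "other_variety"),
    tibble::tibble(lon = bg$lon, lat = bg$lat, y = 0L,
      source = "background")
  )
  out$id <- seq_len(nrow(out))
  dplyr::relocate(out, "id")
}

#' Read a variety-schema occurrence CSV
#'
#' Schema: columns `Variety` (`"P"`, `"S"`, or `"-"` for non-ponderosa
#' absences), `Longitude`, `Latitude`. Records after the 10,000th are the
#' extra absence block used only for last-glacial-maximum reconstruction
#' and are flagged in the `lgm_only` column.
#'
#' @param path CSV path.
#' @param lgm_after Record number after which rows are LGM-only absences
#'   (default 10000).
#' @return Tibble with `variety`, `lon`, `lat`, `y`, `lgm_only`.
#' @export
read_variety_points <- function(path, lgm_after = 10000) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  names(df) <- tolower(names(df))
  out <- tibble::tibble(
    variety = as.character(df$variety),
    lon = df$longitude,
    lat = df$latitude
  )
  stopifnot(all(out$variety %in% c("P", "S", "-")))
  out$y <- as.integer(out$variety != "-")
  out$lgm_only <- seq_len(nrow(out)) > lgm_after
  out
}

#' Write a variety-schema occurrence CSV
#'
#' @param points Tibble with `variety`, `lon`, `lat`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variety_points <- function(points, path) {
  readr::write_csv(
    tibble::tibble(
      Variety = points$variety,
      Longitude = sprintf("%.6f", points$lon), # ~0.1 m, round-trip stable
      Latitude = sprintf("%.6f", points$lat)
    ),
    path
  )
  invisible(path)
}

#' Read a haplotype-schema occurrence CSV
#'
#' Schema: `Haplotype` (0-10, 0 = non-ponderosa location), `Longitude`,
#' `Latitude`, `Exclude` (semicolon-separated haplotype numbers for whose
#' models the record must not serve as an absence; empty or `-` for none).
#'
#' @param path CSV path.
#' @return Tibble with `haplotype`, `lon`, `lat` and list-column `exclude`.
#' @export
read_haplotype_points <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
    col_types = readr::cols(Exclude = readr::col_character()))
  names(df) <- tolower(names(df))
  excl <- lapply(df$exclude, function(e) {
    if (is.na(e) || e %in% c("", "-")) return(integer(0))
    as.integer(strsplit(e, ";")[[1]])
  })
  out <- tibble::tibble(
    haplotype = as.integer(df$haplotype),
    lon = df$longitude,
    lat = df$latitude,
    exclude = excl
  )
  stopifnot(all(out$haplotype %in% 0:10))
  out
}

#' Write a haplotype-schema occurrence CSV
#'
#' @param points Tibble with `haplotype`, `lon`, `lat` and optional
#'   list-column `exclude`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_points <- function(points, path) {
  excl <- if ("exclude" %in% names(points)) {
    vapply(points$exclude, function(e) {
      if (length(e) == 0) "-" else paste(e, collapse = ";")
    }, character(1))
  } else {
    rep("-", nrow(points))
  }
  readr::write_csv(
    tibble::tibble(
      Haplotype = points$haplotype,
      Longitude = sprintf("%.6f", points$lon),
      Latitude = sprintf("%.6f", points$lat),
      Exclude = excl
    ),
    path
  )
  invisible(path)
}
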