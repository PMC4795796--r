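# smooth seeded random field: low-order trend + Gaussian bump mixture,
# roughly in [-1, 1]; pure function of (u, v, k, seed-state)
random_field <- function(u, v, k = 8) {
  cx <- stats::runif(k)
  cy <- stats::runif(k)
  amp <- stats::runif(k, -1, 1)
  sc <- stats::runif(k, 0.1, 0.35)
  f <- rep(0, length(u))
  for (i in seq_len(k)) {
    f <- f + amp[i] * exp(-((u - cx[i])^2 + (v - cy[i])^2) / (2 * sc[i]^2))
  }
  f / max(abs(f))
}

#' Generate a synthetic monthly-climate scene
#'
#' Builds smooth virtual climate surfaces over a regular lon/lat grid:
#' monthly mean and minimum temperatures with a seasonal cycle, a
#' latitudinal gradient and an elevational lapse; monthly precipitation
#' with a west-to-east transition from winter-dominated to
#' summer-dominated regimes (so PRATIO increases eastward, emulating the
#' steep seasonal precipitation cline the niche models exploit); smooth
#' synthetic elevation and a non-negative ruggedness field. All derived
#' predictors are finite. Regeneration with the same arguments is
#' identical.
#'
#' @param extent Named or positional numeric `c(west, east, south, north)`
#'   in decimal degrees. The default covers ~1 degree (~100 km) square.
#' @param resolution Cell size in degrees (default 0.01, ~1 km).
#' @param seed Integer seed.
#' @param derive Also append the derived predictor columns
#'   ([derive_predictors()]); default `TRUE`.
#' @return Tidy cell tibble: `lon`, `lat`, `elev`, `tri`, `tmean_01..12`,
#'   `tmin_01..12`, `prec_01..12` (+ predictors when `derive = TRUE`).
#' @export
generate_climate_surface <- function(extent = c(-114, -113, 44, 45),
                                     resolution = 0.01, seed = 1,
                                     derive = TRUE) {
  stopifnot(resolution > 0, length(extent) == 4)
  west <- extent[1]; east <- extent[2]; south <- extent[3]; north <- extent[4]
  lon <- seq(west + resolution / 2, east - resolution / 2, by = resolution)
  lat <- seq(south + resolution / 2, north - resolution / 2, by = resolution)
  cells <- tidyr::expand_grid(lat = rev(lat), lon = lon)[, c("lon", "lat")]
  u <- (cells$lon - west) / (east - west)
  v <- (cells$lat - south) / (north - south)
  scene <- withr::with_seed(seed, {
    b_elev <- random_field(u, v)
    b_temp <- random_field(u, v)
    b_prec <- random_field(u, v)
    b_tri <- random_field(u, v, k = 12)
    elev <- 1400 + 600 * b_elev + 150 * sin(2 * pi * u)
    tri <- 5 * abs(b_tri)
    out <- cells
    out$elev <- elev
    out$tri <- tri
    for (m in 1:12) {
      seas <- -cos(2 * pi * (m - 0.5) / 12) # -1 in Jan, +1 in Jul
      tmean <- 11 + 11 * seas - 3 * v - 6.5 * (elev - 1000) / 1000 +
        0.8 * b_temp
      out[[sprintf("tmean_%02d", m)]] <- tmean
      out[[sprintf("tmin_%02d", m)]] <- tmean - 6
      winter_w <- 1 - seas # 2 in Jan, 0 in Jul
      summer_w <- 1 + seas
      prec <- 5 + 28 * ((1 - u) * winter_w + u * summer_w) *
        (1 + 0.15 * b_prec)
      out[[sprintf("prec_%02d", m)]] <- pmax(prec, 0.5)
    }
    out
  })
  if (derive) scene <- derive_predictors(scene, study_bounds = c(west, east))
  scene
}

#' Define a virtual multiplicative-Gaussian niche
#'
#' The true occurrence probability surface is
#' `p(x) = pmax * prod_j exp(-(x_j - mu_j)^2 / (2 tau_j^2))` -- the same
#' multiplicative Gaussian family the NPMR estimator assumes, which makes
#' parameter recovery a meaningful oracle. For a deliberately misspecified
#' (bimodal) axis, supply two rows with the same predictor via
#' [bimodal_niche()].
#'
#' @param terms Tibble with `predictor`, `mu` (optimum), `tau` (> 0 niche
#'   width, predictor units).
#' @param pmax Peak occurrence probability in (0, 1].
#' @return Object of class `virtual_niche`.
#' @export
virtual_niche <- function(terms, pmax = 0.8) {
  terms <- tibble::as_tibble(terms)
  stopifnot(
    all(c("predictor", "mu", "tau") %in% names(terms)),
    all(terms$tau > 0), pmax > 0, pmax <= 1
  )
  structure(list(terms = terms, pmax = pmax), class = "virtual_niche")
}

#' A mixture-of-two-optima niche on one predictor
#'
#' Returns a niche object whose probability on the named predictor is the
#' (capped) sum of two Gaussian modes -- a misspecified, bimodal truth the
#' single-Gaussian kernel family can only approximate.
#'
#' @param predictor Predictor name.
#' @param mu Length-2 optima.
#' @param tau Length-2 widths.
#' @param pmax Peak probability of each mode.
#' @return Object of class `virtual_niche` (with `bimodal = TRUE`).
#' @export
bimodal_niche <- function(predictor, mu, tau, pmax = 0.6) {
  stopifnot(length(mu) == 2, length(tau) == 2, all(tau > 0))
  structure(
    list(
      terms = tibble::tibble(predictor = predictor, mu = mu, tau = tau),
      pmax = pmax, bimodal = TRUE
    ),
    class = "virtual_niche"
  )
}

#' True occurrence probability of a niche at given points
#'
#' @param niche A [virtual_niche()].
#' @param data Tibble with the niche's predictor columns.
#' @return Numeric probability vector.
#' @export
niche_probability <- function(niche, data) {
  t <- niche$terms
  if (isTRUE(niche$bimodal)) {
    x <- data[[t$predictor[1]]]
    p <- niche$pmax * (exp(-(x - t$mu[1])^2 / (2 * t$tau[1]^2)) +
      exp(-(x - t$mu[2])^2 / (2 * t$tau[2]^2)))
    return(pmin(p, 1))
  }
  p <- rep(niche$pmax, nrow(data))
  for (i in seq_len(nrow(t))) {
    x <- data[[t$predictor[i]]]
    p <- p * exp(-(x - t$mu[i])^2 / (2 * t$tau[i]^2))
  }
  p
}

#' Sample virtual-species occurrences from a scene
#'
#' Draws candidate locations uniformly over the scene's cells (with a
#' uniform jitter inside each cell) and labels each one presence with its
#' true niche probability, absence otherwise. The true probability is kept
#' alongside for oracle tests.
#'
#' @param scene Cell tibble from [generate_climate_surface()] (predictors
#'   derived).
#' @param niche A [virtual_niche()].
#' @param n_candidates Number of locations.
#' @param seed Integer seed.
#' @return Occurrence tibble: `id`, `lon`, `lat`, `y`, `true_prob` plus
#'   all scene predictor columns.
#' @export
sample_occurrences <- function(scene, niche, n_candidates, seed) {
  missing_preds <- setdiff(niche$terms$predictor, names(scene))
  if (length(missing_preds) > 0) {
    stop("scene lacks niche predictor(s): ",
      paste(missing_preds, collapse = ", "), call. = FALSE)
  }
  lons <- sort(unique(scene$lon))
  cs <- if (length(lons) > 1) min(diff(lons)) else 0
  withr::with_seed(seed, {
    i <- sample.int(nrow(scene), n_candidates, replace = TRUE)
    pts <- scene[i, , drop = FALSE]
    pts$lon <- pts$lon + stats::runif(n_candidates, -cs / 2, cs / 2)
    pts$lat <- pts$lat + stats::runif(n_candidates, -cs / 2, cs / 2)
    p <- niche_probability(niche, pts)
    pts$true_prob <- p
    pts$y <- stats::rbinom(n_candidates, 1, p)
    pts$id <- seq_len(n_candidates)
    dplyr::relocate(pts, "id", "lon", "lat", "y", "true_prob")
  })
}

#' Cluster points into spatially aggregated populations
#'
#' Emulates stand-level field sampling: `k_populations` centers are drawn
#' from the supplied points, and `per_pop` locations are scattered around
#' each with an isotropic Gaussian spread, enforcing a 100 m minimum
#' separation within each population by rejection.
#'
#' @param points Candidate center pool (tibble with `lon`, `lat`).
#' @param k_populations Number of population clusters.
#' @param spread_km Gaussian spatial spread (km) around each center.
#' @param per_pop Points per population.
#' @param seed Integer seed.
#' @param min_sep_km Within-population minimum separation (default 0.1).
#' @return Tibble `population`, `lon`, `lat`.
#' @export
cluster_into_populations <- function(points, k_populations, spread_km,
                                     per_pop, seed, min_sep_km = 0.1) {
  stopifnot(k_populations >= 1, per_pop >= 1, spread_km > 0)
  withr::with_seed(seed, {
    ci <- sample.int(nrow(points), k_populations,
      replace = k_populations > nrow(points))
    out <- vector("list", k_populations)
    for (k in seq_len(k_populations)) {
      c_lon <- points$lon[ci[k]]
      c_lat <- points$lat[ci[k]]
      km_per_deg_lat <- 111.2
      km_per_deg_lon <- 111.2 * cos(c_lat * pi / 180)
      lons <- numeric(0)
      lats <- numeric(0)
      tries <- 0L
      budget <- 400L * per_pop
      while (length(lons) < per_pop && tries < budget) {
        tries <- tries + 1L
        lon <- c_lon + stats::rnorm(1, sd = spread_km / km_per_deg_lon)
        lat <- c_lat + stats::rnorm(1, sd = spread_km / km_per_deg_lat)
        if (min_dist_to_set(lon, lat, lons, lats) >= min_sep_km) {
          lons <- c(lons, lon)
          lats <- c(lats, lat)
        }
      }
      if (length(lons) < per_pop) {
        stop("population ", k, ": could not place ", per_pop,
          " points at ", min_sep_km, " km separation (spread too tight)",
          call. = FALSE)
      }
      out[[k]] <- tibble::tibble(population = k, lon = lons, lat = lats)
    }
    dplyr::bind_rows(out)
  })
}

#' Synthetic variety-schema fixture with the published tallies
#'
#' Builds a fully synthetic occurrence table in the variety CSV schema
#' whose record counts mirror the deposited modeling dataset: Pacific and
#' Rocky Mountain presences drawn from two seasonal-precipitation niches
#' (winter- vs. summer-dominated), non-ponderosa absences, and an extra
#' absence block appended after the main records for glacial-maximum
#' reconstruction use. All coordinates and labels are generated; only the
#' counts echo the real dataset's bookkeeping.
#'
#' @param seed Integer seed.
#' @param scene Optional pre-built scene (default: a coarse 50x50 scene).
#' @param n_presence_p,n_presence_s Presence counts per variety
#'   (defaults 1059 and 861).
#' @param n_absence Main-block absence count (default 8080).
#' @param n_lgm_extra Extra LGM-only absence block size (default 1605).
#' @return Tibble in [read_variety_points()] layout (`variety`, `lon`,
#'   `lat`) ordered main block first.
#' @export
simulate_variety_fixture <- function(seed, scene = NULL,
                                     n_presence_p = 1059,
                                     n_presence_s = 861,
                                     n_absence = 8080,
                                     n_lgm_extra = 1605) {
  if (is.null(scene)) {
    scene <- generate_climate_surface(resolution = 0.02, seed = seed)
  }
  jitter_pts <- function(idx, cs) {
    tibble::tibble(
      lon = scene$lon[idx] + stats::runif(length(idx), -cs / 2, cs / 2),
      lat = scene$lat[idx] + stats::runif(length(idx), -cs / 2, cs / 2)
    )
  }
  cs <- min(diff(sort(unique(scene$lon))))
  pr <- scene$PRATIO
  niche_p <- exp(-(pr - stats::quantile(pr, 0.15))^2 / (2 * 0.06^2))
  niche_s <- exp(-(pr - stats::quantile(pr, 0.85))^2 / (2 * 0.06^2))
  withr::with_seed(seed, {
    ip <- sample.int(nrow(scene), n_presence_p, replace = TRUE,
      prob = niche_p)
    is_ <- sample.int(nrow(scene), n_presence_s, replace = TRUE,
      prob = niche_s)
    ia <- sample.int(nrow(scene), n_absence, replace = TRUE)
    ilgm <- sample.int(nrow(scene), n_lgm_extra, replace = TRUE,
      prob = (scene$lon - min(scene$lon) + 0.05)^2) # eastern-weighted
    main <- dplyr::bind_rows(
      dplyr::mutate(jitter_pts(ip, cs), variety = "P"),
      dplyr::mutate(jitter_pts(is_, cs), variety = "S"),
      dplyr::mutate(jitter_pts(ia, cs), variety = "-")
    )
    main <- main[sample.int(nrow(main)), ] # interleave the main block
    extra <- dplyr::mutate(jitter_pts(ilgm, cs), variety = "-")
    dplyr::bind_rows(main, extra)[, c("variety", "lon", "lat")]
  })
}

#' Synthetic haplotype-schema fixture with the published tallies
#'
#' Generates a haplotype CSV-schema table sized so the haplotype-1 model
#' assembled from it reproduces the published 45 presences and 3125
#' absences: 45 mutually separated haplotype-1 locations, 130 Rocky
#' Mountain-variety haplotype locations of which 5 carry an `exclude`
#' entry for haplotype 1 (leaving 125 eligible absences), a handful of
#' Pacific-variety locations of other haplotypes (neither presences nor
#' absences), and 3000 non-ponderosa (haplotype 0) background locations.
#'
#' @param seed Integer seed.
#' @param n_background Haplotype-0 background rows (default 3000).
#' @return Tibble in [read_haplotype_points()] layout.
#' @export
simulate_haplotype_fixture <- function(seed, n_background = 3000) {
  withr::with_seed(seed, {
    # 45 haplotype-1 presences on a ~2 km lattice (already > 1 km apart)
    g <- tidyr::expand_grid(i = 0:8, j = 0:4)
    h1 <- tibble::tibble(
      haplotype = 1L,
      lon = -113.9 + g$i * 0.02 + stats::runif(45, 0, 0.004),
      lat = 44.1 + g$j * 0.02 + stats::runif(45, 0, 0.004),
      exclude = vector("list", 45)
    )
    other_s <- tibble::tibble(
      haplotype = sample(c(3L, 6L, 7L), 130, replace = TRUE),
      lon = stats::runif(130, -113.5, -113.0),
      lat = stats::runif(130, 44.0, 45.0),
      exclude = c(replicate(5, 1L, simplify = FALSE),
        vector("list", 125))
    )
    other_p <- tibble::tibble(
      haplotype = sample(c(5L, 8L), 12, replace = TRUE),
      lon = stats::runif(12, -114.0, -113.8),
      lat = stats::runif(12, 44.0, 45.0),
      exclude = vector("list", 12)
    )
    background <- tibble::tibble(
      haplotype = 0L,
      lon = stats::runif(n_background, -114, -113),
      lat = stats::runif(n_background, 44, 45),
      exclude = vector("list", n_background)
    )
    dplyr::bind_rows(h1, other_s, other_p, background)
  })
}

#' Write synthetic fixture files in the supplementary CSV schemas
#'
#' Emits the variety-, haplotype- and validation-schema CSVs (plus,
#' optionally, ESRI ASCII grids for selected scene columns) so that every
#' pipeline stage can be exercised from files. Everything written here is
#' synthetic; filenames say so.
#'
#' @param dir Output directory (created if needed).
#' @param variety_points,haplotype_points,validation_points Tibbles in the
#'   respective reader layouts (any may be `NULL` to skip).
#' @param scene Optional scene; `grid_cols` of it are written as `.asc`.
#' @param grid_cols Scene columns to rasterize (default `"elev"`).
#' @return Named character vector of written paths, invisibly.
#' @export
emit_fixture_files <- function(dir, variety_points = NULL,
                               haplotype_points = NULL,
                               validation_points = NULL,
                               scene = NULL, grid_cols = "elev") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if (!is.null(variety_points)) {
    p <- file.path(dir, "synthetic_variety_points.csv")
    write_variety_points(variety_points, p)
    paths["variety"] <- p
  }
  if (!is.null(haplotype_points)) {
    p <- file.path(dir, "synthetic_haplotype_points.csv")
    write_haplotype_points(haplotype_points, p)
    paths["haplotype"] <- p
  }
  if (!is.null(validation_points)) {
    p <- file.path(dir, "synthetic_validation_points.csv")
    write_variety_points(validation_points, p)
    paths["validation"] <- p
  }
  if (!is.null(scene)) {
    for (col in grid_cols) {
      p <- file.path(dir, sprintf("synthetic_%s.asc", tolower(col)))
      write_ascii_grid(scene, p, value = col)
      paths[col] <- p
    }
  }
  invisible(paths)
}

#' Default virtual-species niche for a scene
#'
#' The reference two-term niche used by the end-to-end recovery studies: a
#' multiplicative Gaussian optimum on the seasonal precipitation balance
#' (PRATIO) and warmest-month temperature (MTWM), with widths of 10% of
#' each predictor's range across the scene. That width makes the truth a
#' strong but realistically noisy signal: the true probability surface
#' itself separates presences from absences with AUC about 0.93, and
#' prevalence lands near 5%, comparable to the sparse presence fractions
#' of real occurrence datasets.
#'
#' @param scene Scene tibble with derived predictors.
#' @param pmax Peak occurrence probability (default 0.8).
#' @param tau_frac Niche width as a fraction of each predictor's observed
#'   range (default 0.1).
#' @return A [virtual_niche()].
#' @export
default_virtual_niche <- function(scene, pmax = 0.8, tau_frac = 0.1) {
  virtual_niche(
    tibble::tibble(
      predictor = c("PRATIO", "MTWM"),
      mu = c(
        unname(stats::quantile(scene$PRATIO, 0.35)),
        unname(stats::quantile(scene$MTWM, 0.6))
      ),
      tau = c(
        tau_frac * diff(range(scene$PRATIO)),
        tau_frac * diff(range(scene$MTWM))
      )
    ),
    pmax = pmax
  )
}
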