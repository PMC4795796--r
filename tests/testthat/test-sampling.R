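small_mask <- function(n_side = 20, cellsize = 0.05) {
  g <- tidyr::expand_grid(
    lat = seq(44 + cellsize / 2, 44 + n_side * cellsize, by = cellsize),
    lon = seq(-114 + cellsize / 2, -114 + n_side * cellsize, by = cellsize)
  )[, c("lon", "lat")]
  g$mask <- 1
  g
}

test_that("background sampling honors the separation and is reproducible", {
  mask <- small_mask()
  pts <- sample_background(mask, 120, min_sep = 1, seed = 9)
  expect_equal(nrow(pts), 120)
  d <- geosphere::distHaversine(
    cbind(pts$lon, pts$lat)[rep(1:120, each = 120), ],
    cbind(pts$lon, pts$lat)[rep(1:120, times = 120), ],
    r = 6371
  )
  dmat <- matrix(d, 120, 120)
  diag(dmat) <- Inf
  expect_gte(min(dmat), 1)
  pts2 <- sample_background(mask, 120, min_sep = 1, seed = 9)
  expect_identical(pts, pts2)
})

test_that("infeasible background sampling errors with the achieved count", {
  one_cell <- tibble::tibble(lon = -114, lat = 44, mask = 1)
  expect_error(
    sample_background(one_cell, 5, min_sep = 500, seed = 1, max_tries = 20),
    "could only place"
  )
})

test_that("mask agreement keeps concordant points and drops the rest", {
  m1 <- small_mask()
  m2 <- small_mask()
  # species mask positive in the west half, secondary in the south-west 3/4
  m1$mask <- as.integer(m1$lon < -113.5)
  m2$mask <- as.integer(m1$lon < -113.25)
  pts <- tibble::tibble(
    lon = c(-113.9, -113.9, -113.3, -113.1),
    lat = rep(44.4, 4)
  )
  expect_message(
    lab <- label_by_mask_agreement(pts, m1, m2),
    "disagreement"
  )
  # -113.9 x2 agree-presence; -113.3 disagrees; -113.1 agrees-absence
  expect_equal(nrow(lab), 3)
  expect_equal(lab$y, c(1L, 1L, 0L))

  # checkerboard overlap: retained count equals the analytic intersection
  cb1 <- small_mask()
  cb2 <- small_mask()
  idx <- seq_len(nrow(cb1))
  cb1$mask <- as.integer(idx %% 2 == 0)
  cb2$mask <- as.integer(idx %% 4 %in% c(0, 1))
  centers <- cb1[, c("lon", "lat")]
  agree <- sum((cb1$mask == 1 & cb2$mask == 1) |
    (cb1$mask == 0 & cb2$mask == 0))
  lab2 <- suppressMessages(label_by_mask_agreement(centers, cb1, cb2))
  expect_equal(nrow(lab2), agree)
})

test_that("misaligned masks are rejected", {
  m1 <- small_mask()
  m2 <- small_mask(cellsize = 0.04)
  expect_error(
    label_by_mask_agreement(tibble::tibble(lon = -113.9, lat = 44.2), m1, m2),
    "aligned"
  )
})

test_that("variety assignment follows the nearest haplotype sample", {
  hp <- tibble::tibble(
    haplotype = c(1L, 3L),
    lon = c(-114, -113),
    lat = c(44.5, 44.5)
  )
  pres <- tibble::tibble(lon = c(-113.95, -113.05), lat = c(44.5, 44.5))
  out <- assign_variety(pres, hp)
  expect_equal(out$variety, c("P", "S"))

  # a single Pacific-aligned sample labels everything P
  out1 <- assign_variety(pres, hp[1, ])
  expect_equal(out1$variety, c("P", "P"))

  # exact equidistance (coincident samples of both varieties) resolves to
  # P with a message
  co <- tibble::tibble(
    haplotype = c(1L, 3L), lon = c(-113.5, -113.5), lat = c(44.5, 44.5)
  )
  mid <- tibble::tibble(lon = -113.4, lat = 44.5)
  expect_message(tie <- assign_variety(mid, co), "tie")
  expect_equal(tie$variety, "P")
})

test_that("variety labels match a brute-force nearest-neighbor oracle", {
  withr::with_seed(71, {
    hp <- tibble::tibble(
      haplotype = sample(1:10, 25, replace = TRUE),
      lon = stats::runif(25, -120, -105),
      lat = stats::runif(25, 35, 48)
    )
    pres <- tibble::tibble(
      lon = stats::runif(40, -120, -105),
      lat = stats::runif(40, 35, 48)
    )
  })
  out <- assign_variety(pres, hp)
  p_haps <- c(1, 5, 8, 9, 10)
  for (i in seq_len(40)) {
    d <- geosphere::distHaversine(
      cbind(pres$lon[i], pres$lat[i]),
      cbind(hp$lon, hp$lat), r = 6371
    )
    expected <- if (hp$haplotype[which.min(d)] %in% p_haps) "P" else "S"
    expect_equal(out$variety[i], expected, info = paste("point", i))
  }
})

test_that("thinning keeps a maximal set at the required separation", {
  spread <- tibble::tibble(
    lon = c(-114, -113.5, -113, -112.5),
    lat = rep(44, 4)
  )
  expect_equal(nrow(thin_points(spread, min_sep = 1)), 4)

  dup <- tibble::tibble(lon = c(-114, -114), lat = c(44, 44))
  expect_equal(nrow(thin_points(dup, min_sep = 1)), 1)

  clustered <- withr::with_seed(5, {
    centers <- tibble::tibble(lon = c(-114, -113.7), lat = c(44, 44.2))
    tibble::tibble(
      lon = rep(centers$lon, each = 30) + stats::rnorm(60, 0, 0.005),
      lat = rep(centers$lat, each = 30) + stats::rnorm(60, 0, 0.005)
    )
  })
  kept <- thin_points(clustered, min_sep = 1)
  km <- function(i, j, a, b) geosphere::distHaversine(
    cbind(a$lon[i], a$lat[i]), cbind(b$lon[j], b$lat[j]), r = 6371)
  # all kept pairs separated
  if (nrow(kept) > 1) {
    for (i in 1:(nrow(kept) - 1)) {
      for (j in (i + 1):nrow(kept)) {
        expect_gte(km(i, j, kept, kept), 1)
      }
    }
  }
  # maximality: every dropped point is within min_sep of some kept point
  dropped <- dplyr::anti_join(clustered, kept, by = c("lon", "lat"))
  for (i in seq_len(nrow(dropped))) {
    dmin <- min(vapply(seq_len(nrow(kept)), function(j) {
      km(i, j, dropped, kept)
    }, numeric(1)))
    expect_lt(dmin, 1)
  }
})

test_that("haplotype datasets assemble presences, exclusions and background", {
  hp <- simulate_haplotype_fixture(seed = 2)
  background <- hp[hp$haplotype == 0, ]
  ds <- build_haplotype_dataset(1, hp, background, n_abs = 3000, seed = 5)
  expect_equal(sum(ds$y == 1), 45)
  expect_equal(sum(ds$y == 0), 3125)
  expect_equal(sum(ds$source == "other_variety"), 125)
  # records carrying an exclude entry for a haplotype never serve as
  # absences in that haplotype's model
  hp6 <- hp
  idx <- which(hp6$haplotype %in% c(5, 8))[1:4]
  hp6$exclude[idx] <- list(6L)
  ds6 <- build_haplotype_dataset(6, hp6, background, n_abs = 100, seed = 5,
    thin_sep = NULL)
  n_eligible <- sum(hp6$haplotype %in% c(1, 5, 8, 9, 10)) - 4
  expect_equal(sum(ds6$source == "other_variety"), n_eligible)
  expect_error(
    build_haplotype_dataset(2, hp, background, n_abs = 100, seed = 1),
    "no presences"
  )
})

test_that("variety and haplotype CSVs round-trip byte-identically", {
  dir <- withr::local_tempdir()
  vp <- simulate_variety_fixture(seed = 3,
    n_presence_p = 30, n_presence_s = 20, n_absence = 80, n_lgm_extra = 15)
  p1 <- file.path(dir, "v1.csv")
  p2 <- file.path(dir, "v2.csv")
  write_variety_points(vp, p1)
  rt <- read_variety_points(p1, lgm_after = 130)
  write_variety_points(rt, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(sum(rt$lgm_only), 15)
  expect_equal(sum(rt$y), 50)

  hp <- simulate_haplotype_fixture(seed = 4, n_background = 50)
  h1 <- file.path(dir, "h1.csv")
  h2 <- file.path(dir, "h2.csv")
  write_haplotype_points(hp, h1)
  rt2 <- read_haplotype_points(h1)
  write_haplotype_points(rt2, h2)
  expect_identical(readLines(h1), readLines(h2))
  expect_equal(sum(vapply(rt2$exclude, length, integer(1)) > 0), 5)
})
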