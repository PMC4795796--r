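test_that("ESRI ASCII grids round-trip values and georeferencing", {
  scene <- generate_climate_surface(resolution = 0.1, seed = 6,
    derive = FALSE)
  scene$elev[c(3, 47)] <- NA # NODATA cells survive the trip
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(scene, path, value = "elev")
  back <- read_ascii_grid(path, value = "elev")
  # coordinates agree to float precision; compare in consistent cell order
  ord1 <- order(round(scene$lat, 9), round(scene$lon, 9))
  ord2 <- order(round(back$lat, 9), round(back$lon, 9))
  expect_equal(back$lon[ord2], scene$lon[ord1], tolerance = 1e-9)
  expect_equal(back$lat[ord2], scene$lat[ord1], tolerance = 1e-9)
  expect_equal(back$elev[ord2], signif(scene$elev, 6)[ord1],
    tolerance = 1e-6)
  meta <- attr(back, "grid_meta")
  expect_equal(meta$cellsize, 0.1, tolerance = 1e-9)
  expect_equal(meta$ncols, 10)
  expect_equal(meta$xll, -114, tolerance = 1e-9)
})

test_that("nearest-cell extraction drops points on NODATA cells", {
  g <- tidyr::expand_grid(lat = c(44.25, 44.75), lon = c(-113.75, -113.25))
  g <- g[, c("lon", "lat")]
  g$v <- c(10, 20, 30, NA)
  pts <- tibble::tibble(lon = c(-113.7, -113.3), lat = c(44.2, 44.8))
  expect_message(out <- extract_at_points(pts, g), "dropped")
  expect_equal(nrow(out), 1)
  expect_equal(out$v, 10)
})

test_that("gridded prediction matches per-cell oracle estimates", {
  scene <- make_test_scene(resolution = 0.1)
  niche <- make_test_niche(scene)
  occ <- sample_occurrences(scene, niche, 300, seed = 77)
  fit <- npmr_fit(occ, tibble::tibble(
    predictor = c("PRATIO", "MTWM"),
    tolerance = c(0.06, 1.5)
  ))
  pg <- predict_grid(fit, scene)
  expect_s3_class(pg, "npmr_prob_grid")
  expect_true(all(pg$prob >= 0 & pg$prob <= 1, na.rm = TRUE))
  o <- oracle_estimates(occ, c("PRATIO", "MTWM"), c(0.06, 1.5),
    loo = FALSE, min_local_weight = 1, targets = scene)
  expect_equal(pg$prob, o$estimates, tolerance = 1e-10)
  # no cell exceeds the maximum training estimate (local-mean bound)
  expect_lte(max(pg$prob, na.rm = TRUE),
    max(predict(fit), na.rm = TRUE) + 1e-12)
})

test_that("constant grids at a training point give that point's estimate", {
  occ <- random_toy_data(40, "a", seed = 13)
  fit <- npmr_fit(occ, tibble::tibble(predictor = "a", tolerance = 0.8))
  target <- occ[7, ]
  grid <- tibble::tibble(
    lon = rep(-113.5, 9), lat = seq(44.1, 44.9, by = 0.1),
    a = target$a
  )
  pg <- predict_grid(fit, grid)
  expect_equal(pg$prob, rep(predict(fit, newdata = target), 9))
})

test_that("cells outside all training neighborhoods are NODATA", {
  occ <- random_toy_data(30, "a", seed = 14)
  fit <- npmr_fit(occ, tibble::tibble(predictor = "a", tolerance = 0.3))
  grid <- tibble::tibble(lon = -113.5, lat = 44.5, a = 1e5)
  expect_true(is.na(predict_grid(fit, grid)$prob))
  # a missing predictor grid is an error naming the column
  expect_error(predict_grid(fit, grid[c("lon", "lat")]), "a")
})

test_that("prediction is invariant to training-point order", {
  occ <- random_toy_data(50, c("a", "b"), seed = 15)
  terms <- tibble::tibble(predictor = c("a", "b"), tolerance = c(0.7, 0.9))
  grid <- tibble::tibble(
    lon = seq(-114, -113.2, by = 0.1), lat = 44.5,
    a = seq(-1.5, 1.5, length.out = 9), b = 0
  )
  p1 <- predict_grid(npmr_fit(occ, terms), grid)$prob
  shuffled <- withr::with_seed(1, occ[sample.int(50), ])
  p2 <- predict_grid(npmr_fit(shuffled, terms), grid)$prob
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("display flooring blanks sub-threshold cells only", {
  pg <- structure(
    tibble::tibble(
      lon = rep(1:10 / 10, 10), lat = rep(1:10 / 10, each = 10),
      prob = seq(0, 0.99, length.out = 100)
    ),
    class = c("npmr_prob_grid", class(tibble::tibble()))
  )
  expect_equal(apply_display_floor(pg, 0)$prob, pg$prob)
  floored <- apply_display_floor(pg, 0.135)
  expect_equal(sum(!is.na(floored$prob)), sum(pg$prob >= 0.135))
  expect_equal(floored$prob[!is.na(floored$prob)],
    pg$prob[pg$prob >= 0.135])
  all_gone <- apply_display_floor(pg, 1)
  expect_true(all(is.na(all_gone$prob)))
})

test_that("probability bins are equal intervals up to the maximum", {
  pg <- structure(
    tibble::tibble(lon = 1:100, lat = 1, prob = seq(0.005, 0.5,
      length.out = 100)),
    class = c("npmr_prob_grid", class(tibble::tibble()))
  )
  binned <- bin_probabilities(pg, n_bins = 10)
  expect_equal(attr(binned, "max_prob"), 0.5)
  # direct histogram oracle under the left-closed bin convention
  width <- 0.5 / 10
  oracle_bins <- pmin(floor(pg$prob / width) + 1, 10)
  expect_equal(binned$bin, as.integer(oracle_bins))

  uniform <- structure(
    tibble::tibble(lon = 1:5, lat = 1, prob = rep(0.3, 5)),
    class = c("npmr_prob_grid", class(tibble::tibble()))
  )
  expect_true(all(bin_probabilities(uniform, 10)$bin == 10))
  expect_true(all(bin_probabilities(pg, 1)$bin == 1))
})

test_that("response curves track a unimodal niche and the naive limit", {
  scene <- make_test_scene(resolution = 0.05)
  # one-predictor niche: the marginal response peak IS the niche optimum
  mu_true <- unname(stats::quantile(scene$PRATIO, 0.4))
  niche <- virtual_niche(
    tibble::tibble(predictor = "PRATIO", mu = mu_true,
      tau = 0.1 * diff(range(scene$PRATIO))),
    pmax = 0.85
  )
  occ <- sample_occurrences(scene, niche, 800, seed = 21)
  curve <- response_curve(occ, "PRATIO", threshold = 5)
  expect_true(all(curve$prob >= 0 & curve$prob <= 1, na.rm = TRUE))
  step <- diff(curve$value[1:2])
  peak <- curve$value[which.max(curve$prob)]
  expect_lt(abs(peak - mu_true), 2 * step + 1e-9)

  # response independent of the predictor: flat curve at ~ naive p
  null_occ <- withr::with_seed(31, dplyr::mutate(occ, y = sample(y)))
  flat <- suppressWarnings(response_curve(null_occ, "WINP", threshold = 5))
  expect_lt(diff(range(flat$prob, na.rm = TRUE)), 0.25)

  expect_error(
    response_curve(dplyr::mutate(occ, z = 1), "z", threshold = 5),
    "zero range"
  )
})

test_that("a 1-term curve evaluated at training values equals the fit", {
  occ <- random_toy_data(80, "a", seed = 16)
  s <- free_search(occ, "a", threshold = 5)
  skip_if(nrow(s$fit$model$terms) == 0)
  curve <- response_curve(occ, "a", threshold = 5)
  at_train <- predict(s$fit, newdata = occ)
  direct <- predict(s$fit,
    newdata = tibble::tibble(a = occ$a))
  expect_equal(direct, at_train)
  expect_equal(attr(curve, "tolerance"), s$fit$model$terms$tolerance[1])
})

test_that("autoplot methods return ggplot objects", {
  occ <- random_toy_data(40, "a", seed = 17)
  fit <- npmr_fit(occ, tibble::tibble(predictor = "a", tolerance = 0.8))
  expect_s3_class(autoplot(fit), "ggplot")
  grid <- tibble::tibble(lon = rep(1:5, 5) / 10, lat = rep(1:5, each = 5) / 10,
    a = 0)
  expect_s3_class(autoplot(predict_grid(fit, grid)), "ggplot")
  curve <- response_curve(occ, "a", threshold = 5)
  expect_s3_class(autoplot(curve), "ggplot")
})
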