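# dataset whose occurrence follows a 1-predictor Gaussian niche, with
# independent pure-noise decoys
niche_1d_data <- function(n, seed, tau = 0.6) {
  withr::with_seed(seed, {
    df <- tibble::tibble(
      id = seq_len(n),
      x_true = stats::runif(n, -2, 2),
      decoy1 = stats::runif(n, -2, 2),
      decoy2 = stats::rnorm(n),
      decoy3 = stats::runif(n, 0, 10)
    )
    p <- 0.85 * exp(-df$x_true^2 / (2 * tau^2))
    df$y <- stats::rbinom(n, 1, p)
    df
  })
}

test_that("free search recovers a 1-predictor niche among noise decoys", {
  data <- niche_1d_data(400, seed = 19)
  s <- free_search(data, c("x_true", "decoy1", "decoy2", "decoy3"),
    threshold = 5)
  expect_true("x_true" %in% s$fit$model$terms$predictor)
  expect_false(any(c("decoy1", "decoy2", "decoy3") %in%
    s$fit$model$terms$predictor))
  expect_gt(s$fit$diagnostics$logB, 0)
})

test_that("free search is deterministic for identical data and config", {
  data <- niche_1d_data(200, seed = 4)
  s1 <- free_search(data, c("x_true", "decoy1", "decoy2"), threshold = 5)
  s2 <- free_search(data, c("x_true", "decoy1", "decoy2"), threshold = 5)
  expect_identical(s1$fit$model$terms, s2$fit$model$terms)
  expect_identical(s1$trace, s2$trace)
})

test_that("a response independent of all candidates yields the empty model", {
  n_empty <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    data <- withr::with_seed(1000 + r, {
      tibble::tibble(
        id = 1:150,
        a = stats::runif(150), b = stats::rnorm(150),
        c = stats::runif(150, -3, 3),
        y = stats::rbinom(150, 1, 0.3)
      )
    })
    s <- suppressWarnings(
      free_search(data, c("a", "b", "c"), threshold = 5)
    )
    if (nrow(s$fit$model$terms) == 0) n_empty <- n_empty + 1
  }
  expect_gte(n_empty, ceiling(0.95 * n_rep))
})

test_that("both predictors of a multiplicative niche beat the decoys", {
  data <- withr::with_seed(99, {
    df <- tibble::tibble(
      id = 1:800,
      x1 = stats::runif(800, -2, 2),
      x2 = stats::runif(800, -2, 2),
      decoy1 = stats::runif(800, -2, 2),
      decoy2 = stats::rnorm(800)
    )
    p <- 0.9 * exp(-df$x1^2 / (2 * 0.7^2)) * exp(-df$x2^2 / (2 * 0.7^2))
    df$y <- stats::rbinom(800, 1, p)
    df
  })
  s <- free_search(data, c("decoy1", "x1", "decoy2", "x2"), threshold = 2)
  sel <- s$fit$model$terms$predictor
  expect_true(all(c("x1", "x2") %in% sel))
  # true predictors enter before any decoy
  decoy_pos <- match(c("decoy1", "decoy2"), sel)
  expect_true(all(is.na(decoy_pos) |
    decoy_pos > max(match(c("x1", "x2"), sel))))
})

test_that("every accepted step clears the percent improvement rule", {
  data <- niche_1d_data(500, seed = 7, tau = 0.4)
  data$x_shadow <- data$x_true + withr::with_seed(8, stats::rnorm(500, 0, 0.3))
  s <- free_search(data, c("x_true", "x_shadow", "decoy1"), threshold = 2)
  acc <- s$trace[s$trace$accepted, ]
  if (nrow(acc) > 1) {
    for (k in 2:nrow(acc)) {
      expect_gte(acc$logB[k], acc$logB[k - 1] * 1.02 - 1e-9)
    }
  }
  expect_gt(acc$logB[1], 0)
  # all evaluated-and-accepted models satisfied the neighborhood constraint
  expect_true(all(acc$feasible))
  expect_true(all(acc$nstar >= 0.05 * nrow(data) - 1e-9))
})

test_that("the data-to-predictor ratio floor caps model size", {
  data <- niche_1d_data(25, seed = 3)
  data$x_extra1 <- withr::with_seed(5, stats::runif(25))
  data$x_extra2 <- withr::with_seed(6, stats::runif(25))
  s <- suppressWarnings(free_search(
    data, c("x_true", "decoy1", "x_extra1", "x_extra2"),
    threshold = 0.0001, data_per_predictor = 10
  ))
  expect_lte(nrow(s$fit$model$terms), floor(25 / 10))
})

test_that("fine-tuning never lowers logB and is idempotent at an optimum", {
  data <- niche_1d_data(300, seed = 15)
  s <- free_search(data, c("x_true", "decoy1"), threshold = 5)
  tuned <- fine_tune(s)
  expect_gte(tuned$diagnostics$logB, s$fit$diagnostics$logB)
  # tuning the tuned fit on the same grid changes nothing
  tuned2 <- fine_tune(tuned)
  expect_equal(tuned2$model$terms, tuned$model$terms)
  expect_equal(tuned2$diagnostics$logB, tuned$diagnostics$logB)
})

test_that("fine-tuning helps a sharp niche under-smoothed by the coarse grid", {
  data <- niche_1d_data(600, seed = 23, tau = 0.15)
  s <- free_search(data, "x_true", threshold = 5,
    tol_grid = seq(0.2, 1, by = 0.2)) # deliberately coarse
  skip_if(nrow(s$fit$model$terms) == 0)
  tuned <- fine_tune(s)
  expect_gt(tuned$diagnostics$logB, s$fit$diagnostics$logB)
})

test_that("topography must clear its own percent rule to be kept", {
  data <- niche_1d_data(300, seed = 31)
  data$ELEV <- withr::with_seed(32, stats::runif(300, 500, 2500)) # noise
  sel <- select_with_topography(data, c("x_true", "decoy1"),
    topo_candidates = "ELEV", threshold = 5)
  expect_false(sel$used_topography)
  expect_false("ELEV" %in% sel$fit$model$terms$predictor)

  # an elevation-driven niche flips the outcome
  data2 <- withr::with_seed(41, {
    df <- tibble::tibble(
      id = 1:500,
      decoy1 = stats::runif(500),
      decoy2 = stats::rnorm(500),
      ELEV = stats::runif(500, 500, 2500)
    )
    p <- 0.9 * exp(-(df$ELEV - 1600)^2 / (2 * 250^2))
    df$y <- stats::rbinom(500, 1, p)
    df
  })
  sel2 <- suppressWarnings(select_with_topography(
    data2, c("decoy1", "decoy2"),
    topo_candidates = "ELEV", threshold = 5
  ))
  expect_true(sel2$used_topography)
  expect_true("ELEV" %in% sel2$fit$model$terms$predictor)
})

test_that("batched null calibration agrees with replicate-wise free search", {
  data <- niche_1d_data(150, seed = 77)
  cands <- c("x_true", "decoy1", "decoy2")
  nc <- null_calibration(data, cands, n_reps = 8, seed = 300, threshold = 2)
  for (r in 1:8) {
    shuffled <- withr::with_seed(300 + r,
      dplyr::mutate(data, y = sample(y)))
    s <- suppressWarnings(free_search(shuffled, cands, threshold = 2))
    expect_equal(nrow(s$fit$model$terms) == 0, nc$empty[r],
      info = paste("replicate", r))
  }
})

test_that("niche parameters are recovered across seeded virtual datasets", {
  # 20 virtual-species datasets (n = 200-1000): the true predictors must be
  # selected and the fitted tolerances must lie within a factor of 2 of the
  # generating widths, measured against the grid value nearest each true
  # width (the closest tolerance the 5%-of-range search grid can express),
  # in at least 80% of runs
  ok <- 0
  for (r in 1:20) {
    scene <- generate_climate_surface(resolution = 0.02, seed = 9000 + r)
    niche <- default_virtual_niche(scene)
    n <- withr::with_seed(9100 + r, sample(200:1000, 1))
    train <- sample_occurrences(scene, niche, n, seed = 9200 + r)
    if (sum(train$y) < 2) next
    s <- suppressWarnings(
      free_search(train, c("PRATIO", "MTWM", "SMRPB", "TRI"), threshold = 2)
    )
    sel <- s$fit$model$terms
    both <- all(c("PRATIO", "MTWM") %in% sel$predictor)
    rats <- numeric(0)
    if (both) {
      for (p in c("PRATIO", "MTWM")) {
        tau <- niche$terms$tau[niche$terms$predictor == p]
        tol <- sel$tolerance[sel$predictor == p]
        grid <- seq(0.05, 1, by = 0.05) * diff(range(train[[p]]))
        tau_grid <- grid[which.min(abs(grid - tau))]
        rats <- c(rats, tol / tau_grid)
      }
    }
    if (both && all(rats >= 0.5 - 1e-9) && all(rats <= 2 + 1e-9)) {
      ok <- ok + 1
    }
  }
  expect_gte(ok, 16)
})
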