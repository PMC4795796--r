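# Independent brute-force reference implementations, deliberately written
# as plain double loops over points and terms so they share no code path
# with the package internals.

oracle_weight <- function(x, t, sigma) {
  w <- 1
  for (j in seq_along(sigma)) {
    w <- w * exp(-(x[j] - t[j])^2 / (2 * sigma[j]^2))
  }
  if (is.na(w)) return(NA_real_)
  if (w < 1e-12) 0 else w
}

# per-point local mean estimates; loo drops the target's own row
oracle_estimates <- function(data, preds, sigma, loo = TRUE,
                             min_local_weight = 1, targets = NULL) {
  X <- as.matrix(data[preds])
  Xt <- if (is.null(targets)) X else as.matrix(targets[preds])
  n <- nrow(X)
  m <- nrow(Xt)
  p <- numeric(m)
  sw_all <- numeric(m)
  for (i in seq_len(m)) {
    num <- 0
    den <- 0
    for (k in seq_len(n)) {
      if (loo && is.null(targets) && k == i) next
      w <- oracle_weight(Xt[i, ], X[k, ], sigma)
      if (is.na(w)) next
      num <- num + w * data$y[k]
      den <- den + w
    }
    sw_all[i] <- den
    p[i] <- if (den < min_local_weight) NA_real_ else num / den
  }
  list(estimates = p, nstar = mean(sw_all))
}

oracle_loglik10 <- function(p, y, naive_p, eps = 1e-6) {
  tot <- 0
  for (i in seq_along(y)) {
    pi <- if (is.na(p[i])) naive_p else p[i]
    pi <- min(max(pi, eps), 1 - eps)
    tot <- tot + y[i] * log10(pi) + (1 - y[i]) * log10(1 - pi)
  }
  tot
}

oracle_logB <- function(data, preds, sigma, min_local_weight = 1) {
  p0 <- sum(data$y) / nrow(data)
  est <- oracle_estimates(data, preds, sigma,
    loo = TRUE, min_local_weight = min_local_weight)
  ll_m <- oracle_loglik10(est$estimates, data$y, p0)
  ll_0 <- oracle_loglik10(rep(p0, nrow(data)), data$y, p0)
  list(logB = ll_m - ll_0, nstar = est$nstar, estimates = est$estimates)
}

# AUC by exhaustive presence-absence pair enumeration
oracle_auc <- function(scores, y) {
  pres <- scores[y == 1]
  abs_ <- scores[y == 0]
  tot <- 0
  for (a in pres) {
    for (b in abs_) {
      tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  tot / (length(pres) * length(abs_))
}

oracle_xr2 <- function(p, y) {
  ybar <- mean(y)
  p <- ifelse(is.na(p), ybar, p)
  1 - sum((y - p)^2) / sum((y - ybar)^2)
}

# sensitivity Q by explicit +/- nudging with non-LOO estimates
oracle_q <- function(data, preds, sigma, predictor, nudge = 0.05,
                     min_local_weight = 1) {
  rng <- diff(range(data[[predictor]]))
  base <- oracle_estimates(data, preds, sigma, loo = FALSE,
    min_local_weight = min_local_weight, targets = data)$estimates
  total <- 0
  for (sgn in c(-1, 1)) {
    nudged <- data
    nudged[[predictor]] <- nudged[[predictor]] + sgn * nudge * rng
    pert <- oracle_estimates(data, preds, sigma, loo = FALSE,
      min_local_weight = min_local_weight, targets = nudged)$estimates
    total <- total + mean(abs(pert - base), na.rm = TRUE)
  }
  q_raw <- (total / 2) / diff(range(data$y))
  q_raw / nudge
}

# small random toy occurrence dataset on arbitrary predictor columns
random_toy_data <- function(n, preds, seed) {
  withr::with_seed(seed, {
    df <- tibble::tibble(id = seq_len(n))
    for (p in preds) df[[p]] <- stats::runif(n, -2, 2)
    # response loosely tied to the first predictor so fits are non-trivial
    prob <- stats::plogis(1.5 * df[[preds[1]]])
    df$y <- stats::rbinom(n, 1, prob)
    if (all(df$y == 1)) df$y[1] <- 0L
    if (all(df$y == 0)) df$y[1] <- 1L
    df
  })
}

# independent re-derivation of the climate predictor formulas, written
# spreadsheet-style on one row at a time
oracle_predictors <- function(row) {
  tmean <- as.numeric(row[sprintf("tmean_%02d", 1:12)])
  tmin <- as.numeric(row[sprintf("tmin_%02d", 1:12)])
  prec <- as.numeric(row[sprintf("prec_%02d", 1:12)])
  map <- sum(prec)
  gsp <- sum(prec[4:9])
  mtwm <- max(tmean)
  mtcm <- min(tmean)
  jas <- prec[7] + prec[8] + prec[9]
  list(
    LogMAP = log10(map),
    LogGSP = log10(gsp),
    MTCM = mtcm,
    MTWM = mtwm,
    SUMP = prec[7] + prec[8],
    WINP = prec[11] + prec[12] + prec[1] + prec[2],
    PRATIO = gsp / map,
    SMRPB = jas / (prec[4] + prec[5] + prec[6]),
    SHMI = mtwm / log10(max(jas, 1.0001)),
    TDIFF_LogGSP = (mtwm - mtcm) / log10(gsp),
    DD5 = sum(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31) *
      pmax(tmean - 5, 0)),
    MMINDD0 = sum(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31) *
      pmax(-tmin, 0))
  )
}

# small scene + two-term niche used by several integration tests
make_test_scene <- function(seed = 11, resolution = 0.04) {
  generate_climate_surface(resolution = resolution, seed = seed)
}

make_test_niche <- function(scene) {
  default_virtual_niche(scene)
}
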