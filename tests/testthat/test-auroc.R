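test_that("auROC equals the exhaustive pairwise oracle on random instances", {
  set.seed(42)
  for (k in 1:60) {
    n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
    # integer-ish rates induce ties
    x <- sample(0:8, n1, replace = TRUE)
    y <- sample(0:8, n2, replace = TRUE)
    a <- array(c(x, y), c(1, n1 + n2, 1))
    rt <- as_rate_tensor(a)
    got <- auroc_timecourse(rt, rep(c("A", "B"), c(n1, n2)), "A")[1, 1]
    expect_identical(unname(got), brute_auroc(x, y))
  }
})

test_that("auROC respects its symmetry and boundary identities", {
  set.seed(1)
  x <- rnorm(10); y <- rnorm(12)
  a <- array(c(x, y), c(1, 22, 1))
  lab <- rep(c("A", "B"), c(10, 12))
  rt <- as_rate_tensor(a)
  aAB <- auroc_timecourse(rt, lab, "A")[1, 1]
  aBA <- auroc_timecourse(rt, lab, "B")[1, 1]
  expect_equal(aAB + aBA, 1)
  # perfect separation
  a2 <- array(c(x + 100, y), c(1, 22, 1))
  expect_equal(auroc_timecourse(as_rate_tensor(a2), lab, "A")[1, 1], 1)
  expect_error(auroc_timecourse(rt, rep("A", 22), "A"), "both classes")
  expect_error(
    auroc_timecourse(as_rate_tensor(a), rep(c("A", "B"), c(1, 21)), "A"),
    ">= 2 trials")
})

test_that("permutation masks are calibrated on null units and detect effects", {
  set.seed(3)
  n_units <- 40; n_trials <- 60; n_bins <- 30
  lab <- rep(c("side", "precision"), each = n_trials / 2)
  null_rates <- array(rnorm(n_units * n_trials * n_bins, 10),
                      c(n_units, n_trials, n_bins))
  rt <- as_rate_tensor(null_rates)
  pm <- permutation_mask(rt, lab, "side", n_perm = 2000, alpha = 0.001,
                         min_consec = 2, seed = 5)
  expect_lte(mean(pm$encodes), 0.05)
  expect_lt(abs(mean(pm$auroc) - 0.5), 0.02)
  # strong effect in bins 10:20 -> mask covers the window
  eff <- null_rates
  eff[, lab == "side", 10:20] <- eff[, lab == "side", 10:20] + 3
  pme <- permutation_mask(as_rate_tensor(eff), lab, "side", n_perm = 2000,
                          alpha = 0.001, min_consec = 2, seed = 5)
  expect_gte(mean(pme$encodes), 0.95)
  expect_gte(mean(pme$mask[, 12:18]), 0.9)
  expect_lte(mean(pme$mask[, c(1:7, 24:30)]), 0.05)
  expect_error(permutation_mask(rt, lab, "side", n_perm = 100,
                                alpha = 0.001), "1/alpha")
})

test_that("selectivity classes are recovered on a designed population", {
  ses <- session_small()
  rt <- smooth_rates(ses$spikes, ses$trials, window = c(-1800, 1500))
  res <- single_unit_selectivity(rt, ses$trials, n_perm = 1000,
                                 alpha = 0.005, min_consec = 2, seed = 6)
  cnt <- classify_selectivity(res)
  design <- table(factor(ses$design, levels = levels(res$selectivity_class)))
  agree <- mean(as.character(res$selectivity_class) == ses$design)
  expect_gte(agree, 0.75)
  expect_gte(cnt[["grip_only"]] + cnt[["mixed"]],
             0.8 * (design[["grip_only"]] + design[["mixed"]]))
  # all-null population: per-parameter false-mask rate stays near nominal
  nullpop <- make_population(0, 0, 0, 40, seed = 31)
  spn <- simulate_spikes(ses$trials, nullpop, seed = 44)
  rtn <- smooth_rates(spn, ses$trials, window = c(-1800, 1500))
  resn <- single_unit_selectivity(rtn, ses$trials, n_perm = 1000,
                                  alpha = 0.001, min_consec = 2, seed = 6)
  expect_lte(sum(resn$grip$encodes), 4)
  expect_lte(sum(resn$force$encodes), 4)
})

test_that("the permuted chi-square marginal test is calibrated and powerful", {
  set.seed(9)
  n_units <- 100
  # type-I error across independent draws, alpha = 0.01
  n_sim <- 500
  rej <- logical(n_sim)
  for (s in seq_len(n_sim)) {
    g <- matrix(runif(n_units), ncol = 1)
    f <- matrix(runif(n_units), ncol = 1)
    rej[s] <- marginal_independence_test(g, f, n_perm = 400,
                                         seed = s)$p[1] < 0.01
  }
  expect_gte(mean(rej), 0.5 * 0.01)
  expect_lte(mean(rej), 2 * 0.01)
  # perfect dependence: force == grip
  g <- matrix(runif(n_units), ncol = 1)
  dep <- marginal_independence_test(g, g, n_perm = 400, seed = 1)
  expect_lt(dep$p[1], 0.01)
  # degenerate histogram
  one <- matrix(rep(0.55, 25), ncol = 1)
  expect_error(marginal_independence_test(one, one, n_perm = 10, seed = 1),
               "degenerate")
  expect_error(marginal_independence_test(matrix(runif(10), ncol = 1),
                                          matrix(runif(10), ncol = 1)),
               ">= 20 units")
})

test_that("ellipse angles match analytic axis orientations", {
  # grip varies, force constant (plus tiny jitter) -> vertical, 90 degrees
  set.seed(2)
  y <- runif(50); x <- rep(0.5, 50) + rnorm(50, 0, 1e-6)
  expect_equal(ellipse_angle(x, y)$theta_deg, 90, tolerance = 0.1)
  # points on y = x -> 45 degrees
  v <- runif(50)
  expect_equal(ellipse_angle(v + rnorm(50, 0, 1e-7), v)$theta_deg, 45,
               tolerance = 0.1)
  # random Gaussian with known covariance -> analytic eigenvector angle
  S <- matrix(c(2, 0.8, 0.8, 1), 2)
  P <- MASS::mvrnorm(4000, c(0, 0), S)
  got <- ellipse_angle(P[, 1], P[, 2])
  ev <- eigen(S)$vectors[, 1]
  want <- (atan2(ev[2], ev[1]) * 180 / pi) %% 180
  expect_equal(got$theta_deg, want, tolerance = 3)
  # 95% ellipse semi-axes follow the chi-square radius
  expect_equal(got$semi_axes,
               sqrt(qchisq(0.95, 2) * eigen(cov(P))$values),
               tolerance = 1e-8)
  expect_error(ellipse_angle(c(1, 2), c(1, 2)), ">= 3 points")
})

test_that("strength correlation flags real unit-level coupling only", {
  set.seed(12)
  n_units <- 80; n_bins <- 25
  shared <- matrix(rnorm(n_units * n_bins), n_units)
  dg <- 0.8 * shared + 0.2 * matrix(rnorm(n_units * n_bins), n_units)
  df_ <- 0.8 * shared + 0.2 * matrix(rnorm(n_units * n_bins), n_units)
  pow <- strength_correlation(dg, df_, n_shuffle = 1000, alpha = 0.001,
                              seed = 3)
  expect_gt(mean(pow$mask), 0.9)
  # independent series: mask essentially empty
  ind <- strength_correlation(matrix(rnorm(n_units * n_bins), n_units),
                              matrix(rnorm(n_units * n_bins), n_units),
                              n_shuffle = 1000, alpha = 0.001, seed = 3)
  expect_lte(mean(ind$mask), 0.05)
  # r of a series with itself is 1
  self <- strength_correlation(dg, dg, n_shuffle = 100, alpha = 0.001,
                               seed = 1)
  expect_equal(unname(self$r), rep(1, n_bins))
})

test_that("cross-temporal correlation finds a constructed lag ridge", {
  set.seed(7)
  n_units <- 60; n_bins <- 40
  centers <- seq(0, by = 20, length.out = n_bins)
  dg <- matrix(rnorm(n_units * n_bins), n_units)
  # force delta = grip delta shifted by +200 ms (10 bins)
  df_ <- cbind(matrix(rnorm(n_units * 10), n_units),
               dg[, 1:(n_bins - 10)])
  ct <- cross_temporal_correlation(dg, df_, centers,
                                   lags_ms = seq(-400, 400, 20),
                                   n_shuffle = 300, alpha = 0.01, seed = 2)
  ridge <- which.max(apply(abs(ct$r), 2, mean, na.rm = TRUE))
  expect_equal(ct$lags_ms[ridge], 200)
  expect_gt(mean(ct$mask[, ridge], na.rm = TRUE), 0.5)
  # lag 0 reproduces the zero-lag strength correlation exactly
  sc <- strength_correlation(dg, df_, n_shuffle = 10, seed = 1)
  expect_equal(ct$r[, ct$lags_ms == 0], sc$r)
  # independent series: sparse significance
  ind <- cross_temporal_correlation(
    matrix(rnorm(n_units * n_bins), n_units),
    matrix(rnorm(n_units * n_bins), n_units), centers,
    lags_ms = seq(-200, 200, 20), n_shuffle = 300, alpha = 0.01, seed = 4)
  expect_lte(mean(ind$mask, na.rm = TRUE), 0.05)
})
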