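test_that("marginalized parts reconstruct the centered tensor exactly", {
  set.seed(4)
  X <- array(rnorm(20 * 2 * 2 * 15), c(20, 2, 2, 15))
  m <- marginalize(X)
  expect_equal(m$centered,
               m$time + m$grip + m$force + m$interaction,
               tolerance = 1e-12)
  # constant over conditions -> condition parts vanish exactly
  Xc <- array(rep(rnorm(20 * 15), times = 4), c(20, 15, 2, 2))
  Xc <- aperm(Xc, c(1, 3, 4, 2))
  mc <- marginalize(Xc)
  expect_equal(max(abs(mc$grip)), 0)
  expect_equal(max(abs(mc$force)), 0)
  expect_equal(max(abs(mc$interaction)), 0)
})

test_that("an additively constructed tensor is demixed exactly", {
  X <- planted_tensor(noise_sd = 0, seed = 2)
  m <- marginalize(X)
  split <- marginal_variance_split(X)
  expect_equal(unname(split),
               c(90, 6, 2, 2), tolerance = 1e-8)
  # each recovered part matches the construction's own marginal
  expect_equal(m$time + m$grip + m$force + m$interaction, m$centered,
               tolerance = 1e-12)
})

test_that("single-marginalization dPCA with mu = 0 reduces to PCA", {
  set.seed(6)
  n_units <- 25; n_time <- 30
  M <- matrix(rnorm(n_units * n_time), n_units)  # unit x time pattern
  X <- array(0, c(n_units, 2, 2, n_time))
  for (g in 1:2) for (f in 1:2) X[, g, f, ] <- M
  fit <- fit_dpca(X, n_components = 5, mu = 0)
  tab <- fit$components
  expect_true(all(tab$marginalization[tab$evar_pct > 1e-8] == "time"))
  top <- fit$encoder[, tab$component[tab$marginalization == "time"][1:3]]
  Mc <- M - rowMeans(M)
  pc <- svd(Mc)$u[, 1:3]
  # principal angles between the two 3-d subspaces < 1 degree
  ang <- acos(pmin(svd(crossprod(top, pc))$d, 1)) * 180 / pi
  expect_lt(max(ang), 1)
})

test_that("dPCA recovers a planted grip axis and variance split under noise", {
  X <- planted_tensor(n_units = 40, n_time = 50, noise_sd = 0.02, seed = 8)
  # mild ridge: with observation noise the unregularized decoder whitens
  # against near-zero variance directions
  fit <- fit_dpca(X, n_components = 5,
                  mu = 1e-3 * sum(marginalize(X)$centered^2))
  ev <- explained_variance(fit)
  expect_true(all(ev$marginalization >= 0))
  expect_lte(sum(ev$marginalization), 100 + 1e-6)
  split <- ev$marginalization[c("time", "grip", "force", "interaction")]
  expect_lt(max(abs(as.numeric(split) - c(90, 6, 2, 2))), 2)
  tab <- fit$components
  gdec <- fit$decoder[, tab$component[tab$marginalization == "grip"][1]]
  planted <- attr(X, "axes")$grip
  expect_gte(abs(cor(gdec, planted)), 0.95)
  expect_error(fit_dpca(X, mu = -1), "mu")
})

test_that("ridge shrinkage drives explained variance to zero", {
  X <- planted_tensor(seed = 3)
  total <- sum(marginalize(X)$centered^2)
  big <- fit_dpca(X, n_components = 3, mu = 1e6 * total)
  expect_lt(sum(explained_variance(big)$marginalization), 1)
})

test_that("component classifiers decode planted codes and stay silent on null", {
  set.seed(11)
  tt <- tiny_trials(10)
  n_units <- 20; nb <- 40
  centers <- seq(-1500, 1500, length.out = nb)
  axis <- rnorm(n_units); axis <- axis / sqrt(sum(axis^2))
  s <- ifelse(tt$grip == "side", 1, -1)
  base <- array(rnorm(n_units * nrow(tt) * nb, 10, 0.5),
                c(n_units, nrow(tt), nb))
  code_bins <- which(centers > -1000 & centers < 800)
  for (b in code_bins) base[, , b] <- base[, , b] + outer(axis * 2, s)
  rt <- as_rate_tensor(base, centers)
  X <- condition_tensor(rt, tt)
  fit <- fit_dpca(X, n_components = 3, mu = 0)
  dec <- component_classifier(fit, rt, tt, "grip", n_iter = 30,
                              n_shuffle = 50, min_consec = 5, seed = 2)
  expect_gte(mean(dec$accuracy[code_bins]), 0.95)
  expect_gte(mean(dec$mask[code_bins]), 0.9)
  expect_lte(mean(dec$mask[-code_bins]), 0.2)
  # perfectly separable projections give accuracy 1 inside the code window
  expect_true(all(dec$accuracy[code_bins][3:(length(code_bins) - 3)] > 0.99))
  # label-shuffled data: empty mask almost always
  set.seed(3)
  null_masks <- vapply(1:8, function(k) {
    rtn <- as_rate_tensor(array(rnorm(n_units * nrow(tt) * nb, 10, 0.5),
                                c(n_units, nrow(tt), nb)), centers)
    Xn <- condition_tensor(rtn, tt)
    fn <- fit_dpca(Xn, n_components = 2, mu = 0)
    dn <- component_classifier(fn, rtn, tt, "grip", n_iter = 15,
                               n_shuffle = 50, min_consec = 5, seed = k)
    any(dn$mask)
  }, TRUE)
  expect_lte(mean(null_masks), 0.125)
})

test_that("cross-validated mu selection returns a usable penalty", {
  ses <- session_small()
  rt <- smooth_rates(ses$spikes, ses$trials, step_ms = 100,
                     window = c(-1000, 1000))
  mu <- select_dpca_mu(rt, ses$trials, grid = 10^c(-6, -4), n_components = 3,
                       n_folds = 3, seed = 1)
  expect_true(is.finite(mu) && mu >= 0)
  expect_s3_class(fit_dpca(condition_tensor(rt, ses$trials), 5, mu),
                  "dpca_model")
})
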