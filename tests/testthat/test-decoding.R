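test_that("the population decoder is perfect on separable data, at chance on shuffled", {
  set.seed(21)
  labels <- rep(c("side", "precision"), each = 30)
  # widely separated class means, tiny noise -> 100% in every bin
  sep <- planted_binned(12, labels, function(b) rep(1, 12), d = 10,
                        noise_sd = 0.1, n_bins = 8, seed = 2)
  acc <- decode_timecourse(sep, labels, n_rep = 10, seed = 3)
  expect_true(all(acc == 1))
  # label shuffle -> mean accuracy within the chance CI
  noise <- planted_binned(12, labels, function(b) rep(0, 12), d = 0,
                          noise_sd = 1, n_bins = 10, seed = 4)
  accn <- decode_timecourse(noise, sample(labels), n_rep = 25, seed = 5)
  expect_gt(mean(accn), 0.45)
  expect_lt(mean(accn), 0.55)
  expect_error(decode_timecourse(sep, rep(c("a", "b"), c(55, 5)), seed = 1),
               "class")
})

test_that("decoding accuracy is monotone in planted effect size", {
  labels <- rep(c("side", "precision"), each = 30)
  gains <- c(0, 0.6, 1.5, 5)
  mean_acc <- vapply(gains, function(d) {
    rt <- planted_binned(15, labels, function(b) rep(1, 15) / sqrt(15),
                         d = d, noise_sd = 1, n_bins = 6, seed = 7)
    mean(decode_timecourse(rt, labels, n_rep = 15, seed = 8))
  }, 0)
  expect_true(all(diff(mean_acc) > -0.03))  # nondecreasing within noise
  expect_lt(mean_acc[1], 0.6)
  expect_gt(mean_acc[4], 0.95)
})

test_that("cross-temporal matrices separate static from dynamic codes", {
  set.seed(31)
  labels <- rep(c("side", "precision"), each = 30)
  n_units <- 20; nb <- 16
  const_axis <- rnorm(n_units)
  const_axis <- const_axis / sqrt(sum(const_axis^2))
  static_rt <- planted_binned(n_units, labels,
                              function(b) const_axis, d = 5, noise_sd = 1,
                              n_bins = nb, seed = 1)
  set.seed(77)
  axes <- replicate(nb, { v <- rnorm(n_units); v / sqrt(sum(v^2)) })
  dynamic_rt <- planted_binned(n_units, labels,
                               function(b) axes[, b], d = 5, noise_sd = 1,
                               n_bins = nb, seed = 1)
  Ms <- cross_temporal_matrix(static_rt, labels, n_rep = 10, seed = 2)
  Md <- cross_temporal_matrix(dynamic_rt, labels, n_rep = 10, seed = 2)
  off <- row(Ms) != col(Ms)
  expect_gt(mean(Ms[off]), 0.9)                  # generalizes across bins
  expect_lt(mean(Md[off]), 0.62)                 # does not generalize
  expect_gt(mean(diag(Md)), 0.85)                # but decodes on-diagonal
  # determinism under a fixed seed
  expect_identical(Ms, cross_temporal_matrix(static_rt, labels, n_rep = 10,
                                             seed = 2))
})

test_that("the static-bin rule is the AND of its three conditions plus runs", {
  set.seed(41)
  nb <- 10
  nulls <- array(rnorm(200 * nb * nb, 0.5, 0.01), c(200, nb, nb))
  M <- matrix(0.5, nb, nb)
  M[3:6, 3:6] <- 0.95       # a solid static block
  M[9, 9] <- 0.95           # significant diagonal, isolated
  M[9, 1] <- 0.95           # isolated off-diagonal cell (run length 1)
  diag(M)[c(3:6, 9)] <- 0.95
  diag(M)[1] <- 0.95
  sb <- static_bins(M, nulls, chance = 0.5, min_consec = 2)
  expect_true(all(sb$static[3:6, 3:6] == 1))
  expect_equal(sb$static[9, 1], 0)     # killed by the run rule
  # static cells are a subset of every individual condition
  st <- sb$static == 1
  expect_true(all(sb$conditions$cluster[st]))
  expect_true(all(sb$conditions$cell[st]))
  expect_true(all(sb$conditions$diagonal[st]))
  # all-chance matrix yields an empty static matrix
  sb0 <- static_bins(matrix(0.5, nb, nb), nulls, chance = 0.5)
  expect_true(all(sb0$static == 0))
  expect_error(static_bins(M, NULL), "null")
})

test_that("generalization index counts static train bins per epoch", {
  centers <- seq(-1500, 1500, length.out = 16)
  epochs <- list(preparation = c(-1400, -200), execution = c(0, 1000))
  all1 <- matrix(1, 16, 16)
  gi1 <- generalization_index(all1, centers, epochs)
  expect_true(all(gi1 == 1))
  gi0 <- generalization_index(matrix(0, 16, 16), centers, epochs)
  expect_true(all(gi0 == 0))
  # diagonal-only static matrix: GI_prep nonzero only inside preparation
  gid <- generalization_index(diag(16), centers, epochs)
  prep_bins <- which(centers >= -1400 & centers <= -200)
  expect_equal(unname(gid["preparation", prep_bins]),
               rep(1 / length(prep_bins), length(prep_bins)))
  expect_true(all(gid["preparation", -prep_bins] == 0))
  expect_error(generalization_index(all1, centers,
                                    list(preparation = c(5, 6),
                                         execution = c(0, 1000))),
               "< 2 bins")
})

test_that("null calibration: shuffled labels almost never yield static bins", {
  set.seed(51)
  labels <- rep(c("side", "precision"), each = 30)
  rt <- planted_binned(10, labels, function(b) rep(0, 10), d = 0,
                       noise_sd = 1, n_bins = 8, seed = 9)
  M <- cross_temporal_matrix(rt, labels, n_rep = 5, seed = 1)
  nulls <- null_matrices(rt, labels, n_null = 60, seed = 2)
  sb <- static_bins(M, nulls, chance = 0.5)
  expect_lte(mean(sb$static), 0.02)
})
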