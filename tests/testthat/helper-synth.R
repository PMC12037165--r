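# Shared fixtures and independent oracles, built in code at test time.

# exhaustive pairwise auROC oracle: P(x > y) + 0.5 P(x == y) over all pairs
brute_auroc <- function(x, y) {
  s <- 0
  for (xi in x) s <- s + sum(xi > y) + 0.5 * sum(xi == y)
  s / (length(x) * length(y))
}

# exhaustive rank-sum U oracle (same pairwise count)
brute_U <- function(x, y) {
  s <- 0
  for (xi in x) s <- s + sum(xi > y) + 0.5 * sum(xi == y)
  s
}

# wrap a units x trials x bins array as a rate tensor
as_rate_tensor <- function(a, centers = seq_len(dim(a)[3]),
                           alignment = "movement_on") {
  structure(list(rates = a, bin_centers = centers, alignment = alignment,
                 kernel = list(type = "direct")),
            class = "rate_tensor")
}

# minimal hand-built trial table (one subject, deterministic events)
tiny_trials <- function(n_per_cond = 4, rt = 150, mt = 120) {
  generate_trials(task_config(n_trials_per_condition = n_per_cond,
                              rt_mean_ms = rt, rt_sd_ms = 0,
                              mt_mean_ms = mt, mt_sd_ms = 0,
                              hold_jitter_sd_ms = 0, seed = 99))
}

# spike_data from an explicit list-of-lists of spike times
as_spike_data <- function(spk_by_unit, trial_ids) {
  structure(list(
    units = data.frame(unit_id = seq_along(spk_by_unit), included = TRUE),
    spikes = spk_by_unit, trial_ids = trial_ids),
    class = "spike_data")
}

# small session with planted grip/force structure, cached per test run
session_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pop <- make_population(n_grip = 8, n_mixed = 4, n_force = 2,
                             n_null = 10, gain = 0.6, seed = 202)
      cfg <- task_config(n_trials_per_condition = 12, seed = 303)
      cache <<- c(simulate_session(cfg, pop),
                  list(design = attr(pop, "class_design")))
    }
    cache
  }
})

# constructed condition tensor with an exact variance split:
# unit x 2 x 2 x time built from orthogonal time/grip/force/interaction parts
planted_tensor <- function(n_units = 30, n_time = 40,
                           weights = c(time = 90, grip = 6, force = 2,
                                       interaction = 2),
                           noise_sd = 0, seed = 1) {
  set.seed(seed)
  rand_unit <- function() {
    v <- rnorm(n_units); v / sqrt(sum(v^2))
  }
  z <- function() sin(seq(0, 3 * pi, length.out = n_time)) +
    rnorm(n_time, 0, 0.2)
  axes <- list(time = rand_unit(), grip = rand_unit(), force = rand_unit(),
               interaction = rand_unit())
  # orthogonalize the axes so parts cannot leak into each other's unit space
  A <- qr.Q(qr(cbind(axes$time, axes$grip, axes$force, axes$interaction)))
  axes <- list(time = A[, 1], grip = A[, 2], force = A[, 3],
               interaction = A[, 4])
  zt <- z(); zg <- z(); zf <- z(); zi <- z()
  zt <- zt - mean(zt); zg <- zg - mean(zg); zf <- zf - mean(zf)
  zi <- zi - mean(zi)
  norm2 <- function(v) sqrt(sum(v^2))
  X <- array(0, c(n_units, 2, 2, n_time))
  sg <- c(1, -1); sf <- c(1, -1)
  for (g in 1:2) for (f in 1:2) {
    X[, g, f, ] <- sqrt(weights["time"]) * outer(axes$time, zt / norm2(zt)) +
      sqrt(weights["grip"]) * sg[g] * outer(axes$grip, zg / norm2(zg)) +
      sqrt(weights["force"]) * sf[f] * outer(axes$force, zf / norm2(zf)) +
      sqrt(weights["interaction"]) * sg[g] * sf[f] *
        outer(axes$interaction, zi / norm2(zi))
  }
  if (noise_sd > 0) X <- X + array(rnorm(length(X), 0, noise_sd), dim(X))
  dimnames(X) <- list(NULL, c("side", "precision"), c("low", "high"), NULL)
  attr(X, "axes") <- axes
  X
}

# direct construction of binned "rates" with a class-dependent mean code:
# code_fun(bin) returns a unit-space pattern; separation d scales it
planted_binned <- function(n_units, labels, code_fun, d = 1, noise_sd = 1,
                           n_bins = 20, seed = 1) {
  set.seed(seed)
  nt <- length(labels)
  s <- ifelse(labels == labels[1], 1, -1)
  a <- array(rnorm(n_units * nt * n_bins, 0, noise_sd),
             c(n_units, nt, n_bins))
  for (b in seq_len(n_bins)) {
    pat <- code_fun(b)
    a[, , b] <- a[, , b] + outer(pat, s) * d / 2
  }
  as_rate_tensor(a, centers = seq(-950, 950, length.out = n_bins))
}
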