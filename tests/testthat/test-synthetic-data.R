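test_that("generated trial tables are balanced, ordered and reproducible", {
  cfg <- task_config(n_trials_per_condition = 30, seed = 7)
  tt <- generate_trials(cfg)
  expect_equal(nrow(tt), 120)
  expect_true(all(table(tt$grip, tt$force) == 30))
  expect_true(all(tt$correct))
  # event monotonicity on every trial
  for (r in seq_len(nrow(tt))) {
    v <- as.numeric(tt[r, c("switch_on", "cue_on", "cue_off", "go",
                            "movement_on", "touch", "pull_on", "release")])
    expect_true(all(diff(v) >= 0))
    expect_true(all(diff(v)[c(1, 2, 3, 5, 7)] > 0))
  }
  # determinism under a fixed seed
  expect_identical(tt, generate_trials(cfg))
  # degenerate RT distribution
  t0 <- generate_trials(task_config(n_trials_per_condition = 5,
                                    rt_mean_ms = 150, rt_sd_ms = 0, seed = 1))
  expect_true(all(t0$movement_on - t0$go == 150))
  expect_error(task_config(delay_ms = -5), "positive duration")
})

test_that("event monotonicity holds across random configurations", {
  for (s in 1:10) {
    set.seed(s)
    cfg <- task_config(n_trials_per_condition = 3,
                       rt_mean_ms = runif(1, 100, 400),
                       rt_sd_ms = runif(1, 0, 200),
                       mt_mean_ms = runif(1, 80, 400),
                       mt_sd_ms = runif(1, 0, 150), seed = s)
    tt <- generate_trials(cfg)
    expect_silent(validate_trial_table(tt))
  }
})

test_that("Poisson spike counts match the specified rates", {
  tt <- tiny_trials(10)
  # 20 Hz flat unit: empirical rate within 3 SE of Poisson expectation
  unit <- neuron_spec(20)
  sp <- simulate_spikes(tt, list(unit), seed = 11)
  total_T <- sum(tt$trial_end) / 1000
  n <- sum(lengths(sp$spikes[[1]]))
  expect_lt(abs(n - 20 * total_T), 3 * sqrt(20 * total_T))
  # zero baseline -> silence
  sp0 <- simulate_spikes(tt, list(neuron_spec(0)), seed = 11)
  expect_equal(sum(lengths(sp0$spikes[[1]])), 0)
  # determinism
  sp2 <- simulate_spikes(tt, list(unit), seed = 11)
  expect_identical(sp$spikes, sp2$spikes)
})

test_that("a windowed grip gain of 0.5 produces a 3:1 preferred rate ratio", {
  tt <- tiny_trials(30)
  unit <- neuron_spec(20, grip_gain = 0.5,
                      grip_window = list(event = "movement_on", on = 0,
                                         off = 600))
  sp <- simulate_spikes(tt, list(unit), seed = 4)
  in_win <- function(r) {
    ts <- sp$spikes[[1]][[r]] - tt$movement_on[r]
    sum(ts >= 0 & ts <= 600)
  }
  counts <- vapply(seq_len(nrow(tt)), in_win, 0)
  side <- sum(counts[tt$grip == "side"])
  prec <- sum(counts[tt$grip == "precision"])
  # expected ratio (1 + 0.5) : (1 - 0.5) = 3; Poisson noise around it
  expect_gt(side / prec, 2.4)
  expect_lt(side / prec, 3.7)
})

test_that("no-effect units converge to baseline mean rate", {
  tt <- generate_trials(task_config(n_trials_per_condition = 50, seed = 21))
  sp <- simulate_spikes(tt, list(neuron_spec(15)), seed = 9)
  total_T <- sum(tt$trial_end) / 1000
  n <- sum(lengths(sp$spikes[[1]]))
  expect_lt(abs(n / total_T - 15), 3 * sqrt(15 * total_T) / total_T)
})

test_that("force traces ramp to the commanded level and are flat pre-pull", {
  tt <- tiny_trials(10)
  grid <- seq(-2000, 2000, by = 20)
  f0 <- simulate_force(tt, force_spec(noise_sd = 0), grid, seed = 1)
  for (r in seq_len(nrow(tt))) {
    lev <- if (tt$force[r] == "high") 2 else 1
    plateau <- grid + tt$movement_on[r] >= tt$pull_on[r] + 150 &
      grid + tt$movement_on[r] <= tt$release[r]
    if (any(plateau)) expect_equal(unname(f0[r, plateau]),
                                   rep(lev, sum(plateau)))
    pre <- grid + tt$movement_on[r] < tt$pull_on[r]
    expect_true(all(f0[r, pre] == 0))
  }
  expect_gt(mean(f0[tt$force == "high", ]), mean(f0[tt$force == "low", ]))
  # noisy pre-go segment is zero-mean within a Gaussian CI
  fn <- simulate_force(tt, force_spec(noise_sd = 0.1), grid, seed = 2)
  pre <- grid < -500  # all pull onsets are well after movement onset
  m <- mean(fn[, pre])
  se <- 0.1 / sqrt(sum(pre) * nrow(tt))
  expect_lt(abs(m), 4 * se)
  # determinism of the whole session
  cfg <- task_config(n_trials_per_condition = 3, seed = 5)
  pop <- make_population(2, 1, 1, 1, seed = 5)
  s1 <- simulate_session(cfg, pop)
  s2 <- simulate_session(cfg, pop)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$force, s2$force)
})

test_that("force_spec rejects non-increasing levels", {
  expect_error(force_spec(low_level = 2, high_level = 1), "high_level")
})
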