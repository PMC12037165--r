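# Synthetic delayed reach-to-grasp sessions: task-event tables, inhomogeneous
# Poisson spike trains with configurable grip/force/time coding, and pulling
# force traces. Every downstream stage of the pipeline is testable on these
# without any recorded data.

#' Task configuration for the delayed reach-to-grasp simulator
#'
#' Encodes the trial timeline: the hand rests on a table switch, a grip cue
#' (side vs precision) appears after `switch_to_cue_ms` and lasts
#' `cue_duration_ms`, a delay follows, then the go cue (which also instructs
#' low vs high pulling force), the reach (reaction time), object touch
#' (movement time), pull onset, a hold of at least `pull_hold_ms`, release and
#' reward. Reaction and movement times are drawn from truncated normal
#' distributions (lower bound 20 ms).
#'
#' @param n_trials_per_condition Correct trials per grip x force cell.
#' @param switch_to_cue_ms Switch-on to grip-cue onset (ms).
#' @param cue_duration_ms Grip-cue display duration (ms).
#' @param delay_ms Cue offset to go cue (ms).
#' @param rt_mean_ms,rt_sd_ms Reaction-time mean and SD (ms).
#' @param mt_mean_ms,mt_sd_ms Movement-time mean and SD (ms).
#' @param touch_to_pull_ms Object touch to pull onset (ms).
#' @param pull_hold_ms Minimum pull-hold duration (ms).
#' @param hold_jitter_sd_ms SD of extra (nonnegative) hold time beyond the
#'   minimum (ms).
#' @param reward_delay_ms Release to reward (ms).
#' @param subject Subject label carried into the trial table.
#' @param seed Integer RNG seed.
#' @return An object of class `task_config`.
#' @export
task_config <- function(n_trials_per_condition = 30,
                        switch_to_cue_ms = 800,
                        cue_duration_ms = 300,
                        delay_ms = 1000,
                        rt_mean_ms = 150, rt_sd_ms = 48,
                        mt_mean_ms = 123, mt_sd_ms = 80,
                        touch_to_pull_ms = 100,
                        pull_hold_ms = 500,
                        hold_jitter_sd_ms = 50,
                        reward_delay_ms = 200,
                        subject = "sim",
                        seed = 1L) {
  cfg <- list(
    n_trials_per_condition = as.integer(n_trials_per_condition),
    switch_to_cue_ms = switch_to_cue_ms, cue_duration_ms = cue_duration_ms,
    delay_ms = delay_ms, rt_mean_ms = rt_mean_ms, rt_sd_ms = rt_sd_ms,
    mt_mean_ms = mt_mean_ms, mt_sd_ms = mt_sd_ms,
    touch_to_pull_ms = touch_to_pull_ms, pull_hold_ms = pull_hold_ms,
    hold_jitter_sd_ms = hold_jitter_sd_ms, reward_delay_ms = reward_delay_ms,
    subject = subject, seed = as.integer(seed))
  dur <- c("switch_to_cue_ms", "cue_duration_ms", "delay_ms", "rt_mean_ms",
           "mt_mean_ms", "touch_to_pull_ms", "pull_hold_ms")
  for (d in dur)
    if (!is.numeric(cfg[[d]]) || cfg[[d]] <= 0)
      stop("task_config: '", d, "' must be a positive duration", call. = FALSE)
  if (cfg$rt_sd_ms < 0 || cfg$mt_sd_ms < 0 || cfg$hold_jitter_sd_ms < 0)
    stop("task_config: SDs must be nonnegative", call. = FALSE)
  if (cfg$n_trials_per_condition < 1)
    stop("task_config: n_trials_per_condition must be >= 1", call. = FALSE)
  structure(cfg, class = "task_config")
}

#' Generate a balanced trial-event table
#'
#' Produces `4 * n_trials_per_condition` correct trials, fully crossing grip
#' (side, precision) with force (low, high). All event times are in ms on the
#' per-trial clock with `switch_on = 0`.
#'
#' @param config A [task_config()].
#' @return A `data.frame` of class `trial_table`: `trial_id`, `subject`,
#'   `grip`, `force`, `correct`, and event columns `switch_on`, `cue_on`,
#'   `cue_off`, `go`, `movement_on`, `touch`, `pull_on`, `release`, `reward`,
#'   plus `trial_end` (end of the simulated recording).
#' @export
generate_trials <- function(config) {
  stopifnot(inherits(config, "task_config"))
  n <- config$n_trials_per_condition
  grid <- expand.grid(grip = c("side", "precision"),
                      force = c("low", "high"),
                      rep = seq_len(n), stringsAsFactors = FALSE)
  nt <- nrow(grid)
  with_seed(child_seed(config$seed, "trials"), {
    rt <- rtruncnorm_lower(nt, config$rt_mean_ms, config$rt_sd_ms)
    mt <- rtruncnorm_lower(nt, config$mt_mean_ms, config$mt_sd_ms)
    hold <- config$pull_hold_ms + abs(rnorm(nt, 0, config$hold_jitter_sd_ms))
  })
  cue_on <- config$switch_to_cue_ms
  cue_off <- cue_on + config$cue_duration_ms
  go <- cue_off + config$delay_ms
  movement_on <- go + rt
  touch <- movement_on + mt
  pull_on <- touch + config$touch_to_pull_ms
  release <- pull_on + hold
  reward <- release + config$reward_delay_ms
  tt <- data.frame(
    trial_id = seq_len(nt), subject = config$subject,
    grip = grid$grip, force = grid$force, correct = TRUE,
    switch_on = 0, cue_on = cue_on, cue_off = cue_off, go = go,
    movement_on = movement_on, touch = touch, pull_on = pull_on,
    release = release, reward = reward,
    trial_end = pmax(reward + 300, movement_on + 2100),
    stringsAsFactors = FALSE)
  class(tt) <- c("trial_table", "data.frame")
  validate_trial_table(tt)
  tt
}

#' Specify one simulated unit's rate model
#'
#' The instantaneous rate on trial clock time `t` is
#' `rectify(baseline_hz * time_profile(t - movement_on) *
#' (1 + grip_gain * s_g * in_grip_window) * (1 + force_gain * s_f *
#' in_force_window))`, with `s_g = +1` on side-grip trials and `-1` on
#' precision trials, and `s_f = +1` on high-force, `-1` on low-force trials.
#' Effects are multiplicative gains, so a unit with both gains zero is
#' condition independent by construction.
#'
#' @param baseline_hz Baseline rate (spikes/s).
#' @param time_profile Nonnegative gain function of time relative to movement
#'   onset (ms); defaults to a flat profile.
#' @param grip_gain,force_gain Signed multiplicative gains (sign = preferred
#'   condition).
#' @param grip_window,force_window Lists `list(event, on, off)` giving the
#'   effect window in ms relative to a trial event (e.g. `"cue_on"`,
#'   `"movement_on"`).
#' @return An object of class `neuron_spec`.
#' @export
neuron_spec <- function(baseline_hz,
                        time_profile = function(t) rep(1, length(t)),
                        grip_gain = 0,
                        grip_window = list(event = "movement_on", on = -Inf, off = Inf),
                        force_gain = 0,
                        force_window = list(event = "movement_on", on = -Inf, off = Inf)) {
  stopifnot(is.numeric(baseline_hz), baseline_hz >= 0, is.function(time_profile))
  structure(list(baseline_hz = baseline_hz, time_profile = time_profile,
                 grip_gain = grip_gain, grip_window = grip_window,
                 force_gain = force_gain, force_window = force_window),
            class = "neuron_spec")
}

#' Build a population of unit specifications by selectivity class
#'
#' Mirrors the observed selectivity structure: grip-only units, mixed
#' grip-and-force units, force-only units and condition-independent (null)
#' units. Under the `"static"` scheme each selective unit carries one long
#' effect window from the grip cue through object release; under `"dynamic"`
#' each unit gets a brief window with a random onset spanning the
#' perimovement period, so selectivity sweeps across the population.
#'
#' @param n_grip,n_mixed,n_force,n_null Unit counts per class.
#' @param scheme `"static"` or `"dynamic"` effect windows.
#' @param gain Absolute multiplicative gain of each effect (0.5 gives a 3:1
#'   rate ratio between preferred and anti-preferred conditions).
#' @param baseline_range Uniform range for baseline rates (spikes/s).
#' @param time_bump If TRUE every unit also gets a condition-independent
#'   perimovement activation bump of random amplitude.
#' @param seed Integer seed.
#' @return List of [neuron_spec()] objects, with attribute `"class_design"`
#'   giving each unit's planted class.
#' @export
make_population <- function(n_grip = 40, n_mixed = 20, n_force = 2,
                            n_null = 38, scheme = c("static", "dynamic"),
                            gain = 0.5, baseline_range = c(5, 25),
                            time_bump = TRUE, seed = 1L) {
  scheme <- match.arg(scheme)
  classes <- rep(c("grip_only", "mixed", "force_only", "none"),
                 c(n_grip, n_mixed, n_force, n_null))
  n <- length(classes)
  with_seed(child_seed(seed, "population"), {
    base <- runif(n, baseline_range[1], baseline_range[2])
    sgn_g <- sample(c(-1, 1), n, replace = TRUE)
    sgn_f <- sample(c(-1, 1), n, replace = TRUE)
    amp <- if (time_bump) runif(n, 0, 1) else rep(0, n)
    ctr <- runif(n, -100, 400)
    wid <- runif(n, 300, 600)
    dyn_on <- runif(n, -500, 800)
    dyn_on_f <- runif(n, -500, 800)
  })
  window_for <- function(i, which) {
    if (scheme == "static") {
      # from grip-cue onset through ~object release
      list(event = "cue_on", on = 0, off = 3500)
    } else {
      on <- if (which == "grip") dyn_on[i] else dyn_on_f[i]
      list(event = "movement_on", on = on, off = on + 300)
    }
  }
  lapply(seq_len(n), function(i) {
    a <- amp[i]; c0 <- ctr[i]; w <- wid[i]
    prof <- function(t) 1 + a * exp(-((t - c0) / w)^2)
    g <- if (classes[i] %in% c("grip_only", "mixed")) gain * sgn_g[i] else 0
    f <- if (classes[i] %in% c("force_only", "mixed")) gain * sgn_f[i] else 0
    neuron_spec(base[i], time_profile = prof,
                grip_gain = g, grip_window = window_for(i, "grip"),
                force_gain = f, force_window = window_for(i, "force"))
  }) -> pop
  attr(pop, "class_design") <- classes
  pop
}

# instantaneous rate (spikes/s) of `spec` at trial-clock times `t` on one trial
unit_rate <- function(spec, t, trial) {
  s_g <- if (trial$grip == "side") 1 else -1
  s_f <- if (trial$force == "high") 1 else -1
  r <- spec$baseline_hz * spec$time_profile(t - trial$movement_on)
  wg <- spec$grip_window
  in_g <- t >= trial[[wg$event]] + wg$on & t <= trial[[wg$event]] + wg$off
  r <- r * (1 + spec$grip_gain * s_g * in_g)
  wf <- spec$force_window
  in_f <- t >= trial[[wf$event]] + wf$on & t <= trial[[wf$event]] + wf$off
  r <- r * (1 + spec$force_gain * s_f * in_f)
  pmax(r, 0)
}

#' Simulate spike trains for a population on a trial table
#'
#' Each unit x trial spike train is drawn from an inhomogeneous Poisson
#' process by thinning against the per-trial rate maximum (evaluated on a 5 ms
#' grid with a 2% safety margin, exact for the piecewise-smooth rate models
#' used here).
#'
#' @param trials A `trial_table`.
#' @param neurons List of [neuron_spec()] (e.g. from [make_population()]).
#' @param seed Integer seed.
#' @return An object of class `spike_data`: `units` (data.frame with
#'   `unit_id`, `included`), `spikes` (list over units of lists over trials of
#'   sorted spike-time vectors, ms on the trial clock), `trial_ids`.
#' @export
simulate_spikes <- function(trials, neurons, seed = 1L) {
  stopifnot(inherits(trials, "trial_table"), nrow(trials) > 0)
  nu <- length(neurons)
  spikes <- vector("list", nu)
  with_seed(child_seed(seed, "spikes"), {
    for (u in seq_len(nu)) {
      spec <- neurons[[u]]
      spikes[[u]] <- lapply(seq_len(nrow(trials)), function(r) {
        trial <- trials[r, ]
        t_end <- trial$trial_end
        grid <- seq(0, t_end, by = 5)
        rmax <- 1.02 * max(unit_rate(spec, grid, trial))
        if (!is.finite(rmax) || rmax <= 0) return(numeric(0))
        n_cand <- rpois(1, rmax * t_end / 1000)
        if (n_cand == 0) return(numeric(0))
        cand <- runif(n_cand, 0, t_end)
        keep <- runif(n_cand) < unit_rate(spec, cand, trial) / rmax
        sort(cand[keep])
      })
    }
  })
  structure(list(
    units = data.frame(unit_id = seq_len(nu), included = TRUE),
    spikes = spikes, trial_ids = trials$trial_id),
    class = "spike_data")
}

#' Pulling-force trace specification
#'
#' @param low_level,high_level Plateau force for low/high force trials
#'   (arbitrary units); must satisfy `high_level > low_level > 0`.
#' @param ramp_ms Linear ramp duration after pull onset (and release decay).
#' @param noise_sd SD of additive Gaussian noise.
#' @return An object of class `force_spec`.
#' @export
force_spec <- function(low_level = 1, high_level = 2, ramp_ms = 150,
                       noise_sd = 0.05) {
  if (!(high_level > low_level && low_level > 0))
    stop("force_spec: need high_level > low_level > 0", call. = FALSE)
  structure(list(low_level = low_level, high_level = high_level,
                 ramp_ms = ramp_ms, noise_sd = noise_sd),
            class = "force_spec")
}

#' Simulate per-trial pulling-force traces
#'
#' The trace is ~0 before pull onset, ramps linearly over `ramp_ms` to the
#' condition's plateau, holds until release, decays back over `ramp_ms`, and
#' carries additive Gaussian noise. Traces are sampled on the same
#' movement-aligned clock as a rate tensor.
#'
#' @param trials A `trial_table` with `pull_on` and `release` times.
#' @param spec A [force_spec()].
#' @param bin_centers Time points (ms relative to movement onset).
#' @param seed Integer seed.
#' @return A trials x time matrix of class `force_traces` with attributes
#'   `bin_centers` and `force` (per-trial condition).
#' @export
simulate_force <- function(trials, spec, bin_centers = seq(-2000, 2000, by = 20),
                           seed = 1L) {
  stopifnot(inherits(trials, "trial_table"), inherits(spec, "force_spec"))
  nt <- nrow(trials)
  out <- matrix(0, nt, length(bin_centers))
  for (r in seq_len(nt)) {
    trial <- trials[r, ]
    t <- bin_centers + trial$movement_on  # trial clock
    lev <- if (trial$force == "high") spec$high_level else spec$low_level
    up <- pmin(pmax((t - trial$pull_on) / spec$ramp_ms, 0), 1)
    down <- pmin(pmax((t - trial$release) / spec$ramp_ms, 0), 1)
    out[r, ] <- lev * (up - down)
  }
  if (spec$noise_sd > 0)
    out <- out + with_seed(child_seed(seed, "force"),
                           matrix(rnorm(length(out), 0, spec$noise_sd),
                                  nrow = nt))
  structure(out, class = "force_traces", bin_centers = bin_centers,
            force = trials$force)
}

#' One-call synthetic session
#'
#' Convenience wrapper producing trials, spikes and force traces from one
#' seed, with per-stage child seeds.
#'
#' @param config A [task_config()].
#' @param neurons List of [neuron_spec()].
#' @param fspec A [force_spec()].
#' @param bin_centers Time grid for force traces (ms re movement onset).
#' @return List with `trials`, `spikes`, `force`.
#' @export
simulate_session <- function(config, neurons, fspec = force_spec(),
                             bin_centers = seq(-2000, 2000, by = 20)) {
  trials <- generate_trials(config)
  list(trials = trials,
       spikes = simulate_spikes(trials, neurons, seed = config$seed),
       force = simulate_force(trials, fspec, bin_centers, seed = config$seed))
}
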