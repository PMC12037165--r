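# Firing-rate estimation aligned to movement onset: a causal exponential
# filter on a fine 20 ms grid for single-unit statistics, and 100 ms binned
# counts on the coarser decoding grid.

#' Construct the default movement-aligned time grids
#'
#' The fine grid steps every `step_ms`; the decoding grid places 100 ms
#' windows with centers every 80 ms so that 51 centers span -2000..+2000 ms
#' (adjacent windows overlap by 20 ms).
#'
#' @param window Two-element ms window relative to movement onset.
#' @param step_ms Fine-grid step.
#' @return Numeric vector of bin centers.
#' @export
rate_grid <- function(window = c(-2000, 2000), step_ms = 20) {
  seq(window[1], window[2], by = step_ms)
}

#' @rdname rate_grid
#' @param spacing_ms Center spacing of the decoding grid.
#' @export
decoding_grid <- function(window = c(-2000, 2000), spacing_ms = 80) {
  seq(window[1], window[2], by = spacing_ms)
}

new_rate_tensor <- function(rates, bin_centers, alignment, kernel) {
  stopifnot(length(dim(rates)) == 3, dim(rates)[3] == length(bin_centers))
  structure(list(rates = rates, bin_centers = bin_centers,
                 alignment = alignment, kernel = kernel),
            class = "rate_tensor")
}

#' @export
print.rate_tensor <- function(x, ...) {
  d <- dim(x$rates)
  cat(sprintf("rate_tensor: %d units x %d trials x %d bins (%s, %s)\n",
              d[1], d[2], d[3], x$alignment,
              paste(names(x$kernel), unlist(x$kernel), sep = "=",
                    collapse = " ")))
  invisible(x)
}

# spike times of one unit/trial re-referenced to the alignment event
aligned_spikes <- function(ts, trial, alignment) ts - trial[[alignment]]

#' Smoothed firing rates with a causal exponential filter
#'
#' The rate at grid time `t` is `sum over spikes s <= t of
#' (1/tau) exp(-(t - s)/tau)` (unit-area kernel, so the trace is in
#' spikes/s), evaluated every `step_ms` and aligned to `alignment`
#' (movement onset by default). The kernel is truncated at `5 * tau`
#' (<1% mass loss). Grid points falling outside the recorded trial are NA.
#'
#' @param spikes A `spike_data`.
#' @param trials The matching `trial_table`.
#' @param tau_ms Filter decay constant (ms).
#' @param step_ms Grid step (ms).
#' @param window Window in ms relative to the alignment event.
#' @param alignment Event column used as time zero.
#' @return A `rate_tensor` (units x trials x bins).
#' @export
smooth_rates <- function(spikes, trials, tau_ms = 100, step_ms = 20,
                         window = c(-2000, 2000), alignment = "movement_on") {
  grid <- rate_grid(window, step_ms)
  nu <- length(spikes$spikes); nt <- nrow(trials)
  out <- array(NA_real_, c(nu, nt, length(grid)))
  tau_s <- tau_ms / 1000
  for (r in seq_len(nt)) {
    trial <- trials[r, ]
    t_abs <- grid + trial[[alignment]]
    valid <- t_abs >= 0 & t_abs <= trial$trial_end
    if (!any(valid))
      stop("smooth_rates: window outside recording for trial ",
           trial$trial_id, call. = FALSE)
    for (u in seq_len(nu)) {
      ts <- aligned_spikes(spikes$spikes[[u]][[r]], trial, alignment)
      tr <- numeric(length(grid))
      if (length(ts)) {
        # contributions of each spike to each later grid point, 5*tau cutoff
        dt <- outer(grid, ts, "-")
        k <- ifelse(dt >= 0 & dt <= 5 * tau_ms, exp(-dt / tau_ms) / tau_s, 0)
        tr <- rowSums(k)
      }
      tr[!valid] <- NA_real_
      out[u, r, ] <- tr
    }
  }
  new_rate_tensor(out, grid, alignment,
                  list(type = "exponential", tau_ms = tau_ms,
                       step_ms = step_ms))
}

#' Binned firing rates on the decoding grid
#'
#' Counts spikes in `bin_ms` windows centered on the decoding grid (centers
#' every `spacing_ms`, 51 centers for the default -2000..2000 window) and
#' divides by the window length, giving spikes/s. Windows extending outside
#' the recorded trial are NA.
#'
#' @inheritParams smooth_rates
#' @param bin_ms Window width (ms).
#' @param spacing_ms Center spacing (ms).
#' @return A `rate_tensor`.
#' @export
bin_rates <- function(spikes, trials, bin_ms = 100, spacing_ms = 80,
                      window = c(-2000, 2000), alignment = "movement_on") {
  centers <- decoding_grid(window, spacing_ms)
  half <- bin_ms / 2
  nu <- length(spikes$spikes); nt <- nrow(trials)
  out <- array(NA_real_, c(nu, nt, length(centers)))
  for (r in seq_len(nt)) {
    trial <- trials[r, ]
    lo_abs <- centers - half + trial[[alignment]]
    hi_abs <- centers + half + trial[[alignment]]
    valid <- lo_abs >= 0 & hi_abs <= trial$trial_end
    if (!any(valid))
      stop("bin_rates: window outside recording for trial ",
           trial$trial_id, call. = FALSE)
    for (u in seq_len(nu)) {
      ts <- aligned_spikes(spikes$spikes[[u]][[r]], trial, alignment)
      cnt <- vapply(seq_along(centers), function(i)
        sum(ts >= centers[i] - half & ts < centers[i] + half), 0)
      rt <- cnt / (bin_ms / 1000)
      rt[!valid] <- NA_real_
      out[u, r, ] <- rt
    }
  }
  new_rate_tensor(out, centers, alignment,
                  list(type = "boxcar", bin_ms = bin_ms,
                       spacing_ms = spacing_ms))
}

#' Trial-averaged condition tensor for population analyses
#'
#' Averages a rate tensor within each grip x force cell (equal-weight
#' condition means, so unequal counts cannot leak between marginalizations).
#'
#' @param rt A `rate_tensor`.
#' @param trials The matching `trial_table`.
#' @return A 4-d array unit x grip(2) x force(2) x time with dimnames on the
#'   condition axes.
#' @export
condition_tensor <- function(rt, trials) {
  grips <- c("side", "precision"); forces <- c("low", "high")
  d <- dim(rt$rates)
  X <- array(NA_real_, c(d[1], 2, 2, d[3]),
             dimnames = list(NULL, grips, forces, NULL))
  for (g in 1:2) for (f in 1:2) {
    idx <- which(trials$grip == grips[g] & trials$force == forces[f])
    if (!length(idx))
      stop("condition_tensor: empty condition cell ", grips[g], "/",
           forces[f], call. = FALSE)
    X[, g, f, ] <- apply(rt$rates[, idx, , drop = FALSE], c(1, 3), mean,
                         na.rm = TRUE)
  }
  X
}
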