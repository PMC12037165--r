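# Time-resolved single-unit selectivity: auROC time courses (Mann-Whitney
# formulation), permutation significance with a consecutive-bin rule,
# selectivity classes, and the grip-force independence battery (permuted
# chi-square marginal test, covariance-ellipse angle, shuffled-null
# delta-auROC correlations at zero and nonzero lag).

# auROC per column of a trials x bins matrix: P(A > B) + 0.5 P(tie),
# computed from rank sums (exactly U / (nA * nB)).
auroc_cols <- function(X, is_a) {
  nA <- sum(is_a); nB <- sum(!is_a)
  if (nA < 2 || nB < 2)
    stop("auROC: need >= 2 trials per class", call. = FALSE)
  Rk <- apply(X, 2, rank)  # ties get average ranks
  (colSums(Rk[is_a, , drop = FALSE]) - nA * (nA + 1) / 2) / (nA * nB)
}

#' Time-resolved auROC selectivity per unit
#'
#' For each unit and time bin, compares the firing-rate distribution of the
#' `positive` condition against its counterpart using the area under the ROC
#' curve in its Mann-Whitney form: `P(rate_A > rate_B) + 0.5 P(tie)` over all
#' trial pairs. 0.5 means the distributions fully overlap; 0 or 1 perfect
#' separation with opposite preference.
#'
#' @param rt A `rate_tensor`.
#' @param labels Per-trial condition (character/factor, two levels).
#' @param positive The condition treated as class A (e.g. `"side"` for grip,
#'   `"high"` for force).
#' @return units x bins matrix of auROC values in `[0, 1]`.
#' @export
auroc_timecourse <- function(rt, labels, positive) {
  is_a <- labels == positive
  if (!any(is_a) || all(is_a))
    stop("auROC: both classes must be present", call. = FALSE)
  d <- dim(rt$rates)
  out <- matrix(NA_real_, d[1], d[3])
  for (u in seq_len(d[1])) {
    X <- rt$rates[u, , , drop = FALSE]
    dim(X) <- d[2:3]
    if (anyNA(X)) {
      for (b in seq_len(d[3])) {
        ok <- !is.na(X[, b])
        if (sum(is_a & ok) >= 2 && sum(!is_a & ok) >= 2)
          out[u, b] <- auroc_cols(X[ok, b, drop = FALSE], is_a[ok])
      }
    } else {
      out[u, ] <- auroc_cols(X, is_a)
    }
  }
  out
}

#' Permutation significance mask for auROC time courses
#'
#' Builds a pointwise two-sided permutation null by recomputing auROC under
#' label shuffles (the trial ranks are fixed, so each permutation is a rank
#' sum over a random trial subset); significance is `|auROC - 0.5|` exceeding
#' the null at `p < alpha`, and a unit is taken to encode the parameter when
#' at least `min_consec` consecutive bins are significant.
#'
#' @inheritParams auroc_timecourse
#' @param n_perm Number of label permutations (must be `>= 1/alpha`).
#' @param alpha Pointwise significance level.
#' @param min_consec Minimum run of significant bins.
#' @param seed Integer seed for the permutations.
#' @return List with `auroc`, `delta` (`|auROC - 0.5|`), `p` (units x bins),
#'   `mask` (logical units x bins after the run rule), and `encodes`
#'   (per-unit logical, mask nonempty).
#' @export
permutation_mask <- function(rt, labels, positive, n_perm = 5000,
                             alpha = 0.001, min_consec = 2, seed = 1L) {
  if (n_perm < 1 / alpha)
    stop("permutation_mask: n_perm must be >= 1/alpha", call. = FALSE)
  is_a <- labels == positive
  nA <- sum(is_a); nB <- sum(!is_a); n <- nA + nB
  d <- dim(rt$rates)
  if (anyNA(rt$rates))
    stop("permutation_mask: rates contain NA bins; restrict the window first",
         call. = FALSE)
  # shared permutation selector: n_perm x trials 0/1 matrix
  P <- with_seed(child_seed(seed, "auroc-perm"), {
    t(replicate(n_perm, {
      v <- numeric(n); v[sample.int(n, nA)] <- 1; v
    }))
  })
  auroc <- matrix(NA_real_, d[1], d[3])
  p <- matrix(NA_real_, d[1], d[3])
  for (u in seq_len(d[1])) {
    Xu <- rt$rates[u, , , drop = FALSE]
    dim(Xu) <- d[2:3]
    Rk <- apply(Xu, 2, rank)
    obs <- (colSums(Rk[is_a, , drop = FALSE]) - nA * (nA + 1) / 2) / (nA * nB)
    null_d <- abs((P %*% Rk - nA * (nA + 1) / 2) / (nA * nB) - 0.5)
    obs_d <- abs(obs - 0.5)
    exceed <- colSums(null_d >= rep(obs_d, each = n_perm))
    auroc[u, ] <- obs
    p[u, ] <- (1 + exceed) / (1 + n_perm)
  }
  sig <- p < alpha
  mask <- t(apply(sig, 1, run_mask, min_consec = min_consec))
  list(auroc = auroc, delta = abs(auroc - 0.5), p = p, mask = mask,
       encodes = rowSums(mask) > 0)
}

#' Full single-unit selectivity battery for grip and force
#'
#' Runs [permutation_mask()] for grip (side vs precision) and force (high vs
#' low) and assigns each unit a selectivity class.
#'
#' @param rt A `rate_tensor` (typically smoothed rates on the 20 ms grid).
#' @param trials The matching `trial_table`.
#' @inheritParams permutation_mask
#' @return An object of class `auroc_result` with elements `grip`, `force`
#'   (each as returned by [permutation_mask()]), `selectivity_class`
#'   (per-unit factor: grip_only/force_only/mixed/none) and `bin_centers`.
#' @export
single_unit_selectivity <- function(rt, trials, n_perm = 5000, alpha = 0.001,
                                    min_consec = 2, seed = 1L) {
  g <- permutation_mask(rt, trials$grip, "side", n_perm, alpha, min_consec,
                        seed = child_seed(seed, "grip"))
  f <- permutation_mask(rt, trials$force, "high", n_perm, alpha, min_consec,
                        seed = child_seed(seed, "force"))
  cls <- ifelse(g$encodes & f$encodes, "mixed",
         ifelse(g$encodes, "grip_only",
         ifelse(f$encodes, "force_only", "none")))
  structure(list(grip = g, force = f,
                 selectivity_class = factor(cls, levels = c(
                   "grip_only", "force_only", "mixed", "none")),
                 bin_centers = rt$bin_centers),
            class = "auroc_result")
}

#' @export
print.auroc_result <- function(x, ...) {
  cat("auroc_result:", length(x$selectivity_class), "units\n")
  print(classify_selectivity(x))
  invisible(x)
}

#' Selectivity class counts
#'
#' @param result An `auroc_result`.
#' @return Named integer vector of counts over
#'   grip_only/force_only/mixed/none.
#' @export
classify_selectivity <- function(result) {
  stopifnot(inherits(result, "auroc_result"))
  table(result$selectivity_class)
}

#' Permuted chi-square test of grip-force marginal independence
#'
#' At each time bin, bins the per-unit (force auROC, grip auROC) pairs into a
#' 2D histogram `O` and compares it with the product of its 1D marginals
#' `E(i,j) = N * p_force(i) * p_grip(j)` via `chi2 = sum over cells with
#' E > 0 of (O - E)^2 / E`. The p-value is the fraction of `n_perm`
#' pairings (force values permuted across units) with a chi-square at least
#' as large, i.e. it asks whether grip and force modulation directions are
#' coupled across the population.
#'
#' @param auroc_grip,auroc_force units x bins auROC matrices (or single-bin
#'   vectors).
#' @param n_bins Histogram bins per axis on `[0, 1]`.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with per-timebin `chi2` and `p` vectors.
#' @export
marginal_independence_test <- function(auroc_grip, auroc_force, n_bins = 10,
                                       n_perm = 1000, seed = 1L) {
  g <- as.matrix(auroc_grip); f <- as.matrix(auroc_force)
  stopifnot(all(dim(g) == dim(f)))
  nu <- nrow(g); nb <- ncol(g)
  if (nu < 20)
    stop("marginal_independence_test: need >= 20 units", call. = FALSE)
  edges <- seq(0, 1, length.out = n_bins + 1)
  cell <- function(x) pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE),
                                1L), n_bins)
  chi2_of <- function(ig, iff) {
    O <- matrix(tabulate(ig + n_bins * (iff - 1L), n_bins * n_bins),
                n_bins, n_bins)
    pg <- rowSums(O) / nu; pf <- colSums(O) / nu
    E <- nu * outer(pg, pf)
    if (sum(O > 0) <= 1)
      stop("marginal_independence_test: degenerate histogram (all mass in ",
           "one cell)", call. = FALSE)
    sum((O[E > 0] - E[E > 0])^2 / E[E > 0])
  }
  chi2 <- numeric(nb); p <- numeric(nb)
  with_seed(child_seed(seed, "chi2"), {
    for (b in seq_len(nb)) {
      ig <- cell(g[, b]); iff <- cell(f[, b])
      obs <- chi2_of(ig, iff)
      null <- vapply(seq_len(n_perm), function(k)
        chi2_of(ig, sample(iff)), 0)
      chi2[b] <- obs
      p[b] <- perm_p(null, obs)
    }
  })
  list(chi2 = chi2, p = p)
}

#' Orientation and 95% ellipse of a 2D auROC scatter
#'
#' Fits a bivariate normal to the (force auROC, grip auROC) points and
#' reports the rotation angle of its 95% confidence ellipse. An angle close
#' to 90 degrees (principal axis vertical) is the signature of independent
#' modulation directions: grip spreads the points vertically while force adds
#' no correlated horizontal structure.
#'
#' @param x,y Coordinates (force on x, grip on y).
#' @param level Ellipse coverage probability.
#' @return List with `theta_deg` in `[0, 180)`, `center`, `semi_axes`
#'   (major, minor), and the eigen-decomposition.
#' @export
ellipse_angle <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("ellipse_angle: need >= 3 points", call. = FALSE)
  S <- stats::cov(cbind(x, y))
  if (!all(is.finite(S)))
    stop("ellipse_angle: nonfinite covariance", call. = FALSE)
  e <- eigen(S, symmetric = TRUE)
  if (e$values[1] <= 0)
    stop("ellipse_angle: singular covariance", call. = FALSE)
  v <- e$vectors[, 1]
  theta <- atan2(v[2], v[1]) * 180 / pi
  theta <- theta %% 180
  list(theta_deg = theta, center = c(mean(x), mean(y)),
       semi_axes = sqrt(stats::qchisq(level, df = 2) * pmax(e$values, 0)),
       eigen = e)
}

# column-wise Pearson correlation between two matrices (across rows)
colwise_cor <- function(A, B) {
  As <- scale(A); Bs <- scale(B)
  r <- colSums(As * Bs) / (nrow(A) - 1)
  r[!is.finite(r)] <- NA_real_
  r
}

# joint shuffle across time and units (without replacement)
shuffle_matrix <- function(M) matrix(sample(M), nrow(M), ncol(M))

#' Correlation of grip and force modulation strengths across units
#'
#' Pearson correlation, per time bin, between per-unit grip and force
#' `delta-auROC` values, tested against a null built by shuffling both
#' delta matrices jointly across time and units (`n_shuffle` draws without
#' replacement). Significance uses `p < alpha` for at least `min_consec`
#' consecutive bins.
#'
#' @param delta_grip,delta_force units x bins matrices of `|auROC - 0.5|`.
#' @param n_shuffle Number of shuffles.
#' @param alpha Pointwise level.
#' @param min_consec Consecutive-bin rule.
#' @param seed Integer seed.
#' @return List with `r` (per bin), `p`, `mask`.
#' @export
strength_correlation <- function(delta_grip, delta_force, n_shuffle = 1000,
                                 alpha = 0.001, min_consec = 2, seed = 1L) {
  G <- as.matrix(delta_grip); F_ <- as.matrix(delta_force)
  stopifnot(all(dim(G) == dim(F_)))
  r <- colwise_cor(G, F_)
  null <- with_seed(child_seed(seed, "strength-cor"), {
    vapply(seq_len(n_shuffle), function(k)
      colwise_cor(shuffle_matrix(G), shuffle_matrix(F_)),
      numeric(ncol(G)))
  })  # bins x n_shuffle
  null <- abs(t(null))
  p <- vapply(seq_len(ncol(G)), function(b)
    (1 + sum(null[, b] >= abs(r[b]))) / (1 + n_shuffle), 0)
  list(r = r, p = p, mask = run_mask(p < alpha, min_consec))
}

#' Cross-temporal correlation between grip and lagged force modulation
#'
#' Correlates grip `delta-auROC` at each time bin with force `delta-auROC`
#' shifted by each lag (force taken at `t + lag`), over units. The null is
#' the same joint time-and-unit shuffle as [strength_correlation()].
#' A (bin, lag) cell is significant when `p < alpha` and the bin sits in a
#' run of at least `min_consec` significant bins at that lag.
#'
#' @inheritParams strength_correlation
#' @param bin_centers Time-bin centers (ms), used to convert lags to bins.
#' @param lags_ms Lag grid in ms (must be multiples of the bin step).
#' @return List with `r` (bins x lags), `p`, `mask`, `lags_ms`.
#' @export
cross_temporal_correlation <- function(delta_grip, delta_force, bin_centers,
                                       lags_ms = seq(-400, 400, by = 20),
                                       n_shuffle = 1000, alpha = 0.001,
                                       min_consec = 2, seed = 1L) {
  G <- as.matrix(delta_grip); F_ <- as.matrix(delta_force)
  step <- diff(bin_centers)[1]
  shifts <- lags_ms / step
  if (any(abs(shifts - round(shifts)) > 1e-8))
    stop("lags must be multiples of the bin step", call. = FALSE)
  shifts <- as.integer(round(shifts))
  nb <- ncol(G)
  lag_cor <- function(A, B) {
    out <- matrix(NA_real_, nb, length(shifts))
    for (k in seq_along(shifts)) {
      s <- shifts[k]
      ti <- seq_len(nb); tj <- ti + s
      ok <- tj >= 1 & tj <= nb
      out[ti[ok], k] <- colwise_cor(A[, ti[ok], drop = FALSE],
                                    B[, tj[ok], drop = FALSE])
    }
    out
  }
  r <- lag_cor(G, F_)
  exceed <- matrix(0, nb, length(shifts))
  with_seed(child_seed(seed, "xtemp-cor"), {
    for (k in seq_len(n_shuffle)) {
      rn <- abs(lag_cor(shuffle_matrix(G), shuffle_matrix(F_)))
      exceed <- exceed + (rn >= abs(r))
    }
  })
  p <- (1 + exceed) / (1 + n_shuffle)
  sig <- p < alpha
  mask <- apply(sig, 2, run_mask, min_consec = min_consec)
  list(r = r, p = p, mask = mask, lags_ms = lags_ms)
}
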