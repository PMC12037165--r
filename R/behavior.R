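# Behavioral statistics (reaction and movement times, between-subject
# rank-sum comparison) and the force-signal / demixed-component correlation
# analysis.

#' Reaction- and movement-time summary with a between-subject comparison
#'
#' RT is go-cue to movement onset, MT movement onset to object touch, on
#' correct trials. When exactly two subjects are present their RT and MT
#' distributions are compared with a Mann-Whitney rank-sum test
#' (normal-approximation z with tie correction).
#'
#' @param trials A `trial_table` with a `subject` column.
#' @return An object of class `behavior_summary`: `per_subject` data.frame
#'   (mean/SD of RT and MT, ms) and, for two subjects, `comparison` with
#'   `z` and `p` for RT and MT.
#' @export
behavior_summary <- function(trials) {
  trials <- trials[trials$correct, , drop = FALSE]
  if (!nrow(trials)) stop("behavior_summary: no correct trials", call. = FALSE)
  rt <- trials$movement_on - trials$go
  mt <- trials$touch - trials$movement_on
  if (any(rt <= 0) || any(mt <= 0))
    stop("behavior_summary: nonpositive RT or MT on a correct trial",
         call. = FALSE)
  subj <- as.character(trials$subject %||% "subject")
  per <- do.call(rbind, lapply(split(seq_along(rt), subj), function(ix) {
    if (length(ix) < 2)
      stop("behavior_summary: need >= 2 correct trials per subject",
           call. = FALSE)
    data.frame(n = length(ix),
               rt_mean = mean(rt[ix]), rt_sd = stats::sd(rt[ix]),
               mt_mean = mean(mt[ix]), mt_sd = stats::sd(mt[ix]))
  }))
  per <- cbind(subject = rownames(per), per)
  rownames(per) <- NULL
  comparison <- NULL
  if (nrow(per) == 2) {
    s <- split(seq_along(rt), subj)
    comparison <- rbind(
      rt = ranksum_z(rt[s[[1]]], rt[s[[2]]]),
      mt = ranksum_z(mt[s[[1]]], mt[s[[2]]]))
  }
  structure(list(per_subject = per, comparison = comparison),
            class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat("behavior_summary:\n")
  print(transform(x$per_subject,
                  rt_mean = round(rt_mean), rt_sd = round(rt_sd),
                  mt_mean = round(mt_mean), mt_sd = round(mt_sd)))
  if (!is.null(x$comparison)) {
    cat("rank-sum comparison (subject 1 vs 2):\n")
    print(round(as.data.frame(x$comparison), 4))
  }
  invisible(x)
}

#' Mann-Whitney rank-sum z statistic
#'
#' Normal approximation with tie correction; `z` is signed so that negative
#' values mean the first sample ranks lower.
#'
#' @param x,y Samples.
#' @return Data frame with `z`, `p` (two-sided), `U`.
#' @export
ranksum_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  corr <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
  sig <- sqrt(n1 * n2 / 12 * (n1 + n2 + 1 - corr))
  z <- (U - mu) / sig
  data.frame(z = z, p = 2 * stats::pnorm(-abs(z)), U = U)
}

# normalized cross-correlation of two traces over integer shifts; returns
# max |r| over the lag range (r at shift s compares x[t] with y[t+s])
max_abs_xcorr <- function(x, y, max_shift) {
  n <- length(x)
  best <- 0
  for (s in -max_shift:max_shift) {
    ti <- seq_len(n); tj <- ti + s
    ok <- tj >= 1 & tj <= n
    xs <- x[ti[ok]]; ys <- y[tj[ok]]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) next
    best <- max(best, abs(stats::cor(xs, ys)))
  }
  best
}

#' Correlate per-trial pulling force with demixed-component projections
#'
#' For every trial and each of two components (the leading force component
#' and the leading condition-independent/time component), computes the
#' normalized cross-correlation between the trial's force trace (normalized
#' to unit peak) and its single-trial component projection over lags up to
#' `lag_ms`, keeping `R^2 = (max |r|)^2`. Significance bounds come from a
#' null of random circular time-shifts of the force trace (`n_null`
#' iterations, 99% bound), which preserves the traces' autocorrelation. A
#' two-way ANOVA on R^2 with factors component type x force level tests
#' whether the time component tracks the force signal more closely than the
#' force component.
#'
#' @param force A `force_traces` matrix (trials x time).
#' @param proj_force,proj_time trials x time projection matrices on the same
#'   grid (see [dpca_project()]).
#' @param force_level Per-trial force condition (low/high).
#' @param lag_ms Maximum lag (ms).
#' @param n_null Circular-shift null iterations.
#' @param seed Integer seed.
#' @return An object of class `force_dpc_correlation`: per-trial `r2`
#'   data.frame (`trial`, `dpc`, `force_level`, `r2`, `significant`),
#'   `bound` (99% null bound), `prop_significant` per component, `anova`
#'   table.
#' @export
force_dpc_correlation <- function(force, proj_force, proj_time, force_level,
                                  lag_ms = 500, n_null = 200, seed = 1L) {
  bc <- attr(force, "bin_centers")
  if (is.null(bc)) stop("force traces lack a time grid", call. = FALSE)
  if (ncol(proj_force) != ncol(force) || ncol(proj_time) != ncol(force))
    stop("force_dpc_correlation: time-grid mismatch between force and ",
         "projections", call. = FALSE)
  step <- diff(bc)[1]
  max_shift <- round(lag_ms / step)
  nt <- nrow(force)
  norm_peak <- function(v) if (max(abs(v)) > 0) v / max(abs(v)) else v
  r2 <- matrix(NA_real_, nt, 2, dimnames = list(NULL, c("force", "time")))
  for (r in seq_len(nt)) {
    f <- norm_peak(force[r, ])
    r2[r, "force"] <- max_abs_xcorr(f, proj_force[r, ], max_shift)^2
    r2[r, "time"] <- max_abs_xcorr(f, proj_time[r, ], max_shift)^2
  }
  # circular-shift null pooled over trials and both components
  null <- with_seed(child_seed(seed, "force-null"), {
    vapply(seq_len(n_null), function(k) {
      r <- sample.int(nt, 1)
      s <- sample.int(ncol(force) - 1, 1)
      f <- norm_peak(force[r, c((s + 1):ncol(force), 1:s)])
      p <- if (k %% 2 == 0) proj_force[r, ] else proj_time[r, ]
      max_abs_xcorr(f, p, max_shift)^2
    }, 0)
  })
  bound <- stats::quantile(null, 0.99)
  df <- data.frame(
    trial = rep(seq_len(nt), 2),
    dpc = rep(c("force", "time"), each = nt),
    force_level = rep(force_level, 2),
    r2 = c(r2[, "force"], r2[, "time"]))
  df$significant <- df$r2 > bound
  prop <- tapply(df$significant, df$dpc, mean)
  an <- stats::anova(stats::lm(r2 ~ dpc * force_level, data = df))
  structure(list(r2 = df, bound = unname(bound),
                 prop_significant = prop, anova = an),
            class = "force_dpc_correlation")
}

#' @export
print.force_dpc_correlation <- function(x, ...) {
  cat("force_dpc_correlation:\n  proportion significant:",
      paste(names(x$prop_significant),
            round(x$prop_significant, 3), sep = "=", collapse = ", "), "\n")
  cat(sprintf("  ANOVA dpc effect: F(%d,%d) = %.2f, p = %.3g\n",
              x$anova["dpc", "Df"], x$anova["Residuals", "Df"],
              x$anova["dpc", "F value"], x$anova["dpc", "Pr(>F)"]))
  invisible(x)
}
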