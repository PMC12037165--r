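# Per-bin population decoding with a linear maximum-margin classifier,
# cross-temporal generalization matrices, the three-condition static-bin
# criterion, and the generalization index.

# Fit a linear SVM and return a fast scoring closure. Features must already
# be standardized; the positive-score class is calibrated against predict()
# so the sign convention of the underlying fit never leaks out.
fit_linear_svm <- function(Xtr, ytr, cost = 1) {
  yf <- factor(ytr)
  model <- e1071::svm(x = Xtr, y = yf, kernel = "linear", cost = cost,
                      scale = FALSE)
  w <- crossprod(model$coefs, model$SV)  # 1 x p
  b <- -model$rho
  sc_tr <- drop(Xtr %*% t(w)) + b
  pr_tr <- as.character(predict(model, Xtr))
  pos <- sc_tr > 0
  lev <- levels(yf)
  pos_level <- if (any(pos)) names(which.max(table(pr_tr[pos]))) else
    setdiff(lev, names(which.max(table(pr_tr))))[1]
  if (is.na(pos_level) || !length(pos_level)) pos_level <- lev[1]
  neg_level <- setdiff(lev, pos_level)[1]
  function(X) ifelse(drop(X %*% t(w)) + b > 0, pos_level, neg_level)
}

# stratified train/test indices per repetition
split_trials <- function(labels, train_per_class, test_per_class) {
  classes <- unique(labels)
  tr <- te <- integer(0)
  for (cl in classes) {
    ix <- which(labels == cl)
    n <- length(ix)
    ntr <- train_per_class; nte <- test_per_class
    if (n < ntr + nte) {
      ntr <- max(2L, floor(n * train_per_class /
                             (train_per_class + test_per_class)))
      nte <- n - ntr
      if (nte < 1)
        stop(sprintf("decoding: class '%s' has only %d trials", cl, n),
             call. = FALSE)
    }
    s <- sample(ix)
    tr <- c(tr, s[seq_len(ntr)])
    te <- c(te, s[ntr + seq_len(nte)])
  }
  list(train = tr, test = te)
}

# per-bin standardization of a units x trials x bins array using train-fold
# statistics; returns trials x units matrices per bin accessor
standardize_by_train <- function(rates, train) {
  nb <- dim(rates)[3]
  lapply(seq_len(nb), function(b) {
    X <- t(rates[, , b])  # trials x units
    mu <- colMeans(X[train, , drop = FALSE])
    sd <- apply(X[train, , drop = FALSE], 2, stats::sd)
    sd[sd == 0 | !is.finite(sd)] <- 1
    sweep(sweep(X, 2, mu), 2, sd, "/")
  })
}

check_split_feasible <- function(labels, train_per_class, test_per_class) {
  tab <- table(labels)
  if (any(tab < 6))
    stop("decoding: class counts too small for a train/test split (",
         paste(names(tab), tab, sep = "=", collapse = ", "), ")",
         call. = FALSE)
  if (any(tab < train_per_class + test_per_class))
    warning("decoding: fewer trials than the requested ",
            train_per_class, "/", test_per_class,
            " split; subsampling proportionally", call. = FALSE)
}

#' Per-bin population decoding accuracy
#'
#' Trains a linear maximum-margin classifier at every time bin on
#' `train_per_class` trials per class and scores `test_per_class` held-out
#' trials, repeating `n_rep` times with fresh random splits; features are
#' standardized per bin using training trials only. Chance is `1/n_classes`
#' (50% for the two grip or two force conditions).
#'
#' @param rt A binned `rate_tensor`.
#' @param labels Per-trial condition labels (two classes).
#' @param n_rep Number of random splits.
#' @param train_per_class,test_per_class Split sizes per class.
#' @param cost SVM cost parameter.
#' @param seed Integer seed.
#' @return Numeric accuracy per bin (mean over repetitions).
#' @export
decode_timecourse <- function(rt, labels, n_rep = 50, train_per_class = 25,
                              test_per_class = 5, cost = 1, seed = 1L) {
  drop(decode_engine(rt, labels, n_rep, train_per_class, test_per_class,
                     cost, seed, cross_temporal = FALSE))
}

#' Cross-temporal decoding accuracy matrix
#'
#' For every pair of time bins, trains the classifier at the first bin and
#' tests held-out trials at the second; the diagonal reproduces
#' [decode_timecourse()] up to repetition noise. Above-chance off-diagonal
#' accuracy indicates a temporally stable (static) population code.
#'
#' @inheritParams decode_timecourse
#' @return train-bin x test-bin accuracy matrix.
#' @export
cross_temporal_matrix <- function(rt, labels, n_rep = 50, train_per_class = 25,
                                  test_per_class = 5, cost = 1, seed = 1L) {
  decode_engine(rt, labels, n_rep, train_per_class, test_per_class, cost,
                seed, cross_temporal = TRUE)
}

decode_engine <- function(rt, labels, n_rep, train_per_class, test_per_class,
                          cost, seed, cross_temporal) {
  rates <- rt$rates
  if (anyNA(rates))
    stop("decoding: rates contain NA bins; restrict the window first",
         call. = FALSE)
  check_split_feasible(labels, train_per_class, test_per_class)
  nb <- dim(rates)[3]
  acc <- if (cross_temporal) matrix(0, nb, nb) else matrix(0, nb, 1)
  with_seed(child_seed(seed, "decode"), {
    for (rep in seq_len(n_rep)) {
      sp <- split_trials(labels, train_per_class, test_per_class)
      Xs <- standardize_by_train(rates, sp$train)
      ytr <- labels[sp$train]; yte <- labels[sp$test]
      for (i in seq_len(nb)) {
        clf <- fit_linear_svm(Xs[[i]][sp$train, , drop = FALSE], ytr, cost)
        if (cross_temporal) {
          for (j in seq_len(nb))
            acc[i, j] <- acc[i, j] +
              mean(clf(Xs[[j]][sp$test, , drop = FALSE]) == yte)
        } else {
          acc[i, 1] <- acc[i, 1] +
            mean(clf(Xs[[i]][sp$test, , drop = FALSE]) == yte)
        }
      }
    }
  })
  acc / n_rep
}

#' Label-shuffled null decoding matrices
#'
#' Builds the bootstrap null for the static-bin criterion: `n_null`
#' label-shuffled cross-temporal matrices (each with `n_rep_null`
#' repetitions).
#'
#' @inheritParams cross_temporal_matrix
#' @param n_null Number of shuffled-label iterations.
#' @param n_rep_null Repetitions per iteration.
#' @return n_null x bins x bins array.
#' @export
null_matrices <- function(rt, labels, n_null = 1000, n_rep_null = 1,
                          train_per_class = 25, test_per_class = 5, cost = 1,
                          seed = 1L) {
  nb <- dim(rt$rates)[3]
  out <- array(NA_real_, c(n_null, nb, nb))
  with_seed(child_seed(seed, "null-matrices"), {
    for (k in seq_len(n_null)) {
      lab_k <- sample(labels)
      out[k, , ] <- decode_engine(rt, lab_k, n_rep_null, train_per_class,
                                  test_per_class, cost,
                                  seed = sample.int(2^30, 1),
                                  cross_temporal = TRUE)
    }
  })
  out
}

# 8-connected components of a logical matrix; returns integer label matrix
connected_components8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(lab)
  for (s in seq_len(nrow(idx))) {
    i0 <- idx[s, 1]; j0 <- idx[s, 2]
    if (lab[i0, j0] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i0, j0), 1)
    lab[i0, j0] <- cur
    while (nrow(queue)) {
      nxt <- NULL
      for (q in seq_len(nrow(queue))) {
        i <- queue[q, 1]; j <- queue[q, 2]
        for (di in -1:1) for (dj in -1:1) {
          ii <- i + di; jj <- j + dj
          if (ii < 1 || jj < 1 || ii > nrow(mask) || jj > ncol(mask)) next
          if (mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            nxt <- rbind(nxt, c(ii, jj))
          }
        }
      }
      queue <- if (is.null(nxt)) matrix(numeric(0), 0, 2) else nxt
    }
  }
  lab
}

#' Static-bin binary matrix from the three-condition criterion
#'
#' A train/test bin pair is static when (1) it belongs to a supra-threshold
#' cluster (8-connected, pointwise threshold = 95th percentile of the
#' shuffled null per cell, cluster mass = sum of accuracy minus chance)
#' whose mass exceeds the 99th percentile of the null maximum cluster
#' masses; (2) its accuracy exceeds the 99th percentile of its own shuffled
#' null; and (3) both corresponding diagonal bins pass Bonferroni-corrected
#' permutation tests at `alpha_diag`. Surviving cells are then filtered to
#' runs of at least `min_consec` consecutive static cells along the
#' test-time axis.
#'
#' @param M Observed accuracy matrix.
#' @param nulls n_null x bins x bins array from [null_matrices()].
#' @param chance Chance accuracy (0.5 for two classes).
#' @param alpha_diag Diagonal permutation level (before Bonferroni).
#' @param cluster_alpha Cluster-mass level.
#' @param cell_quantile Per-cell null quantile for condition (2).
#' @param point_quantile Pointwise cluster-forming quantile.
#' @param min_consec Run rule along test time.
#' @return List with the binary `static` matrix, the raw `conditions`
#'   (three logical matrices), `clusters`, and diagonal p-values.
#' @export
static_bins <- function(M, nulls, chance = 0.5, alpha_diag = 0.01,
                        cluster_alpha = 0.01, cell_quantile = 0.99,
                        point_quantile = 0.95, min_consec = 2) {
  if (is.null(nulls)) stop("static_bins: null matrices missing", call. = FALSE)
  nb <- nrow(M)
  n_null <- dim(nulls)[1]
  # (2) cell-wise bootstrap-null exceedance
  thr_cell <- apply(nulls, c(2, 3), stats::quantile, probs = cell_quantile)
  cond2 <- M > thr_cell
  # (1) cluster-based permutation on the full matrix
  thr_point <- apply(nulls, c(2, 3), stats::quantile, probs = point_quantile)
  lab <- connected_components8(M > thr_point)
  null_max_mass <- vapply(seq_len(n_null), function(k) {
    Nk <- nulls[k, , ]
    lk <- connected_components8(Nk > thr_point)
    if (!any(lk > 0)) return(0)
    max(vapply(seq_len(max(lk)), function(cl)
      sum(Nk[lk == cl] - chance), 0))
  }, 0)
  mass_thr <- stats::quantile(null_max_mass, 1 - cluster_alpha)
  cond1 <- matrix(FALSE, nb, nb)
  if (any(lab > 0)) {
    for (cl in seq_len(max(lab))) {
      mass <- sum(M[lab == cl] - chance)
      if (mass > mass_thr) cond1[lab == cl] <- TRUE
    }
  }
  # (3) Bonferroni-corrected diagonal permutation test
  # raw exceedance proportion (an accuracy beating every shuffle gives p = 0,
  # which a Bonferroni threshold below 1/n_null requires)
  diag_null <- vapply(seq_len(nb), function(b) nulls[, b, b], numeric(n_null))
  p_diag <- vapply(seq_len(nb), function(b)
    mean(diag_null[, b] >= M[b, b]), 0)
  diag_sig <- p_diag * nb < alpha_diag
  cond3 <- outer(diag_sig, diag_sig, "&")
  static <- cond1 & cond2 & cond3
  static <- t(apply(static, 1, run_mask, min_consec = min_consec))
  list(static = static * 1,
       conditions = list(cluster = cond1, cell = cond2, diagonal = cond3),
       clusters = lab, p_diag = p_diag)
}

#' Preparation and execution epochs in movement-aligned coordinates
#'
#' Preparation runs from the mean grip-cue onset to the mean go cue;
#' execution from movement onset to the mean object release.
#'
#' @param trials A `trial_table`.
#' @return List of two 2-vectors (ms relative to movement onset).
#' @export
epoch_definition <- function(trials) {
  rel <- function(ev) mean(trials[[ev]] - trials$movement_on)
  list(preparation = c(rel("cue_on"), rel("go")),
       execution = c(0, rel("release")))
}

#' Generalization index curves
#'
#' For each test bin, the proportion of train bins inside an epoch
#' (preparation or execution) whose cross-temporal decoding was classified
#' static: `GI_E(t_test) = #\{train in E : static\} / #\{train in E\}`.
#'
#' @param static Binary static matrix (train x test).
#' @param bin_centers Bin centers (ms re movement onset).
#' @param epochs List as from [epoch_definition()].
#' @return Matrix with rows `preparation` and `execution`, columns = test
#'   bins, values in `[0, 1]`.
#' @export
generalization_index <- function(static, bin_centers, epochs) {
  stopifnot(nrow(static) == length(bin_centers))
  out <- vapply(epochs, function(w) {
    ix <- which(bin_centers >= w[1] & bin_centers <= w[2])
    if (length(ix) < 2)
      stop("generalization_index: epoch contains < 2 bins", call. = FALSE)
    colMeans(static[ix, , drop = FALSE])
  }, numeric(ncol(static)))
  t(out)
}

#' End-to-end cross-temporal decoding for one parameter
#'
#' Convenience wrapper: accuracy matrix, shuffled nulls, static-bin matrix
#' and generalization-index curves.
#'
#' @inheritParams cross_temporal_matrix
#' @param trials Matching `trial_table` (for the epoch definition).
#' @param n_null Shuffled-label iterations for the null.
#' @param min_consec Run rule for the static matrix.
#' @return An object of class `cross_temporal_result`.
#' @export
cross_temporal_analysis <- function(rt, labels, trials, n_rep = 50,
                                    train_per_class = 25, test_per_class = 5,
                                    n_null = 1000, cost = 1, min_consec = 2,
                                    seed = 1L) {
  M <- cross_temporal_matrix(rt, labels, n_rep, train_per_class,
                             test_per_class, cost, seed)
  nulls <- null_matrices(rt, labels, n_null = n_null,
                         train_per_class = train_per_class,
                         test_per_class = test_per_class, cost = cost,
                         seed = seed)
  chance <- 1 / length(unique(labels))
  sb <- static_bins(M, nulls, chance = chance, min_consec = min_consec)
  epochs <- epoch_definition(trials)
  gi <- generalization_index(sb$static, rt$bin_centers, epochs)
  structure(list(matrix = M, accuracy = diag(M), static = sb$static,
                 conditions = sb$conditions, p_diag = sb$p_diag,
                 gi = gi, epochs = epochs, bin_centers = rt$bin_centers,
                 chance = chance),
            class = "cross_temporal_result")
}

#' @export
print.cross_temporal_result <- function(x, ...) {
  cat(sprintf(paste0("cross_temporal_result: %d bins, peak accuracy %.2f, ",
                     "%d static cells\n"),
              length(x$accuracy), max(x$accuracy), sum(x$static)))
  cat(sprintf("mean GI: preparation %.2f, execution %.2f\n",
              mean(x$gi["preparation", ]), mean(x$gi["execution", ])))
  invisible(x)
}
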