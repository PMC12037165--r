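# Demixed PCA of the trial-averaged unit x grip x force x time tensor:
# marginalization into condition-independent (time), grip, force and
# interaction parts, reduced-rank ridge estimation of decoder/encoder axis
# pairs per marginalization, explained-variance accounting, and single-trial
# classifiers on component projections.

MARGS <- c("time", "grip", "force", "interaction")

# broadcast helpers for the unit x 2 x 2 x T tensor
bc_time <- function(M, d) aperm(array(M, c(d[1], d[4], d[2], d[3])),
                                c(1, 3, 4, 2))
bc_grip <- function(M, d) aperm(array(M, c(d[1], d[2], d[4], d[3])),
                                c(1, 2, 4, 3))
bc_force <- function(M, d) aperm(array(M, c(d[1], d[3], d[4], d[2])),
                                 c(1, 4, 2, 3))

#' Marginalize a trial-averaged population tensor
#'
#' Splits the grand-mean-centered tensor `X[unit, grip, force, time]` into
#' condition-independent (time), grip, force, and interaction parts:
#' the time part is the mean over conditions, the grip part the
#' force-averaged grip-conditional mean minus the time part (symmetrically
#' for force), and the interaction the remainder. The four parts sum exactly
#' to the centered tensor.
#'
#' @param X unit x grip(2) x force(2) x time array (see [condition_tensor()]).
#' @return List with `centered` and the four marginalized arrays (same
#'   shape), plus `grand_mean` per unit.
#' @export
marginalize <- function(X) {
  d <- dim(X)
  stopifnot(length(d) == 4, d[2] == 2, d[3] == 2)
  if (anyNA(X)) stop("marginalize: tensor contains NA", call. = FALSE)
  gm <- apply(X, 1, mean)
  Xc <- X - array(gm, d)
  M_time <- apply(Xc, c(1, 4), mean)              # unit x time
  X_time <- bc_time(M_time, d)
  M_grip <- apply(Xc, c(1, 2, 4), mean) -
    aperm(array(M_time, c(d[1], d[4], d[2])), c(1, 3, 2))
  X_grip <- bc_grip(M_grip, d)
  M_force <- apply(Xc, c(1, 3, 4), mean) -
    aperm(array(M_time, c(d[1], d[4], d[3])), c(1, 3, 2))
  X_force <- bc_force(M_force, d)
  X_inter <- Xc - X_time - X_grip - X_force
  list(centered = Xc, time = X_time, grip = X_grip, force = X_force,
       interaction = X_inter, grand_mean = gm)
}

flatten4 <- function(X) {
  d <- dim(X)
  matrix(X, d[1], prod(d[-1]))
}

#' Fit demixed PCA by reduced-rank ridge regression
#'
#' For each marginalization part `X_phi`, finds encoder/decoder axes
#' minimizing `||X_phi - F D X||^2 + mu ||F D||^2` over rank-constrained
#' `F D`: the full-rank ridge solution `M = X_phi X' (X X' + mu I)^-1` is
#' rank-truncated through the SVD of `M X`, giving orthonormal encoders (the
#' left singular vectors) and decoders `D = F' M`. Components from all
#' marginalizations are pooled and numbered globally by explained variance,
#' as is conventional for demixed components.
#'
#' @param X unit x grip x force x time trial-averaged tensor.
#' @param n_components Components retained per marginalization.
#' @param mu Ridge penalty (>= 0), on the scale of `||X||^2`.
#' @return An object of class `dpca_model`: `components` data.frame
#'   (`component`, `marginalization`, `evar_pct`), `decoder` and `encoder`
#'   matrices (units x total components, global order), `grand_mean`, `mu`,
#'   `dims`, `total_var`.
#' @export
fit_dpca <- function(X, n_components = 10, mu = 0) {
  if (mu < 0) stop("fit_dpca: mu must be >= 0", call. = FALSE)
  m <- marginalize(X)
  d <- dim(X)
  n_components <- min(n_components, d[1])
  Xf <- flatten4(m$centered)
  total <- sum(Xf^2)
  XXt <- tcrossprod(Xf)
  # regularized (pseudo)inverse of X X' via its eigendecomposition; with
  # mu = 0 and a rank-deficient population this is the Moore-Penrose inverse
  e <- eigen(XXt, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  keep <- (lam + mu) > max(lam) * 1e-12
  inv_lam <- ifelse(keep, 1 / (lam + mu), 0)
  ridge_inv <- e$vectors %*% (t(e$vectors) * inv_lam)
  dec <- enc <- list(); rows <- list()
  for (phi in MARGS) {
    Xphi <- flatten4(m[[phi]])
    Mphi <- Xphi %*% t(Xf) %*% ridge_inv
    s <- svd(Mphi %*% Xf, nu = n_components, nv = 0)
    q <- min(n_components, sum(s$d > max(s$d[1], 0) * 1e-10))
    if (q == 0) next
    Fq <- s$u[, seq_len(q), drop = FALSE]          # encoders, orthonormal
    Dq <- t(Fq) %*% Mphi                           # decoders (rows)
    Z <- Dq %*% Xf                                 # component projections
    ev <- vapply(seq_len(q), function(i) {
      Zi <- outer(Fq[, i], Z[i, ])
      (2 * sum(Xf * Zi) - sum(Zi^2)) / total * 100
    }, 0)
    dec[[phi]] <- t(Dq); enc[[phi]] <- Fq
    rows[[phi]] <- data.frame(marginalization = phi,
                              within_rank = seq_len(q), evar_pct = ev)
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$evar_pct)
  tab <- tab[ord, ]
  tab$component <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  decoder <- do.call(cbind, dec)[, ord, drop = FALSE]
  encoder <- do.call(cbind, enc)[, ord, drop = FALSE]
  colnames(decoder) <- colnames(encoder) <- paste0("dPC", tab$component)
  structure(list(components = tab[, c("component", "marginalization",
                                      "within_rank", "evar_pct")],
                 decoder = decoder, encoder = encoder,
                 grand_mean = m$grand_mean, mu = mu, dims = d,
                 total_var = total),
            class = "dpca_model")
}

#' @export
print.dpca_model <- function(x, ...) {
  cat(sprintf("dpca_model: %d components, mu = %g\n", nrow(x$components),
              x$mu))
  agg <- explained_variance(x)$marginalization
  print(round(agg, 2))
  invisible(x)
}

#' Explained variance per component and per marginalization
#'
#' Component variance is the reduction in squared residual of the centered
#' tensor attributable to that component, as a percentage of total centered
#' variance; marginalization totals sum their components.
#'
#' @param model A `dpca_model`.
#' @return List with `component` (data.frame) and `marginalization` (named
#'   vector of totals, %).
#' @export
explained_variance <- function(model) {
  stopifnot(inherits(model, "dpca_model"))
  tab <- model$components
  totals <- tapply(tab$evar_pct, tab$marginalization, sum)
  totals <- totals[MARGS[MARGS %in% names(totals)]]
  list(component = tab, marginalization = totals)
}

#' Raw variance split of the marginalized parts
#'
#' Fraction of total centered variance carried by each marginalization,
#' independent of any fitted components (the four fractions sum to 100).
#'
#' @param X unit x grip x force x time tensor.
#' @return Named percentage vector over time/grip/force/interaction.
#' @export
marginal_variance_split <- function(X) {
  m <- marginalize(X)
  total <- sum(m$centered^2)
  vapply(MARGS, function(phi) sum(m[[phi]]^2) / total * 100, 0)
}

#' Project single-trial rates onto a demixed component
#'
#' @param model A `dpca_model`.
#' @param rt A `rate_tensor` (same units, any trials).
#' @param component Global component number.
#' @return trials x time matrix of projections.
#' @export
dpca_project <- function(model, rt, component) {
  d <- model$decoder[, paste0("dPC", component)]
  X <- sweep(rt$rates, 1, model$grand_mean)  # units x trials x time
  apply(X, c(2, 3), function(v) sum(v * d))
}

#' Single-trial classifier on a demixed component
#'
#' Projects held-out single trials on a component's decoder axis and assigns
#' them, per time bin, to the nearest training-set class mean under a
#' stratified Monte Carlo leave-group-out cross-validation (one trial per
#' condition cell held out per iteration). The chance distribution comes from
#' `n_shuffle` label-shuffled runs; bins are significant when the actual
#' accuracy exceeds every shuffled accuracy for at least `min_consec`
#' consecutive bins.
#'
#' @param model A `dpca_model`.
#' @param rt Single-trial `rate_tensor`.
#' @param trials Matching `trial_table`.
#' @param marginalization One of `"grip"`, `"force"`, `"interaction"`.
#' @param component Global component number; default the marginalization's
#'   highest-variance component.
#' @param n_iter Cross-validation iterations.
#' @param n_shuffle Size of the Monte Carlo chance distribution.
#' @param min_consec Consecutive-bin rule for significance.
#' @param seed Integer seed.
#' @return An object of class `component_decoding`: `accuracy` (per bin),
#'   `shuffled` (n_shuffle x bins), `mask`, `component`, `marginalization`.
#' @export
component_classifier <- function(model, rt, trials,
                                 marginalization = c("grip", "force",
                                                     "interaction"),
                                 component = NULL, n_iter = 100,
                                 n_shuffle = 100, min_consec = 10,
                                 seed = 1L) {
  marginalization <- match.arg(marginalization)
  tab <- model$components
  if (is.null(component)) {
    cand <- tab$component[tab$marginalization == marginalization]
    if (!length(cand))
      stop("no fitted component for marginalization ", marginalization,
           call. = FALSE)
    component <- cand[1]
  }
  labels <- switch(marginalization,
                   grip = trials$grip,
                   force = trials$force,
                   interaction = paste(trials$grip, trials$force, sep = "/"))
  cells <- paste(trials$grip, trials$force, sep = "/")
  if (any(table(cells) < 2))
    stop("component_classifier: a condition cell has < 2 trials",
         call. = FALSE)
  Z <- dpca_project(model, rt, component)  # trials x bins
  nb <- ncol(Z)
  cv_accuracy <- function(lab) {
    classes <- unique(lab)
    acc <- matrix(NA_real_, n_iter, nb)
    for (it in seq_len(n_iter)) {
      test <- vapply(split(seq_along(cells), cells),
                     function(ix) ix[sample.int(length(ix), 1)], 0L)
      train <- setdiff(seq_along(cells), test)
      mu_cls <- vapply(classes, function(cl)
        colMeans(Z[train[lab[train] == cl], , drop = FALSE]),
        numeric(nb))  # bins x classes
      pred <- vapply(test, function(ti)
        classes[max.col(-abs(matrix(Z[ti, ], nb, length(classes)) - mu_cls),
                        ties.method = "first")],
        character(nb))  # bins x ntest
      acc[it, ] <- rowMeans(pred == matrix(lab[test], nb, length(test),
                                           byrow = TRUE))
    }
    colMeans(acc)
  }
  with_seed(child_seed(seed, paste0("cclf-", marginalization)), {
    accuracy <- cv_accuracy(labels)
    shuffled <- t(vapply(seq_len(n_shuffle), function(k)
      cv_accuracy(sample(labels)), numeric(nb)))
  })
  sig <- accuracy > apply(shuffled, 2, max)
  structure(list(accuracy = accuracy, shuffled = shuffled,
                 mask = run_mask(sig, min_consec),
                 component = component, marginalization = marginalization),
            class = "component_decoding")
}

#' First significant component of a marginalization
#'
#' The lowest-numbered (highest-variance) component of a marginalization
#' whose single-trial classifier mask is nonempty; NA when none is
#' significant (as happens for the interaction marginalization when its
#' components carry no decodable signal).
#'
#' @inheritParams component_classifier
#' @param max_components How many components of the marginalization to try.
#' @return List with `component` (or NA), `decoding` (the significant
#'   `component_decoding`, or last tried).
#' @export
first_significant_component <- function(model, rt, trials, marginalization,
                                        max_components = 5, n_iter = 100,
                                        n_shuffle = 100, min_consec = 10,
                                        seed = 1L) {
  tab <- model$components
  cand <- tab$component[tab$marginalization == marginalization]
  cand <- utils::head(cand, max_components)
  dec <- NULL
  for (comp in cand) {
    dec <- component_classifier(model, rt, trials, marginalization,
                                component = comp, n_iter = n_iter,
                                n_shuffle = n_shuffle,
                                min_consec = min_consec, seed = seed)
    if (any(dec$mask)) return(list(component = comp, decoding = dec))
  }
  list(component = NA_integer_, decoding = dec)
}

#' Choose the dPCA ridge penalty by cross-validated reconstruction
#'
#' Splits trials into `n_folds` folds; for each candidate `mu` fits the model
#' on the training-fold condition averages and scores the squared error
#' between the reconstructed marginalizations and the held-out-fold
#' marginalizations.
#'
#' @param rt Single-trial `rate_tensor`.
#' @param trials Matching `trial_table`.
#' @param grid Candidate penalties as fractions of total variance.
#' @param n_components Components per marginalization during scoring.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return The selected `mu` (absolute scale), with the score table as
#'   attribute `"scores"`.
#' @export
select_dpca_mu <- function(rt, trials, grid = 10^seq(-7, -3), n_components = 5,
                           n_folds = 5, seed = 1L) {
  cells <- paste(trials$grip, trials$force, sep = "/")
  folds <- with_seed(child_seed(seed, "mu-folds"), {
    f <- integer(nrow(trials))
    for (cl in unique(cells)) {
      ix <- which(cells == cl)
      f[ix] <- sample(rep_len(seq_len(n_folds), length(ix)))
    }
    f
  })
  sub_tensor <- function(idx) condition_tensor(
    list(rates = rt$rates[, idx, , drop = FALSE]), trials[idx, ])
  err <- sapply(grid, function(g) {
    tot <- 0
    for (k in seq_len(n_folds)) {
      Xtr <- sub_tensor(which(folds != k))
      Xte <- sub_tensor(which(folds == k))
      mu <- g * sum(flatten4(marginalize(Xtr)$centered)^2)
      fit <- fit_dpca(Xtr, n_components = n_components, mu = mu)
      mte <- marginalize(Xte)
      Xte_f <- flatten4(mte$centered)
      for (phi in MARGS) {
        sel <- fit$components$marginalization == phi
        if (!any(sel)) next
        Fq <- fit$encoder[, sel, drop = FALSE]
        Dq <- t(fit$decoder[, sel, drop = FALSE])
        tot <- tot + sum((flatten4(mte[[phi]]) - Fq %*% (Dq %*% Xte_f))^2)
      }
    }
    tot
  })
  best <- grid[which.min(err)]
  Xall <- condition_tensor(rt, trials)
  mu <- best * sum(flatten4(marginalize(Xall)$centered)^2)
  attr(mu, "scores") <- data.frame(grid = grid, error = err)
  mu
}
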