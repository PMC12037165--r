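# Stage-ordered pipeline driver and the structured text config.

#' Default pipeline configuration
#'
#' Nested list of per-module settings; all analysis parameters default to the
#' study's stated values (exponential filter tau 100 ms on a 20 ms grid,
#' 100 ms decoding bins on 51 centers over -2000..2000 ms, auROC permutation
#' alpha 0.001 with >= 2 consecutive bins, 50 x 25/5 decoding splits,
#' 1,000-iteration decoding null, 100-iteration component-classifier chance
#' distribution with >= 10 consecutive bins).
#'
#' @param seed Global seed expanded into per-stage child seeds.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    synthetic = list(n_trials_per_condition = 30, scheme = "static",
                     n_grip = 40, n_mixed = 20, n_force = 2, n_null = 38,
                     gain = 0.5),
    rates = list(tau_ms = 100, step_ms = 20, bin_ms = 100, spacing_ms = 80,
                 window = c(-2000, 2000)),
    auroc = list(n_perm = 5000, alpha = 0.001, min_consec = 2),
    independence = list(n_bins = 10, n_perm = 1000, n_shuffle = 1000,
                        lags_ms = seq(-400, 400, by = 20)),
    dpca = list(n_components = 10, mu = 0, n_iter = 100, n_shuffle = 100,
                min_consec = 10),
    decoding = list(n_rep = 50, train_per_class = 25, test_per_class = 5,
                    n_null = 1000, min_consec = 2),
    behavior = list(lag_ms = 500, n_null = 200))
}

#' Read a structured text configuration file
#'
#' `key = value` lines under `[section]` headers; values are parsed as
#' numbers when possible, comma-separated values become vectors, `#` starts
#' a comment. Unknown keys override/extend [default_config()].
#'
#' @param path File path.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  cfg <- default_config()
  lines <- readLines(path)
  section <- NULL
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("config: cannot parse line '", ln, "'",
                             call. = FALSE)
    key <- trimws(kv[1])
    raw <- trimws(paste(kv[-1], collapse = "="))
    vals <- trimws(strsplit(raw, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(vals))
    val <- if (!anyNA(num)) num else vals
    if (is.null(section)) cfg[[key]] <- val
    else cfg[[section]][[key]] <- val
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Pipeline stage names, in dependency order
#' @export
PIPELINE_STAGES <- c("simulate", "rates", "auroc", "independence", "dpca",
                     "decoding", "behavior")

#' Run the analysis pipeline
#'
#' Executes the stages in dependency order on a synthetic session (or a
#' session loaded from `input_dir`), logging per-stage timing to stderr, and
#' returns a stage-keyed [result_store()].
#'
#' @param config Configuration list (see [default_config()], [read_config()]).
#' @param stages Character subset of stages to run (dependencies must be
#'   included or already present in `store`).
#' @param input_dir Optional directory from [write_session()]; when NULL a
#'   synthetic session is generated.
#' @param store Optional existing store to extend.
#' @return A `result_store` with one entry per executed stage.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = PIPELINE_STAGES,
                         input_dir = NULL, store = NULL) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  if (is.null(store)) store <- result_store(config)
  seed <- config$seed
  log_stage <- function(name, expr) {
    t0 <- proc.time()[3]
    val <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] done in %.1f s", name, proc.time()[3] - t0))
    val
  }
  if ("simulate" %in% stages) {
    store <- store_set(store, "simulate", log_stage("simulate", {
      if (!is.null(input_dir)) {
        ses <- read_session(input_dir)
        ses$trials <- select_correct_trials(ses$trials, quiet = TRUE)
        ses$spikes <- filter_included_units(ses$spikes)
        ses
      } else {
        sc <- config$synthetic
        pop <- make_population(sc$n_grip, sc$n_mixed, sc$n_force, sc$n_null,
                               scheme = sc$scheme, gain = sc$gain,
                               seed = child_seed(seed, "pop"))
        cfg <- task_config(n_trials_per_condition = sc$n_trials_per_condition,
                           seed = seed)
        simulate_session(cfg, pop,
                         bin_centers = rate_grid(config$rates$window,
                                                 config$rates$step_ms))
      }
    }), seed = seed)
  }
  ses <- store_get(store, "simulate")
  if ("rates" %in% stages) {
    store <- store_set(store, "rates", log_stage("rates", {
      rc <- config$rates
      list(smoothed = smooth_rates(ses$spikes, ses$trials, rc$tau_ms,
                                   rc$step_ms, rc$window),
           binned = bin_rates(ses$spikes, ses$trials, rc$bin_ms,
                              rc$spacing_ms, rc$window))
    }))
  }
  if ("auroc" %in% stages) {
    store <- store_set(store, "auroc", log_stage("auroc", {
      rts <- store_get(store, "rates")
      ac <- config$auroc
      single_unit_selectivity(rts$smoothed, ses$trials, n_perm = ac$n_perm,
                              alpha = ac$alpha, min_consec = ac$min_consec,
                              seed = child_seed(seed, "auroc"))
    }), seed = child_seed(seed, "auroc"))
  }
  if ("independence" %in% stages) {
    store <- store_set(store, "independence", log_stage("independence", {
      au <- store_get(store, "auroc")
      ic <- config$independence
      chi2 <- marginal_independence_test(au$grip$auroc, au$force$auroc,
                                         n_bins = ic$n_bins,
                                         n_perm = ic$n_perm,
                                         seed = child_seed(seed, "chi2"))
      sc <- strength_correlation(au$grip$delta, au$force$delta,
                                 n_shuffle = ic$n_shuffle,
                                 seed = child_seed(seed, "strength"))
      xt <- cross_temporal_correlation(au$grip$delta, au$force$delta,
                                       au$bin_centers, lags_ms = ic$lags_ms,
                                       n_shuffle = ic$n_shuffle,
                                       seed = child_seed(seed, "xtemp"))
      list(chi2 = chi2, strength = sc, cross_temporal = xt)
    }), seed = child_seed(seed, "independence"))
  }
  if ("dpca" %in% stages) {
    store <- store_set(store, "dpca", log_stage("dpca", {
      rts <- store_get(store, "rates")
      dc <- config$dpca
      X <- condition_tensor(rts$smoothed, ses$trials)
      model <- fit_dpca(X, n_components = dc$n_components, mu = dc$mu)
      cls <- lapply(c(grip = "grip", force = "force",
                      interaction = "interaction"), function(mg)
        first_significant_component(model, rts$smoothed, ses$trials, mg,
                                    n_iter = dc$n_iter,
                                    n_shuffle = dc$n_shuffle,
                                    min_consec = dc$min_consec,
                                    seed = child_seed(seed, mg)))
      list(model = model, classifiers = cls,
           variance = explained_variance(model))
    }), seed = child_seed(seed, "dpca"))
  }
  if ("decoding" %in% stages) {
    store <- store_set(store, "decoding", log_stage("decoding", {
      rts <- store_get(store, "rates")
      dc <- config$decoding
      lapply(c(grip = "grip", force = "force"), function(par)
        cross_temporal_analysis(
          rts$binned, ses$trials[[par]], ses$trials, n_rep = dc$n_rep,
          train_per_class = dc$train_per_class,
          test_per_class = dc$test_per_class, n_null = dc$n_null,
          min_consec = dc$min_consec,
          seed = child_seed(seed, paste0("dec-", par))))
    }), seed = child_seed(seed, "decoding"))
  }
  if ("behavior" %in% stages) {
    store <- store_set(store, "behavior", log_stage("behavior", {
      bs <- behavior_summary(ses$trials)
      fc <- NULL
      if (!is.null(ses$force) && !is.null(store$stages$dpca)) {
        dp <- store_get(store, "dpca")
        rts <- store_get(store, "rates")
        tab <- dp$model$components
        comp_of <- function(mg) tab$component[tab$marginalization == mg][1]
        if (!is.na(comp_of("force")) && !is.na(comp_of("time"))) {
          pf <- dpca_project(dp$model, rts$smoothed, comp_of("force"))
          pt <- dpca_project(dp$model, rts$smoothed, comp_of("time"))
          fc <- force_dpc_correlation(ses$force, pf, pt, ses$trials$force,
                                      lag_ms = config$behavior$lag_ms,
                                      n_null = config$behavior$n_null,
                                      seed = child_seed(seed, "force-dpc"))
        }
      }
      list(summary = bs, force_dpc = fc)
    }), seed = child_seed(seed, "behavior"))
  }
  store
}
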