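#' @keywords internal
#' @importFrom stats rnorm runif rpois predict
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed for a named pipeline stage
#'
#' One global seed is expanded into per-stage seeds so that each stage is
#' independently reproducible. The mapping is a fixed integer hash of the
#' stage name combined with the parent seed; results stay below 2^31.
#'
#' @param seed Parent integer seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31)`.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer(((abs(seed) %% 2147483647) * 31 + h * 2654435) %% 2147483647)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so surrounding RNG state is untouched.
#'
#' @param seed Integer seed (NULL leaves the RNG stream alone).
#' @param expr Expression to evaluate.
#' @return Value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# runs of TRUE with length >= min_consec, as a logical mask
run_mask <- function(x, min_consec = 2L) {
  x <- as.logical(x)
  x[is.na(x)] <- FALSE
  r <- rle(x)
  keep <- r$values & r$lengths >= min_consec
  rep(keep, r$lengths)
}

# truncated normal by rejection; lower bound only
rtruncnorm_lower <- function(n, mean, sd, lower = 20) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower]
  }
  out
}

# permutation p-value with add-one correction
perm_p <- function(null_stats, observed) {
  (1 + sum(null_stats >= observed)) / (1 + length(null_stats))
}
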