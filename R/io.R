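# Reading, writing and validating the pipeline's data objects. Trial tables
# travel as tab-separated text (human-auditable); spike trains as a long
# three-column table; bulk arrays and the stage-keyed ResultStore as RDS at
# run time.

EVENT_COLS <- c("switch_on", "cue_on", "cue_off", "go", "movement_on",
                "touch", "pull_on", "release", "reward")

#' Validate a trial table
#'
#' Checks column presence, condition labels, and event-order monotonicity
#' (`switch_on < cue_on < cue_off < go <= movement_on < touch <= pull_on <
#' release`) on every correct trial.
#'
#' @param trials A data.frame to validate.
#' @return The validated `trial_table` (invisibly classed), or an error naming
#'   the offending field and row.
#' @export
validate_trial_table <- function(trials) {
  need <- c("trial_id", "grip", "force", "correct", EVENT_COLS)
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  ok <- trials$correct
  if (any(ok & (is.na(trials$grip) | is.na(trials$force))))
    stop("trial table: grip/force missing on a correct trial", call. = FALSE)
  if (!all(trials$grip %in% c("side", "precision")))
    stop("trial table: field 'grip' must be side/precision", call. = FALSE)
  if (!all(trials$force %in% c("low", "high")))
    stop("trial table: field 'force' must be low/high", call. = FALSE)
  seq_cols <- c("switch_on", "cue_on", "cue_off", "go", "movement_on",
                "touch", "pull_on", "release")
  strict <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  for (r in which(ok)) {
    v <- as.numeric(trials[r, seq_cols])
    d <- diff(v)
    bad <- which(ifelse(strict, d <= 0, d < 0))
    if (length(bad))
      stop(sprintf("trial table: row %d violates event order (%s !< %s)",
                   r, seq_cols[bad[1]], seq_cols[bad[1] + 1]), call. = FALSE)
  }
  if (!inherits(trials, "trial_table"))
    class(trials) <- c("trial_table", "data.frame")
  invisible(trials)
}

#' Keep only correct trials
#'
#' All analyses run on correct trials only; per-condition counts are reported
#' as a message.
#'
#' @param trials A `trial_table`.
#' @param quiet Suppress the count message.
#' @return The correct-trial subset (errors if empty).
#' @export
select_correct_trials <- function(trials, quiet = FALSE) {
  out <- trials[trials$correct, , drop = FALSE]
  if (nrow(out) == 0) stop("no correct trials", call. = FALSE)
  if (!quiet) {
    tab <- table(out$grip, out$force)
    message("correct trials per condition: ",
            paste(sprintf("%s/%s=%d", rep(rownames(tab), ncol(tab)),
                          rep(colnames(tab), each = nrow(tab)), tab),
                  collapse = ", "))
  }
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Write a synthetic or recorded session to disk
#'
#' Trials become `trials.tsv`; spike trains a long `spikes.tsv`
#' (`unit_id, trial_id, time_ms`) plus `units.tsv`; force traces
#' `force.tsv` with the time grid in the header row.
#'
#' @param session List with `trials`, `spikes`, and optionally `force`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(session$trials, file.path(dir, "trials.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  sp <- session$spikes
  utils::write.table(sp$units, file.path(dir, "units.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  long <- do.call(rbind, lapply(seq_along(sp$spikes), function(u) {
    do.call(rbind, lapply(seq_along(sp$spikes[[u]]), function(r) {
      ts <- sp$spikes[[u]][[r]]
      if (!length(ts)) return(NULL)
      data.frame(unit_id = sp$units$unit_id[u], trial_id = sp$trial_ids[r],
                 time_ms = ts)
    }))
  }))
  if (is.null(long)) long <- data.frame(unit_id = integer(), trial_id = integer(),
                                        time_ms = numeric())
  utils::write.table(format(long, digits = 15, scientific = FALSE, trim = TRUE),
                     file.path(dir, "spikes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(session$force)) {
    f <- session$force
    df <- as.data.frame(unclass(f))
    names(df) <- paste0("t", attr(f, "bin_centers"))
    df <- cbind(trial_id = session$trials$trial_id, df)
    utils::write.table(df, file.path(dir, "force.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param path Session directory.
#' @return List with validated `trials`, `spikes` (`spike_data`), and `force`
#'   (or NULL).
#' @export
read_session <- function(path) {
  tf <- file.path(path, "trials.tsv")
  if (!file.exists(tf)) stop("no trials.tsv under ", path, call. = FALSE)
  trials <- utils::read.table(tf, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  trials <- validate_trial_table(trials)
  units <- utils::read.table(file.path(path, "units.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  if (!any(units$included))
    stop("no analyzable units: every unit has included = FALSE", call. = FALSE)
  long <- utils::read.table(file.path(path, "spikes.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  spikes <- lapply(units$unit_id, function(u) {
    lapply(trials$trial_id, function(r) {
      ts <- long$time_ms[long$unit_id == u & long$trial_id == r]
      sort(as.numeric(ts))
    })
  })
  sd <- structure(list(units = units, spikes = spikes,
                       trial_ids = trials$trial_id), class = "spike_data")
  ff <- file.path(path, "force.tsv")
  force <- NULL
  if (file.exists(ff)) {
    fdf <- utils::read.table(ff, header = TRUE, sep = "\t",
                             check.names = FALSE)
    bc <- as.numeric(sub("^t", "", names(fdf)[-1]))
    force <- structure(as.matrix(fdf[, -1, drop = FALSE]),
                       class = "force_traces", bin_centers = bc,
                       force = trials$force)
    dimnames(force) <- NULL
  }
  list(trials = trials, spikes = sd, force = force)
}

#' Drop units flagged as outside the motor-cortex array region
#'
#' Only units with `included = TRUE` (electrodes posterior to the putative
#' premotor/M1 border in the recorded data) enter the analyses.
#'
#' @param spikes A `spike_data` object.
#' @return A `spike_data` with excluded units removed (errors if none remain).
#' @export
filter_included_units <- function(spikes) {
  keep <- which(spikes$units$included)
  if (!length(keep)) stop("no analyzable units", call. = FALSE)
  structure(list(units = spikes$units[keep, , drop = FALSE],
                 spikes = spikes$spikes[keep],
                 trial_ids = spikes$trial_ids), class = "spike_data")
}

#' Create an empty stage-keyed result store
#'
#' A versioned in-memory container keyed by pipeline stage, carrying the
#' config and seeds that produced each entry so that every stored result is
#' regenerable.
#'
#' @param config The pipeline configuration list.
#' @return An object of class `result_store`.
#' @export
result_store <- function(config = list()) {
  structure(list(version = 1L, config = config, stages = list()),
            class = "result_store")
}

#' Insert a stage result into a store
#' @param store A `result_store`.
#' @param stage Stage name.
#' @param value Stage output.
#' @param seed Seed the stage ran under (stored for provenance).
#' @return The updated store.
#' @export
store_set <- function(store, stage, value, seed = NULL) {
  store$stages[[stage]] <- list(value = value, seed = seed,
                                time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  store
}

#' Fetch a stage result
#' @param store A `result_store`.
#' @param stage Stage name.
#' @return The stored value (errors if absent).
#' @export
store_get <- function(store, stage) {
  if (is.null(store$stages[[stage]]))
    stop("result store: stage '", stage, "' not present", call. = FALSE)
  store$stages[[stage]]$value
}

#' Save / load a result store (RDS)
#' @param store A `result_store`.
#' @param path File path.
#' @return `path` (write) or the store (read).
#' @export
write_result_store <- function(store, path) {
  saveRDS(store, path); invisible(path)
}

#' @rdname write_result_store
#' @export
read_result_store <- function(path) readRDS(path)

#' @export
print.trial_table <- function(x, ...) {
  cat(sprintf("trial_table: %d trials (%d correct), %s\n", nrow(x),
              sum(x$correct),
              paste(capture_counts(x), collapse = ", ")))
  invisible(x)
}

capture_counts <- function(x) {
  tab <- table(x$grip, x$force)
  sprintf("%s/%s=%d", rep(rownames(tab), ncol(tab)),
          rep(colnames(tab), each = nrow(tab)), as.vector(tab))
}

#' @export
print.spike_data <- function(x, ...) {
  nsp <- sum(vapply(x$spikes, function(u) sum(lengths(u)), 0))
  cat(sprintf("spike_data: %d units (%d included), %d trials, %d spikes\n",
              nrow(x$units), sum(x$units$included), length(x$trial_ids), nsp))
  invisible(x)
}
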