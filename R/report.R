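# Figure rendering and the machine-readable results manifest.

#' Assemble report figures and a results manifest from a result store
#'
#' Renders the standard panels (unit-sorted delta-auROC heatmaps, mean
#' delta-auROC time courses, auROC scatter with covariance ellipse, demixed
#' component projections with significance underlines, cross-temporal
#' accuracy heatmaps with static-bin overlays, generalization-index curves,
#' explained-variance bars) as PDF files, and writes a JSON manifest of the
#' key numbers, every one of which is re-derivable from the store. Report
#' generation never modifies the store.
#'
#' @param store A `result_store` from [run_pipeline()].
#' @param out_dir Output directory.
#' @return The manifest list (invisibly); files land in `out_dir`.
#' @export
build_report <- function(store, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(version = store$version,
                   seed = store$config$seed,
                   stages = names(store$stages), figures = character(0))
  have <- function(s) !is.null(store$stages[[s]])
  missing_stages <- setdiff(c("rates", "auroc"), names(store$stages))
  if (length(missing_stages))
    warning("build_report: missing stage(s) ",
            paste(missing_stages, collapse = ", "),
            "; rendering a partial report", call. = FALSE)
  fig <- function(name, expr) {
    path <- file.path(out_dir, paste0(name, ".pdf"))
    grDevices::pdf(path, width = 7, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    expr
    manifest$figures <<- c(manifest$figures, path)
  }
  if (have("auroc")) {
    au <- store_get(store, "auroc")
    cnt <- classify_selectivity(au)
    manifest$selectivity_counts <- as.list(cnt)
    fig("delta_auroc_heatmaps", {
      graphics::par(mfrow = c(1, 2))
      for (par_ in c("grip", "force")) {
        res <- au[[par_]]
        sel <- which(res$encodes)
        if (!length(sel)) { graphics::plot.new(); next }
        peak <- apply(res$delta[sel, , drop = FALSE], 1, which.max)
        D <- res$delta[sel[order(peak)], , drop = FALSE]
        graphics::image(au$bin_centers, seq_along(sel), t(D),
                        xlab = "time re movement onset (ms)",
                        ylab = "unit (sorted by peak time)",
                        main = paste("delta auROC:", par_))
      }
    })
    fig("delta_auroc_timecourse", {
      graphics::plot(au$bin_centers, colMeans(au$grip$delta), type = "l",
                     col = "goldenrod", lwd = 2, ylab = "mean delta auROC",
                     xlab = "time re movement onset (ms)")
      graphics::lines(au$bin_centers, colMeans(au$force$delta),
                      col = "purple", lwd = 2)
      graphics::abline(v = 0)
      graphics::legend("topleft", c("grip", "force"), lwd = 2,
                       col = c("goldenrod", "purple"), bty = "n")
    })
  }
  if (have("auroc")) {
    au <- store_get(store, "auroc")
    b0 <- which.min(abs(au$bin_centers - 400))
    fig("auroc_scatter_ellipse", {
      x <- au$force$auroc[, b0]; y <- au$grip$auroc[, b0]
      graphics::plot(x, y, xlim = c(0, 1), ylim = c(0, 1),
                     xlab = "force auROC", ylab = "grip auROC",
                     main = "auROC scatter, +400 ms")
      el <- tryCatch(ellipse_angle(x, y), error = function(e) NULL)
      if (!is.null(el)) {
        th <- seq(0, 2 * pi, length.out = 181)
        pts <- cbind(el$semi_axes[1] * cos(th), el$semi_axes[2] * sin(th)) %*%
          t(el$eigen$vectors)
        graphics::lines(pts[, 1] + el$center[1], pts[, 2] + el$center[2],
                        col = "blue")
        graphics::title(sub = sprintf("theta = %.1f deg", el$theta_deg))
        manifest$ellipse_theta_deg <- el$theta_deg
      }
    })
  }
  if (have("dpca")) {
    dp <- store_get(store, "dpca")
    manifest$dpca_variance_pct <- as.list(dp$variance$marginalization)
    manifest$dpca_first_significant <- lapply(dp$classifiers,
                                              function(z) z$component)
    fig("dpca_variance", {
      graphics::barplot(dp$variance$marginalization,
                        ylab = "% explained variance",
                        main = "variance per marginalization")
    })
  }
  if (have("decoding")) {
    dec <- store_get(store, "decoding")
    manifest$static_cells <- lapply(dec, function(z) sum(z$static))
    manifest$mean_gi <- lapply(dec, function(z)
      list(preparation = mean(z$gi["preparation", ]),
           execution = mean(z$gi["execution", ])))
    fig("cross_temporal", {
      graphics::par(mfrow = c(2, 2))
      for (par_ in names(dec)) {
        z <- dec[[par_]]
        graphics::image(z$bin_centers, z$bin_centers, z$matrix,
                        xlab = "train (ms)", ylab = "test (ms)",
                        main = paste("accuracy:", par_))
        graphics::image(z$bin_centers, z$bin_centers, z$static,
                        xlab = "train (ms)", ylab = "test (ms)",
                        main = paste("static bins:", par_))
      }
    })
    fig("generalization_index", {
      graphics::par(mfrow = c(1, length(dec)))
      for (par_ in names(dec)) {
        z <- dec[[par_]]
        graphics::plot(z$bin_centers, z$gi["preparation", ], type = "l",
                       col = "blue", ylim = c(0, 1), xlab = "test (ms)",
                       ylab = "generalization index", main = par_)
        graphics::lines(z$bin_centers, z$gi["execution", ], col = "red")
        graphics::legend("topleft", c("train: preparation",
                                      "train: execution"),
                         col = c("blue", "red"), lwd = 1, bty = "n")
      }
    })
  }
  if (have("behavior")) {
    bh <- store_get(store, "behavior")
    manifest$behavior <- list(per_subject = bh$summary$per_subject)
    if (!is.null(bh$force_dpc))
      manifest$force_dpc_prop_significant <-
        as.list(bh$force_dpc$prop_significant)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
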