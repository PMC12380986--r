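#' Assemble a pipeline run configuration
#'
#' Exactly one of `stacks` (pre-built annual layer stacks) or `generator`
#' (an [generator_config()], from which the landscape is simulated) must be
#' provided.
#'
#' @param generator an [generator_config()], or `NULL` when `stacks` given.
#' @param stacks a list of annual layer stacks, or `NULL`.
#' @param segmentation an [segmentation_params()].
#' @param use_segmentation run stand segmentation and restrict the conifer
#'   mosaic to conifer-modal stands (default `TRUE`); when `FALSE`, the
#'   conifer mosaic is taken from the land-cover raster directly.
#' @param features an [feature_config()].
#' @param rf an [rf_params()].
#' @param fit_annual_models fit the per-year stratified-CV models as well as
#'   the full time-series model.
#' @param outdir output directory for tables, maps and the manifest.
#' @param seed global seed; stage seeds are derived from it (balancing:
#'   `seed + 11`, model fits: `seed + 13`, importance: `seed + 17`).
#' @return a `run_config` list.
#' @export
run_config <- function(generator = NULL, stacks = NULL,
                       segmentation = segmentation_params(),
                       use_segmentation = TRUE,
                       features = feature_config(), rf = NULL,
                       fit_annual_models = TRUE,
                       outdir = tempfile("sbwrun"), seed = 1) {
  if (is.null(generator) == is.null(stacks))
    stop("provide exactly one of `generator` or `stacks`")
  if (is.null(rf)) rf <- rf_params(seed = seed + 13)
  structure(list(generator = generator, stacks = stacks,
                 segmentation = segmentation,
                 use_segmentation = use_segmentation,
                 features = features, rf = rf,
                 fit_annual_models = fit_annual_models,
                 outdir = outdir, seed = as.integer(seed)),
            class = "sbw_run_config")
}

#' Run the full analysis pipeline
#'
#' Executes generate (or load) -> mask -> segment -> tile metrics -> label
#' -> features -> search-radius filter -> balance -> model, writing
#' intermediate tables as CSV, probability maps as ESRI ASCII grids, the
#' tile grid as GeoJSON, and a JSON manifest (config snapshot, package
#' version, per-file checksums, fold composition, warnings). A failure in
#' one year's stages is logged and that year skipped; other years proceed.
#'
#' @param config a [run_config()] (or YAML path, see [read_run_config()]).
#' @return the manifest (list, class `sbw_run_manifest`) with the fitted
#'   models attached as attribute `"models"`. `manifest$status` is `"ok"`
#'   when models were fitted and `"no-model"` when no year yielded both
#'   disturbed and undisturbed tiles.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "sbw_run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character()
  note <- function(...) {
    msg <- sprintf(...)
    warnings_log <<- c(warnings_log, msg)
    message(msg)
  }

  stacks <- if (!is.null(config$generator))
    generate_landscape(config$generator) else config$stacks
  geo <- stacks[[1]]$geo
  nr <- nrow(stacks[[1]]$land_cover); nc <- ncol(stacks[[1]]$land_cover)
  for (s in stacks) {
    if (!identical(dim(s$land_cover), c(nr, nc)) ||
        !identical(s$geo, geo))
      stop(sprintf("misaligned rasters: year %d is %d x %d (cell %g m), expected %d x %d (cell %g m)",
                   s$year, nrow(s$land_cover), ncol(s$land_cover),
                   s$geo$cell_size, nr, nc, geo$cell_size))
  }
  grid <- tile_grid(nr, nc, geo$cell_size)
  masks <- build_mask(stacks)

  per_year <- list()
  labels_all <- NULL
  skipped <- integer()
  for (i in seq_along(stacks)) {
    st <- stacks[[i]]
    res <- tryCatch({
      msk <- masks[[i]]
      sm <- NULL
      if (config$use_segmentation) {
        sm <- segment_stands(st, nodata_mask = msk,
                             params = config$segmentation)
      }
      met <- tile_metrics(st$land_cover, grid, mask = msk, stand_map = sm)
      lab <- label_tiles(grid, st$severity, msk, st$land_cover, st$year)
      polys <- disturbance_polygons(st$severity, grid)
      circ <- withCallingHandlers(
        search_radius(polys, config$features),
        warning = function(w) {
          note("year %d: %s", st$year, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      list(year = st$year, met = met, lab = lab, circle = circ)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      note("year %d failed and was skipped: %s", st$year,
           conditionMessage(res))
      skipped <- c(skipped, st$year)
      next
    }
    per_year[[as.character(st$year)]] <- res
    labels_all <- rbind(labels_all, res$lab)
  }
  # a tile contributes a disturbed sample only at infestation onset
  labels_all <- filter_onset(labels_all)
  samples <- NULL
  for (py in per_year) {
    lab <- labels_all[labels_all$year == py$year, ]
    feats <- build_features(py$met, lab, config$features)
    feats <- filter_by_radius(feats, grid, py$circle)
    samples <- rbind(samples, feats)
  }
  excl <- if (!is.null(labels_all))
    mean(labels_all$status == "excluded") else NA_real_
  if (!is.na(excl))
    note("excluded tile-year fraction: %.3f", excl)

  balanced <- if (!is.null(samples) && nrow(samples) > 0)
    balance_samples(samples, seed = config$seed + 11) else samples

  models <- list(full = NULL, annual = list())
  status <- "no-model"
  if (!is.null(balanced) && nrow(balanced) > 0 &&
      length(unique(balanced$year)) >= 2 &&
      length(unique(balanced$label)) == 2) {
    models$full <- fit_full_series(balanced, config$rf, config$features)
    status <- "ok"
    if (config$fit_annual_models) {
      for (y in sort(unique(balanced$year))) {
        m <- tryCatch(fit_annual(balanced, y, config$rf, config$features),
                      error = function(e) {
                        note("annual model %d skipped: %s", y,
                             conditionMessage(e))
                        NULL
                      })
        if (!is.null(m)) models$annual[[as.character(y)]] <- m
      }
    }
  } else {
    note("model stage skipped: no year with both disturbed and undisturbed tiles")
  }

  # ---- outputs ----
  out <- config$outdir
  paths <- character()
  wr <- function(obj, name) {
    p <- file.path(out, name)
    write.csv(obj, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(labels_all)) wr(labels_all, "tile_labels.csv")
  if (!is.null(samples) && nrow(samples)) wr(samples, "tile_samples.csv")
  if (!is.null(balanced) && nrow(balanced))
    wr(balanced, "tile_samples_balanced.csv")
  p <- file.path(out, "tile_grid.geojson")
  write_tile_geojson(grid, p); paths <- c(paths, p)
  fold_composition <- list()
  if (!is.null(models$full)) {
    wr(models$full$pooled, "probabilities_full_series.csv")
    wr(models$full$roc, "roc_full_series.csv")
    fold_composition$full <- lapply(models$full$folds, function(f)
      list(test_year = f$year, train_years = f$train_years,
           n_train = f$n_train, n_test = f$n_test))
    # per-tile probability map for the last modelled year
    last <- models$full$folds[[length(models$full$folds)]]
    prob_map <- matrix(NA_real_, grid$n_tile_rows, grid$n_tile_cols)
    t <- grid$tiles[match(last$test$tile_id, grid$tiles$tile_id), ]
    prob_map[cbind(t$trow, t$tcol)] <- last$prob
    p <- file.path(out, sprintf("probability_map_%d.asc", last$year))
    write_ascii_grid(prob_map, p,
                     geo = list(origin = geo$origin,
                                cell_size = grid$tile_size))
    paths <- c(paths, p)
  }

  manifest <- list(package_version = as.character(utils::packageVersion("sbwrisk")),
                   status = status,
                   seed = config$seed,
                   years = vapply(stacks, `[[`, 0L, "year"),
                   skipped_years = skipped,
                   use_segmentation = config$use_segmentation,
                   rf = unclass(config$rf),
                   features = unclass(config$features),
                   segmentation = unclass(config$segmentation),
                   excluded_fraction = excl,
                   fold_composition = fold_composition,
                   warnings = warnings_log,
                   outputs = as.list(setNames(unname(tools::md5sum(paths)),
                                              basename(paths))))
  mp <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest$outdir <- out
  class(manifest) <- "sbw_run_manifest"
  attr(manifest, "models") <- models
  manifest
}

#' @export
print.sbw_run_manifest <- function(x, ...) {
  cat(sprintf("sbw_run_manifest: status %s, %d year(s), outputs in %s\n",
              x$status, length(x$years), x$outdir))
  if (length(x$warnings)) cat("  notes:", length(x$warnings), "\n")
  invisible(x)
}

#' Render the summary report panels for a pipeline run
#'
#' Writes five PNG panels into `outdir`: disturbed-vs-undisturbed mean
#' metric time series, the pooled ROC with its threshold, partial-dependence
#' curves of the six focal metrics, the permutation-importance boxplot, and
#' per-year probability distributions. When no model was fitted, the report
#' notes the absence instead of failing.
#'
#' @param manifest an `sbw_run_manifest` from [run_pipeline()].
#' @param outdir output directory (defaults to the run's).
#' @param n_perm permutation count for the importance panel.
#' @return character vector of files written.
#' @export
report_run <- function(manifest, outdir = manifest$outdir, n_perm = 20) {
  stopifnot(inherits(manifest, "sbw_run_manifest"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  models <- attr(manifest, "models")
  files <- character()
  panel <- function(name, fun) {
    p <- file.path(outdir, name)
    grDevices::png(p, width = 900, height = 700)
    ok <- tryCatch({ fun(); TRUE },
                   error = function(e) { graphics::plot.new(); FALSE })
    grDevices::dev.off()
    files <<- c(files, p)
    ok
  }
  samples_path <- file.path(manifest$outdir, "tile_samples.csv")
  samples <- if (file.exists(samples_path))
    utils::read.csv(samples_path) else NULL

  panel("metric_time_series.png", function() {
    if (is.null(samples) || !nrow(samples)) {
      no_model_note("no samples available"); return(invisible())
    }
    graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
    for (m in METRIC_NAMES) {
      col <- paste0(m, "_focal")
      agg <- aggregate(samples[[col]],
                       list(year = samples$year, label = samples$label),
                       mean)
      yl <- range(agg$x)
      graphics::plot(NA, xlim = range(agg$year), ylim = yl,
                     xlab = "year", ylab = m, main = m)
      for (l in 0:1)
        graphics::lines(agg$year[agg$label == l], agg$x[agg$label == l],
                        col = c("forestgreen", "red")[l + 1], lwd = 2)
    }
  })
  panel("roc.png", function() {
    if (is.null(models$full)) { no_model_note(); return(invisible()) }
    plot(models$full)
    for (f in models$full$folds)
      graphics::lines(roc_curve(f$prob, f$test$label)[, c("fpr", "tpr")],
                      col = "grey70")
  })
  panel("partial_dependence.png", function() {
    if (is.null(models$full)) { no_model_note(); return(invisible()) }
    graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
    for (m in METRIC_NAMES) {
      f <- paste0(m, "_focal")
      if (!f %in% models$full$final_stats$keep) {
        graphics::plot.new(); graphics::title(main = paste(m, "(dropped)"))
        next
      }
      pd <- partial_dependence(models$full, f)
      graphics::plot(pd$value, pd$pd, type = "b", xlab = m,
                     ylab = "P(disturbed)", main = m)
      graphics::abline(h = models$full$threshold, lty = 2, col = "red")
    }
  })
  panel("importance.png", function() {
    if (is.null(models$full)) { no_model_note(); return(invisible()) }
    imp <- permutation_importance(models$full, n_perm = n_perm,
                                  seed = manifest$seed + 17)
    d <- attr(imp, "distribution")
    ord <- order(apply(d, 1, median), decreasing = TRUE)
    graphics::par(mar = c(8, 4, 2, 1))
    graphics::boxplot(t(d[ord, ]), las = 2,
                      ylab = "accuracy decrease",
                      main = "Permutation importance")
  })
  panel("annual_probabilities.png", function() {
    if (is.null(models$full)) { no_model_note(); return(invisible()) }
    p <- models$full$pooled
    graphics::boxplot(prob ~ year, data = p,
                      ylab = "P(disturbed)", xlab = "year",
                      main = "Out-of-fold probabilities by year")
    graphics::abline(h = models$full$threshold, lty = 2, col = "red")
  })
  files
}

no_model_note <- function(msg = "no model was fitted for this run") {
  graphics::plot.new()
  graphics::text(0.5, 0.5, msg, cex = 1.4)
}
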