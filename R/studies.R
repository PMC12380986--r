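#' Parameter-recovery simulation study
#'
#' Generates a synthetic multi-year landscape whose tile-level infestation
#' odds are driven by known configuration effects, runs the analysis chain
#' (tile metrics, labelling, multi-scale features, balancing, temporal CV
#' random forest), and extracts the diagnostics needed to check that the
#' generative effects are recovered: pooled AUC, permutation importance and
#' the partial dependence of the focal largest-patch-index feature. The
#' default effects (log-odds falling one unit per standard deviation of LPI
#' and half a unit per standard deviation of PA) encode the fragmentation
#' hypothesis: smaller, less dominant conifer patches carry more risk.
#'
#' The conifer mosaic is measured directly on the land-cover raster (the
#' same measurement pathway the generative model uses), so the study tests
#' the feature/label/model chain, not the segmenter.
#'
#' @param seed integer seed for the whole study.
#' @param effect_beta named generative coefficients (see
#'   [generator_config()]); `NULL` or an empty vector gives the null model.
#' @param n_perm permutation count for the importance diagnostic.
#' @param grid_size landscape edge length in cells.
#' @param years simulated years.
#' @return list: `model` (`sbw_rf`), `importance` (data.frame),
#'   `pd_lpi` (partial-dependence curve of `LPI_focal`), `n` (pooled test
#'   samples), `auc`, `threshold`.
#' @export
recovery_study <- function(seed = 1, effect_beta = c(LPI = -1.0, PA = -0.5),
                           n_perm = 100, grid_size = 600, years = 2008:2015) {
  cfg <- generator_config(grid_height = grid_size, grid_width = grid_size,
                          years = years, effect_beta = effect_beta,
                          seed = seed)
  # the dispersal extension of the annual search radius scales with the
  # domain so the radius control keeps its geometry on the compressed
  # landscape (75 km on a ~300 km study area = a quarter of the domain edge)
  fc <- feature_config(search_radius_extension =
                         0.25 * grid_size * cfg$cell_size)
  rc <- run_config(generator = cfg, use_segmentation = FALSE,
                   fit_annual_models = FALSE, rf = rf_params(seed = seed + 13),
                   features = fc,
                   outdir = file.path(tempdir(), paste0("sbw_study_", seed)),
                   seed = seed)
  manifest <- suppressMessages(run_pipeline(rc))
  model <- attr(manifest, "models")$full
  if (is.null(model)) stop("study produced no model (no disturbed tiles?)")
  imp <- permutation_importance(model, n_perm = n_perm, seed = seed + 17)
  pd <- if ("LPI_focal" %in% model$final_stats$keep)
    partial_dependence(model, "LPI_focal") else NULL
  list(model = model, importance = imp, pd_lpi = pd,
       n = nrow(model$pooled), auc = model$auc,
       threshold = model$threshold, manifest = manifest)
}

#' Count increases along a curve
#'
#' Number of grid steps on which a partial-dependence curve rises by more
#' than `tol` — the violation count used to judge monotonically
#' non-increasing dependence.
#'
#' @param pd data.frame with a `pd` column (see [partial_dependence()]).
#' @param tol increase tolerated as numerically flat.
#' @return integer count of rising steps.
#' @export
pd_increase_count <- function(pd, tol = 1e-9) {
  sum(diff(pd$pd) > tol)
}
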