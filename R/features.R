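#' Feature-construction configuration
#'
#' @param weights named multipliers for the focal tile and the merged 3 x 3
#'   and 5 x 5 tile regions (defaults 1, 0.4, 0.2).
#' @param scale_quantiles lower/upper quantiles of the robust feature
#'   scaling: features are centred to the training median and divided by the
#'   `q95 - q05` range (defaults 0.05, 0.95).
#' @param search_radius_extension metres added to the annual search radius
#'   beyond the northernmost qualifying disturbance polygon; the default
#'   75 km is a median dispersal distance for migratory budworm adults.
#' @param min_polygon_area_ha minimum polygon area (ha) to qualify as the
#'   northernmost anchor of the search radius (default 5).
#' @return validated list of class `sbw_feature_config`.
#' @export
feature_config <- function(weights = c(focal = 1, ring3 = 0.4, ring5 = 0.2),
                           scale_quantiles = c(0.05, 0.95),
                           search_radius_extension = 75000,
                           min_polygon_area_ha = 5) {
  stopifnot(length(weights) == 3, all(weights > 0),
            length(scale_quantiles) == 2,
            all(scale_quantiles > 0 & scale_quantiles < 1),
            scale_quantiles[1] < scale_quantiles[2],
            search_radius_extension >= 0, min_polygon_area_ha >= 0)
  names(weights) <- c("focal", "ring3", "ring5")
  structure(list(weights = weights, scale_quantiles = scale_quantiles,
                 search_radius_extension = search_radius_extension,
                 min_polygon_area_ha = min_polygon_area_ha),
            class = "sbw_feature_config")
}

SCALE_TAGS <- c("focal", "3x3", "5x5")

#' Configuration metrics per tile at three scales
#'
#' Computes the six conifer configuration metrics for every tile of the
#' tessellation, for the focal tile window and for the merged 3 x 3 and
#' 5 x 5 tile regions centred on it (metrics are computed on the merged
#' window, not averaged over member tiles). Ring rows are `NA` for edge
#' tiles whose neighbourhood is incomplete.
#'
#' The conifer mosaic defaults to `land_cover == conifer`; when a segmented
#' stand map with modal covers is supplied, cells belong to the conifer
#' mosaic when their stand's modal land cover is conifer.
#'
#' @param land_cover categorical raster.
#' @param grid an [tile_grid()].
#' @param mask optional logical raster, `TRUE` = nodata.
#' @param stand_map optional `sbw_stand_map` with modal covers assigned.
#' @return data.frame: `tile_id`, `scale` (`focal`, `3x3`, `5x5`) and the six
#'   metric columns.
#' @export
tile_metrics <- function(land_cover, grid, mask = NULL, stand_map = NULL) {
  stopifnot(inherits(grid, "sbw_tile_grid"))
  conifer <- if (!is.null(stand_map)) {
    if (is.null(stand_map$modal_cover_raster))
      stop("stand_map has no modal covers; run assign_modal_cover() first")
    m <- stand_map$modal_cover_raster == LC_CONIFER
    m[is.na(m)] <- FALSE
    m
  } else {
    land_cover == LC_CONIFER
  }
  cls <- matrix(0L, nrow(conifer), ncol(conifer))
  cls[conifer] <- 1L
  if (is.null(mask)) mask <- matrix(FALSE, nrow(cls), ncol(cls))
  valid <- !mask
  tiles <- grid$tiles
  half <- c(0L, 1L, 2L)
  out <- vector("list", nrow(tiles) * 3)
  k <- 0
  for (i in seq_len(nrow(tiles))) {
    for (s in 1:3) {
      k <- k + 1
      tr <- tiles$trow[i] + (-half[s]):half[s]
      tc <- tiles$tcol[i] + (-half[s]):half[s]
      if (min(tr) < 1 || max(tr) > grid$n_tile_rows ||
          min(tc) < 1 || max(tc) > grid$n_tile_cols) {
        out[[k]] <- c(tiles$tile_id[i], s, rep(NA_real_, 6))
        next
      }
      cc <- tile_cells(grid, tr, tc)
      m <- compute_metrics(cls[cc$rows, cc$cols, drop = FALSE], class = 1L,
                           valid = valid[cc$rows, cc$cols, drop = FALSE],
                           cell_size = grid$cell_size)
      out[[k]] <- c(tiles$tile_id[i], s, m)
    }
  }
  res <- as.data.frame(do.call(rbind, out))
  names(res) <- c("tile_id", "scale_idx", METRIC_NAMES)
  res$scale <- SCALE_TAGS[res$scale_idx]
  res[, c("tile_id", "scale", METRIC_NAMES)]
}

#' Assemble weighted tile-sample feature vectors
#'
#' Joins multi-scale tile metrics with tile labels for one year and builds
#' the 18-dimensional feature vector (6 metrics x 3 scales), each scale's
#' metrics multiplied by its weight. Only tiles labelled `disturbed` or
#' `undisturbed` are kept; tiles with any missing feature (edge tiles with
#' incomplete rings, or windows without conifer) are dropped. Features are
#' *not* scaled here: robust scaling statistics belong to the model fit,
#' where they are estimated on training data only (see [fit_full_series()]).
#'
#' @param metrics output of [tile_metrics()] for one year.
#' @param labels output of [label_tiles()] for the same year.
#' @param cfg an [feature_config()].
#' @return data.frame: `tile_id`, `year`, `label` (1 = disturbed) and 18
#'   feature columns named `<METRIC>_<scale>`.
#' @export
build_features <- function(metrics, labels, cfg = feature_config()) {
  stopifnot(inherits(cfg, "sbw_feature_config"))
  keep <- labels[labels$status %in% c("disturbed", "undisturbed"), ]
  if (nrow(keep) == 0) return(empty_samples())
  wide <- NULL
  for (s in 1:3) {
    m <- metrics[metrics$scale == SCALE_TAGS[s], c("tile_id", METRIC_NAMES)]
    m[METRIC_NAMES] <- m[METRIC_NAMES] * cfg$weights[s]
    names(m)[-1] <- paste0(METRIC_NAMES, "_", SCALE_TAGS[s])
    wide <- if (is.null(wide)) m else merge(wide, m, by = "tile_id")
  }
  out <- merge(keep[, c("tile_id", "year", "status")], wide, by = "tile_id")
  out$label <- as.integer(out$status == "disturbed")
  out$status <- NULL
  out <- out[complete.cases(out), ]
  out <- out[order(out$tile_id), ]
  rownames(out) <- NULL
  out[, c("tile_id", "year", "label", feature_names())]
}

feature_names <- function() {
  as.vector(t(outer(METRIC_NAMES, SCALE_TAGS, paste, sep = "_")))
}

empty_samples <- function() {
  out <- data.frame(tile_id = integer(), year = integer(), label = integer())
  for (f in feature_names()) out[[f]] <- numeric()
  out
}

#' Balance disturbed and undisturbed samples within each year
#'
#' Random undersampling of the majority class without replacement, applied
#' independently per year. Years with no disturbed (or no undisturbed) tiles
#' contribute nothing.
#'
#' @param samples data.frame from [build_features()] (possibly several years
#'   bound together).
#' @param seed integer seed for the undersampling draw.
#' @return balanced data.frame, ordered by year then tile id.
#' @export
balance_samples <- function(samples, seed = 1) {
  set.seed(seed)
  parts <- lapply(split(samples, samples$year), function(d) {
    pos <- which(d$label == 1); neg <- which(d$label == 0)
    n <- min(length(pos), length(neg))
    if (n == 0) return(d[integer(0), ])
    keep <- c(if (length(pos) > n) sort(sample(pos, n)) else pos,
              if (length(neg) > n) sort(sample(neg, n)) else neg)
    d[sort(keep), ]
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Dissolve a severity raster into disturbance polygons
#'
#' Maximal 8-connected patches of cells at or above `min_severity` stand in
#' for the annual aerial-survey disturbance polygons. Each polygon carries
#' its area, area centroid (cell-centre average) and the vertex of maximum
#' northing (north-west corner of its northernmost cell), which is the
#' representative point the search radius must cover.
#'
#' @param severity integer severity raster.
#' @param grid an [tile_grid()] (supplies geometry).
#' @param min_severity minimum severity class included (default 1: any
#'   defoliation).
#' @return data.frame: `polygon`, `cells`, `area_ha`, `centroid_easting`,
#'   `centroid_northing`, `north_easting`, `north_northing`.
#' @export
disturbance_polygons <- function(severity, grid, min_severity = 1) {
  stopifnot(inherits(grid, "sbw_tile_grid"))
  cs <- grid$cell_size
  ind <- matrix(0L, nrow(severity), ncol(severity))
  ind[severity >= min_severity] <- 1L
  lab <- .label_patches_cpp(ind, 1L, matrix(TRUE, nrow(ind), ncol(ind)))
  k <- length(lab$cells)
  if (k == 0)
    return(data.frame(polygon = integer(), cells = integer(),
                      area_ha = numeric(), centroid_easting = numeric(),
                      centroid_northing = numeric(),
                      north_easting = numeric(), north_northing = numeric()))
  idx <- which(lab$labels > 0, arr.ind = TRUE)
  lbl <- lab$labels[lab$labels > 0]
  east <- (idx[, 2] - 0.5) * cs
  north <- grid$height - (idx[, 1] - 0.5) * cs
  ce <- as.vector(tapply(east, lbl, mean))
  cn <- as.vector(tapply(north, lbl, mean))
  # north-west corner of the northernmost (lowest-row) cell of each patch
  ne <- nn <- numeric(k)
  for (p in seq_len(k)) {
    rows <- idx[lbl == p, , drop = FALSE]
    top <- rows[rows[, 1] == min(rows[, 1]), , drop = FALSE]
    c0 <- min(top[, 2])
    ne[p] <- (c0 - 1) * cs
    nn[p] <- grid$height - (min(top[, 1]) - 1) * cs
  }
  data.frame(polygon = seq_len(k), cells = lab$cells,
             area_ha = lab$cells * cs^2 / 1e4,
             centroid_easting = ce, centroid_northing = cn,
             north_easting = ne, north_northing = nn)
}

#' Annual search circle around the infestation
#'
#' Centre is the area-weighted centroid of all disturbance polygons; the
#' radius reaches the representative (maximum-northing) point of the
#' northernmost polygon of at least `min_polygon_area_ha`, plus the
#' dispersal-range extension. Only tiles whose centre falls inside the
#' circle enter the year's sample.
#'
#' @param polygons data.frame from [disturbance_polygons()].
#' @param cfg an [feature_config()].
#' @return list with `easting`, `northing`, `radius` (metres), or `NULL`
#'   (with a warning) when no polygon qualifies.
#' @export
search_radius <- function(polygons, cfg = feature_config()) {
  qual <- polygons[polygons$area_ha >= cfg$min_polygon_area_ha, ]
  if (nrow(qual) == 0) {
    warning("no disturbance polygon of at least ",
            cfg$min_polygon_area_ha, " ha; year skipped")
    return(NULL)
  }
  w <- polygons$area_ha / sum(polygons$area_ha)
  cx <- sum(w * polygons$centroid_easting)
  cy <- sum(w * polygons$centroid_northing)
  northmost <- qual[which.max(qual$north_northing), ]
  r <- sqrt((cx - northmost$north_easting)^2 +
            (cy - northmost$north_northing)^2) +
       cfg$search_radius_extension
  list(easting = cx, northing = cy, radius = r)
}

#' Keep samples whose tile centre lies inside the search circle
#'
#' @param samples data.frame with a `tile_id` column.
#' @param grid an [tile_grid()].
#' @param circle list from [search_radius()]; `NULL` keeps nothing.
#' @return filtered samples.
#' @export
filter_by_radius <- function(samples, grid, circle) {
  if (is.null(circle)) return(samples[integer(0), ])
  t <- grid$tiles[match(samples$tile_id, grid$tiles$tile_id), ]
  d2 <- (t$easting - circle$easting)^2 + (t$northing - circle$northing)^2
  samples[d2 <= circle$radius^2, ]
}
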