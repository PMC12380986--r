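#' Multiresolution segmentation parameters
#'
#' @param scale dimensionless merge threshold; pairwise merges execute while
#'   the merge cost is below `scale^2`. Default 50, appropriate for scaled
#'   surface reflectance (reflectance x 10000).
#' @param shape_weight weight of the shape term against the colour term,
#'   in \[0, 1\] (default 0.3).
#' @param compactness_weight weight of the compactness term against the
#'   smoothness term inside the shape term, in \[0, 1\] (default 0.5).
#' @param min_stand_area_ha minimum retained stand area in hectares
#'   (default 0.45); smaller stands are merged into the neighbour with the
#'   longest shared boundary or, if isolated, removed.
#' @return validated list of class `sbw_segmentation_params`.
#' @export
segmentation_params <- function(scale = 50, shape_weight = 0.3,
                                compactness_weight = 0.5,
                                min_stand_area_ha = 0.45) {
  stopifnot(scale > 0,
            shape_weight >= 0, shape_weight <= 1,
            compactness_weight >= 0, compactness_weight <= 1,
            min_stand_area_ha >= 0)
  structure(list(scale = scale, shape_weight = shape_weight,
                 compactness_weight = compactness_weight,
                 min_stand_area_ha = min_stand_area_ha),
            class = "sbw_segmentation_params")
}

#' Segment a 3-band reflectance image into stands
#'
#' Iterative pairwise region merging from single-cell seeds. The cost of
#' merging two 4-adjacent regions is
#' `f = (1 - shape_weight) * dh_color + shape_weight * dh_shape`, where the
#' colour term is the growth in size-weighted per-band standard deviation and
#' the shape term mixes a compactness (`n * p / sqrt(n)`) and a smoothness
#' (`n * p / bounding-box perimeter`) penalty. Merges execute while
#' `f < scale^2`, using local mutual-best-fitting candidate selection with a
#' fixed ascending scan order and ties broken to the lower label, so results
#' are deterministic. Region adjacency is 4-neighbour (shared cell sides) so
#' perimeters are well defined.
#'
#' Post-processing applies [enforce_min_area()] and, when `land_cover` is
#' given, [assign_modal_cover()].
#'
#' @param reflectance list of three numeric matrices (`red`, `nir`, `swir`)
#'   or an `sbw_layer_stack` with reflectance rendered.
#' @param nodata_mask logical matrix, `TRUE` = excluded from segmentation.
#' @param params an [segmentation_params()].
#' @param land_cover optional categorical raster for modal cover attributes.
#' @param cell_size cell edge length in metres.
#' @return object of class `sbw_stand_map`: list with the integer `labels`
#'   raster (0 = nodata) and an `attributes` data.frame (segment, cells,
#'   area_ha, modal_cover when available, mean reflectance per band).
#' @export
segment_stands <- function(reflectance, nodata_mask = NULL,
                           params = segmentation_params(),
                           land_cover = NULL, cell_size = 30) {
  if (inherits(reflectance, "sbw_layer_stack")) {
    stack <- reflectance
    if (is.null(stack$reflectance)) stop("stack has no rendered reflectance")
    reflectance <- stack$reflectance
    if (is.null(land_cover)) land_cover <- stack$land_cover
    cell_size <- stack$geo$cell_size
  }
  stopifnot(inherits(params, "sbw_segmentation_params"))
  b <- lapply(reflectance[1:3], as.matrix)
  if (is.null(nodata_mask)) nodata_mask <- matrix(FALSE, nrow(b[[1]]), ncol(b[[1]]))
  valid <- !nodata_mask
  if (!any(valid)) {
    labels <- matrix(0L, nrow(b[[1]]), ncol(b[[1]]))
    return(new_stand_map(labels, NULL, NULL, cell_size))
  }
  if (any(!is.finite(b[[1]][valid])) || any(!is.finite(b[[2]][valid])) ||
      any(!is.finite(b[[3]][valid])))
    stop("reflectance must be finite on unmasked cells")
  labels <- .segment_cpp(b[[1]], b[[2]], b[[3]], valid,
                         params$scale, params$shape_weight,
                         params$compactness_weight)
  if (params$min_stand_area_ha > 0)
    labels <- enforce_min_area(labels, params$min_stand_area_ha, cell_size)
  new_stand_map(labels, b, land_cover, cell_size)
}

new_stand_map <- function(labels, bands = NULL, land_cover = NULL,
                          cell_size = 30) {
  k <- max(labels)
  att <- if (k > 0) {
    cells <- tabulate(labels[labels > 0], nbins = k)
    att <- data.frame(segment = seq_len(k), cells = cells,
                      area_ha = cells * cell_size^2 / 1e4)
    if (!is.null(bands)) {
      idx <- labels > 0
      f <- factor(labels[idx], levels = seq_len(k))
      att$mean_red <- as.vector(tapply(bands[[1]][idx], f, mean))
      att$mean_nir <- as.vector(tapply(bands[[2]][idx], f, mean))
      att$mean_swir <- as.vector(tapply(bands[[3]][idx], f, mean))
    }
    att
  } else {
    data.frame(segment = integer(), cells = integer(), area_ha = numeric())
  }
  sm <- structure(list(labels = labels, attributes = att,
                       cell_size = cell_size),
                  class = "sbw_stand_map")
  if (!is.null(land_cover) && k > 0) sm <- assign_modal_cover(sm, land_cover)
  sm
}

#' @export
print.sbw_stand_map <- function(x, ...) {
  k <- nrow(x$attributes)
  cat(sprintf("sbw_stand_map: %d segments over %d x %d cells\n",
              k, nrow(x$labels), ncol(x$labels)))
  if (k > 0)
    cat(sprintf("  mean stand area %.2f ha (sd %.2f)\n",
                mean(x$attributes$area_ha), sd(x$attributes$area_ha)))
  invisible(x)
}

#' Merge or remove stands below a minimum area
#'
#' Each segment smaller than `min_stand_area_ha` is aggregated into the
#' adjacent segment sharing the longest boundary (ties to the lower label
#' id); sub-threshold segments with no neighbour are set to nodata. Applied
#' iteratively until no sub-threshold segment remains.
#'
#' @param stands an `sbw_stand_map` or an integer label raster.
#' @param min_stand_area_ha minimum stand area in hectares.
#' @param cell_size cell edge length in metres.
#' @return same type as the input, with labels renumbered 1..K.
#' @export
enforce_min_area <- function(stands, min_stand_area_ha = 0.45,
                             cell_size = 30) {
  if (inherits(stands, "sbw_stand_map")) {
    labels <- enforce_min_area(stands$labels, min_stand_area_ha,
                               stands$cell_size)
    return(new_stand_map(labels, NULL, NULL, stands$cell_size))
  }
  min_cells <- min_stand_area_ha * 1e4 / cell_size^2 - 1e-9
  .enforce_min_area_cpp(as_int_matrix(stands), min_cells)
}

#' Assign the modal land cover to each stand
#'
#' Each segment receives the most frequent land-cover class among its cells;
#' ties resolve by the priority conifer > mixedwood > hardwood > shrub >
#' water (the lowest class code).
#'
#' @param stands an `sbw_stand_map`.
#' @param land_cover co-registered categorical raster.
#' @return the stand map with a `modal_cover` column in its attribute table
#'   and a `modal_cover_raster` element.
#' @export
assign_modal_cover <- function(stands, land_cover) {
  stopifnot(inherits(stands, "sbw_stand_map"))
  stopifnot(identical(dim(stands$labels), dim(land_cover)))
  k <- max(stands$labels)
  idx <- stands$labels > 0
  if (k == 0 || !any(idx)) return(stands)
  f <- factor(stands$labels[idx], levels = seq_len(k))
  modal <- as.integer(tapply(as.integer(land_cover)[idx], f, modal_class))
  stands$attributes$modal_cover <- modal
  mc <- matrix(NA_integer_, nrow(stands$labels), ncol(stands$labels))
  mc[idx] <- modal[stands$labels[idx]]
  stands$modal_cover_raster <- mc
  stands
}
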