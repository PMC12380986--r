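#' Write a raster matrix as an ESRI ASCII grid
#'
#' Plain-text, georeferenced raster interchange (readable by common GIS
#' software). Row 1 of the matrix is the northern edge.
#'
#' @param m numeric or integer matrix.
#' @param path output file path.
#' @param geo list with `origin` (south-west corner, metres) and `cell_size`.
#' @param nodata nodata value written to the header.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(m, path, geo = list(origin = c(0, 0),
                                                 cell_size = 30),
                             nodata = -9999) {
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(m)),
               sprintf("nrows %d", nrow(m)),
               sprintf("xllcorner %g", geo$origin[1]),
               sprintf("yllcorner %g", geo$origin[2]),
               sprintf("cellsize %g", geo$cell_size),
               sprintf("NODATA_value %g", nodata)), con)
  write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [write_ascii_grid()].
#' @return numeric matrix with a `geo` attribute; nodata cells are `NA`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(hdr, "\\s+"))
  val <- setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  m[m == val["nodata_value"]] <- NA
  attr(m, "geo") <- list(origin = c(val["xllcorner"], val["yllcorner"]),
                         cell_size = val["cellsize"])
  m
}

#' Export a tile grid as GeoJSON polygons
#'
#' @param grid an [tile_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tile_geojson <- function(grid, path) {
  stopifnot(inherits(grid, "sbw_tile_grid"))
  ts <- grid$tile_size
  feats <- lapply(seq_len(nrow(grid$tiles)), function(i) {
    t <- grid$tiles[i, ]
    x0 <- (t$tcol - 1) * ts; x1 <- t$tcol * ts
    y1 <- grid$height - (t$trow - 1) * ts; y0 <- y1 - ts
    list(type = "Feature",
         properties = list(tile_id = t$tile_id, trow = t$trow,
                           tcol = t$tcol),
         geometry = list(type = "Polygon",
                         coordinates = list(list(c(x0, y0), c(x1, y0),
                                                 c(x1, y1), c(x0, y1),
                                                 c(x0, y0)))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pipeline run configuration from YAML
#'
#' Recognised top-level keys: `generator` (arguments of
#' [generator_config()]), `segmentation` (arguments of
#' [segmentation_params()] plus logical `use`), `features`
#' ([feature_config()] arguments), `rf` ([rf_params()] arguments), `outdir`
#' and `seed`.
#'
#' @param path YAML file.
#' @return a `run_config` list as accepted by [run_pipeline()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(generator = do.call(generator_config,
                                 as.list(y$generator %||% list())),
             segmentation = do.call(segmentation_params,
                                    as.list(y$segmentation$params %||%
                                            list())),
             use_segmentation = isTRUE(y$segmentation$use),
             features = do.call(feature_config,
                                as.list(y$features %||% list())),
             rf = do.call(rf_params, as.list(y$rf %||% list())),
             outdir = y$outdir %||% tempfile("sbwrun"),
             seed = y$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
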