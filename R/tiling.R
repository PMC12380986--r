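#' Build a square tessellation over a raster extent
#'
#' Imposes a regular grid of square analysis tiles (default 400 m, i.e. 16 ha)
#' over a raster of `n_rows` x `n_cols` cells. A cell belongs to the tile that
#' contains its centre, which resolves fractional overlap when the tile size
#' is not an integer multiple of the cell size (400 m vs 30 m cells). Row 1 of
#' the raster is the northern edge; all geometry is in metres in a local
#' Cartesian frame with the origin at the south-west corner.
#'
#' @param n_rows,n_cols raster dimensions in cells.
#' @param cell_size cell edge length in metres.
#' @param tile_size tile edge length in metres.
#' @return an object of class `sbw_tile_grid`: a list with the tile table
#'   (`tiles`: tile_id, trow, tcol, centre easting/northing), cell-to-tile
#'   index maps and the grid geometry.
#' @export
tile_grid <- function(n_rows, n_cols, cell_size = 30, tile_size = 400) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0, tile_size > 0)
  height <- n_rows * cell_size
  # tile index of each cell row/col (tiles indexed from the north-west corner)
  trow_of <- floor(((seq_len(n_rows) - 0.5) * cell_size) / tile_size) + 1L
  tcol_of <- floor(((seq_len(n_cols) - 0.5) * cell_size) / tile_size) + 1L
  ntr <- max(trow_of)
  ntc <- max(tcol_of)
  tiles <- expand.grid(tcol = seq_len(ntc), trow = seq_len(ntr))
  tiles <- tiles[, c("trow", "tcol")]
  tiles$tile_id <- (tiles$trow - 1L) * ntc + tiles$tcol
  tiles$easting <- (tiles$tcol - 0.5) * tile_size
  tiles$northing <- height - (tiles$trow - 0.5) * tile_size
  structure(list(tiles = tiles[, c("tile_id", "trow", "tcol",
                                   "easting", "northing")],
                 trow_of_row = trow_of, tcol_of_col = tcol_of,
                 n_tile_rows = ntr, n_tile_cols = ntc,
                 n_rows = n_rows, n_cols = n_cols,
                 cell_size = cell_size, tile_size = tile_size,
                 height = height, width = n_cols * cell_size),
            class = "sbw_tile_grid")
}

#' @export
print.sbw_tile_grid <- function(x, ...) {
  cat(sprintf("sbw_tile_grid: %d x %d tiles of %g m (%g ha) over %d x %d cells of %g m\n",
              x$n_tile_rows, x$n_tile_cols, x$tile_size, tile_area_ha(x),
              x$n_rows, x$n_cols, x$cell_size))
  invisible(x)
}

#' Tile area in hectares
#'
#' @param grid an `sbw_tile_grid`, or a numeric tile edge length in metres.
#' @return area of one tile in hectares (`tile_size^2 / 1e4`).
#' @export
#' @examples
#' tile_area_ha(400)   # 16
#' tile_area_ha(1200)  # 144 (3 x 3 block)
#' tile_area_ha(2000)  # 400 (5 x 5 block)
tile_area_ha <- function(grid) {
  size <- if (inherits(grid, "sbw_tile_grid")) grid$tile_size else grid
  stopifnot(is.numeric(size), size > 0)
  size^2 / 1e4
}

#' Cell row/column ranges of one tile (or tile block)
#'
#' @param grid an `sbw_tile_grid`.
#' @param trow,tcol tile indices; vectors describe a rectangular block.
#' @return list with integer vectors `rows` and `cols`.
#' @keywords internal
tile_cells <- function(grid, trow, tcol) {
  list(rows = which(grid$trow_of_row %in% trow),
       cols = which(grid$tcol_of_col %in% tcol))
}

#' Build per-year analysis masks
#'
#' A cell is masked (excluded from the analysis) in year `y` if it is water,
#' if it burned in or before `y`, or if it was harvested between
#' `first_year - lookback_years` and `y`. Harvest and fire rasters record the
#' event year per cell, 0 meaning never.
#'
#' @param stacks list of annual layer stacks (see [generate_landscape()]).
#' @param lookback_years harvest look-back before the first year (default 15).
#' @return named list (one per year) of logical matrices, `TRUE` = masked.
#' @export
build_mask <- function(stacks, lookback_years = 15) {
  stopifnot(length(stacks) >= 1)
  first_year <- stacks[[1]]$year
  out <- lapply(stacks, function(s) {
    m <- s$land_cover == LC_WATER
    m <- m | (s$fire_year > 0 & s$fire_year <= s$year)
    m <- m | (s$harvest_year >= first_year - lookback_years &
              s$harvest_year > 0 & s$harvest_year <= s$year)
    m
  })
  names(out) <- vapply(stacks, function(s) as.character(s$year), "")
  out
}

#' Label tiles as disturbed, undisturbed or excluded
#'
#' Applies the tile labelling rules for one year. The disturbed fraction is
#' the share of the tile's unmasked area carrying moderate or severe
#' defoliation (severity 2 or 3). A tile is `disturbed` when that fraction is
#' at least `disturbed_min` (default 0.50), `undisturbed` when below
#' `undisturbed_max` (default 0.25), and `excluded` in between. Tiles whose
#' modal land cover over unmasked cells is not conifer are `non_conifer`
#' (they never enter the model, avoiding tiles that are "undisturbed" merely
#' for lack of host); fully masked tiles are `masked`. Light defoliation
#' (severity 1) does not count toward the disturbed fraction but does count
#' as disturbance for the undisturbed minimum-mapping-unit test: a tile
#' labelled undisturbed must contain a contiguous (8-connected) extent of at
#' least `mmu_ha` of unmasked, severity-0 cells, else it is excluded.
#'
#' @param grid an [tile_grid()] object.
#' @param severity integer severity raster (0 none, 1 light, 2 moderate,
#'   3 severe).
#' @param mask logical raster, `TRUE` = masked.
#' @param land_cover categorical land-cover raster.
#' @param year calendar year recorded in the output.
#' @param disturbed_min,undisturbed_max fraction thresholds.
#' @param mmu_ha minimum mapping unit for the undisturbed dataset, in ha.
#' @param cell_size cell edge length in metres.
#' @return data.frame: `tile_id`, `year`, `status`, `disturbed_fraction`,
#'   `modal_cover`.
#' @export
label_tiles <- function(grid, severity, mask, land_cover, year,
                        disturbed_min = 0.50, undisturbed_max = 0.25,
                        mmu_ha = 1, cell_size = grid$cell_size) {
  stopifnot(inherits(grid, "sbw_tile_grid"))
  stopifnot(identical(dim(severity), dim(mask)),
            identical(dim(severity), dim(land_cover)))
  mmu_cells <- ceiling(mmu_ha * 1e4 / cell_size^2)
  tiles <- grid$tiles
  n <- nrow(tiles)
  status <- character(n)
  dfrac <- rep(NA_real_, n)
  modal <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    tc <- tile_cells(grid, tiles$trow[i], tiles$tcol[i])
    sev <- severity[tc$rows, tc$cols, drop = FALSE]
    msk <- mask[tc$rows, tc$cols, drop = FALSE]
    lc <- land_cover[tc$rows, tc$cols, drop = FALSE]
    ok <- !msk
    if (!any(ok)) { status[i] <- "masked"; next }
    modal[i] <- modal_class(lc[ok])
    dfrac[i] <- sum(sev[ok] >= 2) / sum(ok)
    if (modal[i] != LC_CONIFER) { status[i] <- "non_conifer"; next }
    if (dfrac[i] >= disturbed_min) {
      status[i] <- "disturbed"
    } else if (dfrac[i] >= undisturbed_max) {
      status[i] <- "excluded"
    } else {
      # candidate undisturbed: require a contiguous undisturbed extent of
      # at least the MMU (any severity, including light, breaks it)
      und <- matrix(0L, nrow(sev), ncol(sev))
      und[ok & sev == 0L] <- 1L
      pat <- .label_patches_cpp(und, 1L, matrix(TRUE, nrow(und), ncol(und)))
      if (length(pat$cells) > 0 && max(pat$cells) >= mmu_cells) {
        status[i] <- "undisturbed"
      } else {
        status[i] <- "excluded"
      }
    }
  }
  data.frame(tile_id = tiles$tile_id, year = year, status = status,
             disturbed_fraction = dfrac, modal_cover = modal)
}

#' Restrict tile labels to infestation onset
#'
#' The likelihood models estimate the probability of infestation *onset*:
#' each tile may contribute a disturbed sample only in the first year it is
#' labelled disturbed. In later years a previously disturbed tile is
#' excluded from both classes — as a repeat it carries no new evidence, and
#' under the no-disturbance-in-history rule it can no longer be an
#' undisturbed reference. Without this filter a tile with persistent
#' defoliation and a near-static configuration fingerprint recurs across
#' temporal-CV folds with the same label, and the forest scores it by
#' recognition rather than by configuration.
#'
#' @param labels data.frame from [label_tiles()], several years bound
#'   together.
#' @return the labels with post-onset tile-years set to `excluded`.
#' @export
filter_onset <- function(labels) {
  dist <- labels[labels$status == "disturbed", c("tile_id", "year")]
  if (nrow(dist) == 0) return(labels)
  onset <- tapply(dist$year, dist$tile_id, min)
  o <- onset[as.character(labels$tile_id)]
  post <- !is.na(o) & labels$year > o &
    labels$status %in% c("disturbed", "undisturbed")
  labels$status[post] <- "excluded"
  labels
}

# modal class of an integer vector; ties resolve to the lowest code
# (conifer > mixedwood > hardwood > shrub > water priority)
modal_class <- function(x) {
  if (length(x) == 0) return(NA_integer_)
  tab <- tabulate(x, nbins = max(x))
  as.integer(which.max(tab))
}
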