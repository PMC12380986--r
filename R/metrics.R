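#' Minimum perimeter of a raster patch of n cells
#'
#' Smallest possible perimeter, in cell sides, of any polyomino (edge-connected
#' arrangement) of `n` raster cells. Used as the normalising denominator of the
#' landscape shape index and the mean shape index, where a maximally compact
#' (square-ish) patch scores 1.
#'
#' With `m = floor(sqrt(n))` the minimum is `4m` when `n` is a perfect square,
#' `4m + 2` when `n <= m * (m + 1)`, and `4m + 4` otherwise.
#'
#' @param n integer vector of cell counts (>= 1).
#' @return integer vector of minimum perimeters in cell sides.
#' @export
#' @examples
#' min_perimeter(c(1, 3, 5, 16))
min_perimeter <- function(n) {
  if (any(n < 1)) stop("cell counts must be >= 1")
  n <- as.numeric(n)
  m <- floor(sqrt(n))
  # guard floating sqrt at perfect squares
  m <- ifelse((m + 1)^2 <= n, m + 1, m)
  m <- ifelse(m^2 > n, m - 1, m)
  out <- ifelse(m * m == n, 4 * m,
                ifelse(n <= m * (m + 1), 4 * m + 2, 4 * m + 4))
  as.integer(out)
}

#' Delineate patches of a class within a window
#'
#' Finds maximal 8-connected components of cells of `class` within a
#' categorical window. Patch perimeters count 4-neighbour cell sides exposed
#' to a different class, to nodata, or to the window boundary, so each window
#' is treated as a self-contained landscape.
#'
#' @param window integer matrix of class codes.
#' @param class class code to delineate.
#' @param valid logical matrix of the same shape; `FALSE` marks nodata cells.
#' @param cell_size cell edge length in metres (default 30).
#' @return a data.frame with one row per patch: `patch`, `cells`,
#'   `perimeter` (sides) and `area_ha`; zero rows when the class is absent.
#'   The label matrix is attached as attribute `"labels"`.
#' @export
delineate_patches <- function(window, class, valid = NULL, cell_size = 30) {
  window <- as_int_matrix(window)
  if (is.null(valid)) valid <- matrix(TRUE, nrow(window), ncol(window))
  stopifnot(identical(dim(window), dim(valid)))
  lab <- .label_patches_cpp(window, as.integer(class), valid)
  out <- data.frame(patch = seq_along(lab$cells),
                    cells = lab$cells,
                    perimeter = lab$perimeter,
                    area_ha = lab$cells * cell_size^2 / 1e4)
  attr(out, "labels") <- lab$labels
  out
}

#' Configuration metrics for one analysis window
#'
#' Computes the six configuration metrics used throughout the package for the
#' patches of one class inside a rectangular window, under an 8-neighbour
#' patch rule:
#'
#' * `PA` — mean patch area (ha), class level.
#' * `LPI` — largest patch index: percent of the window's unmasked area in the
#'   largest patch of the class.
#' * `COHESION` — patch cohesion index (percent), a perimeter/area measure of
#'   physical connectedness.
#' * `LSI` — landscape shape index: total class edge relative to the minimum
#'   edge possible for the same class area (1 = maximally compact).
#' * `AREA_CV` — coefficient of variation of patch area, in percent
#'   (population standard deviation over the mean).
#' * `SHAPE` — mean patch shape index: mean over patches of perimeter divided
#'   by the minimum perimeter for the patch's cell count.
#'
#' Window boundary and nodata cells count toward patch perimeter. When the
#' class is absent from the window all metrics are `NA` (a defined missing
#' value, never a silent zero).
#'
#' @inheritParams delineate_patches
#' @return named numeric vector `c(PA, LPI, COHESION, LSI, AREA_CV, SHAPE)`.
#' @export
#' @examples
#' w <- matrix(1L, 10, 10)
#' compute_metrics(w, class = 1)   # LPI 100, LSI = SHAPE = 1, AREA_CV 0
compute_metrics <- function(window, class = LC_CONIFER, valid = NULL,
                            cell_size = 30) {
  window <- as_int_matrix(window)
  if (is.null(valid)) valid <- matrix(TRUE, nrow(window), ncol(window))
  Z <- sum(valid)
  if (Z == 0) return(setNames(rep(NA_real_, 6), METRIC_NAMES))
  p <- delineate_patches(window, class, valid, cell_size)
  if (nrow(p) == 0) return(setNames(rep(NA_real_, 6), METRIC_NAMES))

  n <- p$cells
  per <- p$perimeter
  area <- p$area_ha

  PA <- mean(area)
  LPI <- 100 * max(n) / Z
  COHESION <- if (Z > 1) {
    100 * (1 - sum(per) / sum(per * sqrt(n))) / (1 - 1 / sqrt(Z))
  } else 0
  LSI <- sum(per) / min_perimeter(sum(n))
  SHAPE <- mean(per / min_perimeter(n))
  mu <- mean(area)
  AREA_CV <- 100 * sqrt(mean((area - mu)^2)) / mu   # population sd

  c(PA = PA, LPI = LPI, COHESION = COHESION, LSI = LSI,
    AREA_CV = AREA_CV, SHAPE = SHAPE)
}

as_int_matrix <- function(m) {
  if (!is.matrix(m)) stop("expected a matrix")
  if (!is.integer(m)) storage.mode(m) <- "integer"
  m
}
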