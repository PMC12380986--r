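#' Configuration for the synthetic landscape generator
#'
#' Bundles and validates every knob of the neutral-landscape generator. The
#' defaults describe the conditions the package's simulation studies use: a
#' 14.4 km square of 30 m cells (480 x 480), six annual time steps, conifer
#' covering ~70% of the land base, an infestation process whose tile-level
#' log-odds decrease with the largest patch index (strongly) and the mean
#' patch area (weakly), and a defoliation front that enters from the south
#' and advances northward each year.
#'
#' @param grid_height,grid_width raster dimensions in cells (>= 50).
#' @param cell_size cell edge length in metres (default 30, Landsat grain).
#' @param years strictly increasing integer years.
#' @param fragmentation dimensionless in \[0, 1\]: 0 yields one large conifer
#'   block, 1 a highly interspersed mosaic. Controls the autocorrelation
#'   length of the underlying random field.
#' @param conifer_fraction proportion of cells classed conifer, in (0, 1).
#' @param effect_beta named logistic coefficients (per standard deviation of
#'   the tile configuration metric) linking tile configuration to the odds of
#'   a tile becoming moderately/severely infested once exposed. Names must be
#'   among `PA, LPI, COHESION, LSI, AREA_CV, SHAPE`.
#' @param risk_intercept logistic intercept: per-year infestation log-odds of
#'   an exposed tile with average configuration.
#' @param front_start,front_speed fraction of the grid height (from the south
#'   edge) exposed to infestation in the first year, and the per-year advance
#'   of that front.
#' @param recovery_prob per-year probability that an infested tile recovers
#'   ("greens up"); 0 means defoliation persists.
#' @param light_rate per-year probability that a forested cell in an exposed
#'   but uninfested tile carries light (severity 1) defoliation.
#' @param noise_sd reflectance noise standard deviation, in scaled surface
#'   reflectance units (reflectance x 10000).
#' @param harvest_blocks,fire_blobs number of rectangular harvest blocks
#'   (years spanning the 18 years before the series through its end) and
#'   circular burns (years within the series) to imprint.
#' @param tile_size edge length of the infestation/analysis tile in metres.
#' @param seed integer seed; every generator operation derives its stream
#'   from it, so identical configurations reproduce byte-identical output.
#' @return validated list of class `sbw_generator_config`.
#' @export
generator_config <- function(grid_height = 480, grid_width = 480,
                             cell_size = 30, years = 2008:2013,
                             fragmentation = 0.7, conifer_fraction = 0.705,
                             effect_beta = c(LPI = -1.0, PA = -0.5),
                             risk_intercept = -1.5,
                             front_start = 0.85, front_speed = 0.03,
                             recovery_prob = 0, light_rate = 0.05,
                             noise_sd = 80, harvest_blocks = 4,
                             fire_blobs = 1, tile_size = 400, seed = 1) {
  stopifnot(grid_height >= 50, grid_width >= 50, cell_size > 0)
  years <- as.integer(years)
  if (length(years) < 1 || any(diff(years) <= 0))
    stop("years must be strictly increasing")
  stopifnot(fragmentation >= 0, fragmentation <= 1)
  if (conifer_fraction <= 0 || conifer_fraction >= 1)
    stop("conifer_fraction must be in (0, 1)")
  ncell <- grid_height * grid_width
  if (round(ncell * conifer_fraction) < 1 ||
      round(ncell * conifer_fraction) >= ncell)
    stop("grid too small to honour conifer_fraction")
  beta <- setNames(numeric(6), METRIC_NAMES)
  if (length(effect_beta)) {
    if (is.null(names(effect_beta)) ||
        !all(names(effect_beta) %in% METRIC_NAMES))
      stop("effect_beta must be named with metric names")
    beta[names(effect_beta)] <- effect_beta
  }
  structure(list(grid_height = as.integer(grid_height),
                 grid_width = as.integer(grid_width),
                 cell_size = cell_size, years = years,
                 fragmentation = fragmentation,
                 conifer_fraction = conifer_fraction,
                 effect_beta = beta, risk_intercept = risk_intercept,
                 front_start = front_start, front_speed = front_speed,
                 recovery_prob = recovery_prob, light_rate = light_rate,
                 noise_sd = noise_sd, harvest_blocks = harvest_blocks,
                 fire_blobs = fire_blobs, tile_size = tile_size,
                 seed = as.integer(seed)),
            class = "sbw_generator_config")
}

# Gaussian smoothing of a matrix by FFT with circular (toroidal) boundary;
# the torus keeps the field stationary, which is all the neutral model needs.
smooth_field <- function(z, sigma) {
  if (sigma <= 0) return(z)
  nr <- nrow(z); nc <- ncol(z)
  dr <- pmin(0:(nr - 1), nr - (0:(nr - 1)))
  dc <- pmin(0:(nc - 1), nc - (0:(nc - 1)))
  k <- outer(exp(-dr^2 / (2 * sigma^2)), exp(-dc^2 / (2 * sigma^2)))
  k <- k / sum(k)
  Re(fft(fft(z) * fft(k), inverse = TRUE)) / (nr * nc)
}

#' Generate a categorical land-cover raster
#'
#' Thresholded smoothed white noise (a neutral landscape model). The conifer
#' class is a two-component mosaic: a coarse matrix from a Gaussian random
#' field whose smoothing radius shrinks geometrically as `fragmentation`
#' grows, plus — in proportion to `fragmentation` — an independent
#' fine-grained component of scattered conifer. The split keeps the total
#' conifer share at `conifer_fraction` (exact per field, so the realised
#' proportion is within a fraction of a percentage point) while letting
#' largest-patch dominance vary between tiles of equal conifer density;
#' with a single thresholded field every size metric would be a rank-copy
#' of one local-density factor. At `fragmentation = 0` the mosaic collapses
#' to the pure coarse field (a few large blocks). Non-conifer cells are
#' partitioned by a second, rougher field into mixedwood (45%), hardwood
#' (30%), shrub/barren (15%) and water (10%).
#'
#' @param cfg an [generator_config()].
#' @return integer matrix of land-cover codes (1 conifer, 2 mixedwood,
#'   3 hardwood, 4 shrub/barren, 5 water) with a `geo` attribute.
#' @export
generate_land_cover <- function(cfg) {
  stopifnot(inherits(cfg, "sbw_generator_config"))
  set.seed(cfg$seed)
  nr <- cfg$grid_height; nc <- cfg$grid_width
  # autocorrelation length interpolates geometrically between a grid-scale
  # block (fragmentation 0) and cell-scale speckle (fragmentation 1), so the
  # middle of the range produces patch structure at the analysis grain
  sigma_max <- 0.3 * min(nr, nc)
  sigma_min <- 0.5
  sigma <- sigma_max * (sigma_min / sigma_max)^cfg$fragmentation
  # two-component conifer mosaic: a coarse matrix plus, as fragmentation
  # grows, an independent fine-grained "dust" component (scattered remnant
  # or regenerating conifer). A single thresholded field makes every size
  # metric a rank-copy of one local-density factor; the second component
  # lets largest-patch dominance vary at a fixed conifer share.
  dust_share <- 0.35 * cfg$fragmentation
  c_matrix <- cfg$conifer_fraction * (1 - dust_share)
  f1 <- smooth_field(matrix(rnorm(nr * nc), nr, nc), sigma)
  conifer <- f1 <= quantile(f1, c_matrix)
  if (dust_share > 0) {
    c_dust <- (cfg$conifer_fraction - c_matrix) / (1 - c_matrix)
    # fine speckle whose local intensity is modulated by an independent
    # coarse field: scattered conifer clusters regionally rather than
    # raining down uniformly
    f3 <- smooth_field(matrix(rnorm(nr * nc), nr, nc), 0.8)
    f4 <- smooth_field(matrix(rnorm(nr * nc), nr, nc), sigma)
    fd <- f3 / sd(f3) + f4 / sd(f4)
    conifer <- conifer | (fd <= quantile(fd, c_dust))
  }
  lc <- matrix(LC_CONIFER, nr, nc)
  non <- !conifer
  f2 <- smooth_field(matrix(rnorm(nr * nc), nr, nc), max(1.5, 0.6 * sigma))
  v <- f2[non]
  q <- quantile(v, c(0.45, 0.75, 0.90))
  cls <- ifelse(v <= q[1], LC_MIXEDWOOD,
                ifelse(v <= q[2], LC_HARDWOOD,
                       ifelse(v <= q[3], LC_SHRUB, LC_WATER)))
  lc[non] <- cls
  storage.mode(lc) <- "integer"
  attr(lc, "geo") <- list(origin = c(0, 0), cell_size = cfg$cell_size)
  lc
}

# Static harvest/fire event-year rasters (0 = never).
generate_disturbance_history <- function(cfg, land_cover) {
  nr <- cfg$grid_height; nc <- cfg$grid_width
  first <- cfg$years[1]; last <- cfg$years[length(cfg$years)]
  harvest <- matrix(0L, nr, nc)
  fire <- matrix(0L, nr, nc)
  if (cfg$harvest_blocks > 0) {
    for (i in seq_len(cfg$harvest_blocks)) {
      h <- sample(8:20, 1); w <- sample(8:20, 1)
      r0 <- sample(seq_len(nr - h), 1); c0 <- sample(seq_len(nc - w), 1)
      harvest[r0:(r0 + h - 1), c0:(c0 + w - 1)] <-
        sample((first - 18):last, 1)
    }
  }
  if (cfg$fire_blobs > 0) {
    for (i in seq_len(cfg$fire_blobs)) {
      rad <- sample(5:12, 1)
      r0 <- sample(seq_len(nr), 1); c0 <- sample(seq_len(nc), 1)
      rr <- outer((seq_len(nr) - r0)^2, (seq_len(nc) - c0)^2, "+") <= rad^2
      fire[rr] <- sample(first:last, 1)
    }
  }
  list(harvest_year = harvest, fire_year = fire)
}

#' Generate the multi-year defoliation severity process
#'
#' The infestation unit is the analysis tile: for every tile with conifer
#' present, the six configuration metrics of the conifer class are computed,
#' standardized across tiles, and combined through the logistic model
#' `log-odds = risk_intercept + effect_beta . z`. Each year a northward-
#' advancing front exposes tiles from the south; exposed, conifer-modal,
#' not-yet-infested tiles become infested with that probability, and
#' infested tiles persist (or recover with `recovery_prob`). Infested tiles
#' are rasterized by assigning moderate/severe severity (2 or 3) to their
#' forested cells; exposed but uninfested tiles receive scattered light
#' (severity 1) defoliation at `light_rate`.
#'
#' @param cfg an [generator_config()].
#' @param land_cover raster from [generate_land_cover()].
#' @return list of annual layer stacks (class `sbw_layer_stack`), each with
#'   `year`, `land_cover`, `severity`, `harvest_year`, `fire_year`, `geo` and
#'   (after [render_reflectance()]) `reflectance`. Generative ground truth is
#'   attached as attributes: `tile_truth` (per-tile metrics, log-odds and
#'   infestation probability) and `front_northing` (per-year front position,
#'   metres from the south edge).
#' @export
generate_severity_series <- function(cfg, land_cover) {
  stopifnot(inherits(cfg, "sbw_generator_config"))
  set.seed(cfg$seed + 1L)
  nr <- cfg$grid_height; nc <- cfg$grid_width
  grid <- tile_grid(nr, nc, cfg$cell_size, cfg$tile_size)
  tiles <- grid$tiles
  nt <- nrow(tiles)

  # per-tile conifer configuration metrics on the raw land cover
  met <- matrix(NA_real_, nt, 6, dimnames = list(NULL, METRIC_NAMES))
  modal <- integer(nt)
  for (i in seq_len(nt)) {
    tc <- tile_cells(grid, tiles$trow[i], tiles$tcol[i])
    w <- land_cover[tc$rows, tc$cols, drop = FALSE]
    modal[i] <- modal_class(as.vector(w))
    met[i, ] <- compute_metrics(w, class = LC_CONIFER,
                                cell_size = cfg$cell_size)
  }
  infectable <- modal == LC_CONIFER & stats::complete.cases(met)
  z <- met
  for (j in seq_len(6)) {
    v <- met[infectable, j]
    mu <- mean(v); s <- sqrt(mean((v - mu)^2))
    z[, j] <- if (s > 0) (met[, j] - mu) / s else 0
  }
  eta <- cfg$risk_intercept + as.vector(z %*% cfg$effect_beta)
  p <- plogis(eta)
  p[!infectable] <- 0

  hist <- generate_disturbance_history(cfg, land_cover)
  forested <- matrix(land_cover %in% LC_FORESTED, nr, nc)

  ny <- length(cfg$years)
  infected <- rep(FALSE, nt)
  sev_persist <- matrix(0L, nr, nc)
  front <- numeric(ny)
  infected_by_year <- matrix(FALSE, nt, ny)
  stacks <- vector("list", ny)
  for (k in seq_len(ny)) {
    coverage <- min(1, cfg$front_start + cfg$front_speed * (k - 1))
    front[k] <- coverage * grid$height
    exposed <- tiles$northing <= front[k]
    if (cfg$recovery_prob > 0 && any(infected)) {
      rec <- infected & runif(nt) < cfg$recovery_prob
      for (i in which(rec)) {
        tc <- tile_cells(grid, tiles$trow[i], tiles$tcol[i])
        sev_persist[tc$rows, tc$cols] <- 0L
      }
      infected[rec] <- FALSE
    }
    fresh <- exposed & infectable & !infected & runif(nt) < p
    for (i in which(fresh)) {
      tc <- tile_cells(grid, tiles$trow[i], tiles$tcol[i])
      blk <- sev_persist[tc$rows, tc$cols, drop = FALSE]
      for_blk <- forested[tc$rows, tc$cols, drop = FALSE]
      blk[for_blk] <- sample(c(2L, 3L), sum(for_blk), replace = TRUE,
                             prob = c(0.55, 0.45))
      sev_persist[tc$rows, tc$cols] <- blk
    }
    infected <- infected | fresh
    infected_by_year[, k] <- infected
    sev <- sev_persist
    light_tiles <- which(exposed & infectable & !infected)
    for (i in light_tiles) {
      tc <- tile_cells(grid, tiles$trow[i], tiles$tcol[i])
      blk <- sev[tc$rows, tc$cols, drop = FALSE]
      for_blk <- forested[tc$rows, tc$cols, drop = FALSE]
      hit <- for_blk & matrix(runif(length(blk)) < cfg$light_rate,
                              nrow(blk), ncol(blk))
      blk[hit & blk == 0L] <- 1L
      sev[tc$rows, tc$cols] <- blk
    }
    stacks[[k]] <- structure(list(year = cfg$years[k],
                                  reflectance = NULL,
                                  land_cover = land_cover,
                                  severity = sev,
                                  harvest_year = hist$harvest_year,
                                  fire_year = hist$fire_year,
                                  geo = list(origin = c(0, 0),
                                             cell_size = cfg$cell_size)),
                             class = "sbw_layer_stack")
  }
  attr(stacks, "tile_truth") <- data.frame(tile_id = tiles$tile_id,
                                           modal_cover = modal,
                                           eta = eta, p = p, met,
                                           check.names = FALSE)
  attr(stacks, "front_northing") <- front
  attr(stacks, "infected_by_year") <- infected_by_year
  stacks
}

# mean scaled surface reflectance (x 10000) by land cover: red, NIR, SWIR
REFL_BASE <- rbind(conifer = c(300, 2800, 1300),
                   mixedwood = c(400, 3300, 1600),
                   hardwood = c(500, 3800, 1900),
                   shrub = c(700, 2400, 2100),
                   water = c(150, 80, 40))
# per severity-class spectral shift (red up, NIR down, SWIR up), scaled by
# the host weight of the cover type (conifer 1, mixedwood 0.6, hardwood 0.3)
REFL_SEV_DELTA <- c(red = 60, nir = -140, swir = 110)
HOST_WEIGHT <- c(1, 0.6, 0.3, 0, 0)

#' Render reflectance for one annual layer stack
#'
#' Band means are conditioned on land cover and defoliation severity:
#' relative to undisturbed conifer, severely defoliated conifer is brighter
#' in red and SWIR (browning, loss of foliage water) and darker in NIR (loss
#' of standing green vegetation); the shift scales with severity class and
#' with the host content of the cover type. Water keeps a fixed, distinct
#' signature. Gaussian noise with standard deviation `noise_sd` is added.
#' Units are scaled surface reflectance (reflectance x 10000).
#'
#' @param stack an `sbw_layer_stack`.
#' @param noise_sd noise standard deviation (scaled reflectance units).
#' @param seed optional seed for the noise stream.
#' @return the stack with `reflectance` set: list of matrices
#'   `red`, `nir`, `swir`.
#' @export
render_reflectance <- function(stack, noise_sd = 80, seed = NULL) {
  stopifnot(inherits(stack, "sbw_layer_stack"))
  if (!is.null(seed)) set.seed(seed)
  lc <- stack$land_cover
  sev <- stack$severity
  nr <- nrow(lc); nc <- ncol(lc)
  host <- matrix(HOST_WEIGHT[lc], nr, nc)
  bands <- list()
  for (b in 1:3) {
    base <- matrix(REFL_BASE[lc, b], nr, nc)
    val <- base + REFL_SEV_DELTA[b] * sev * host
    if (noise_sd > 0) val <- val + rnorm(nr * nc, sd = noise_sd)
    bands[[b]] <- val
  }
  stack$reflectance <- list(red = bands[[1]], nir = bands[[2]],
                            swir = bands[[3]])
  stack
}

#' Generate a complete multi-year synthetic landscape
#'
#' Convenience wrapper running [generate_land_cover()],
#' [generate_severity_series()] and [render_reflectance()] under seeds
#' derived from `cfg$seed` (land cover: `seed`; severity: `seed + 1`;
#' disturbance history uses the severity stream; reflectance: `seed + 3`).
#' Identical configurations therefore reproduce identical landscapes.
#'
#' @param cfg an [generator_config()].
#' @return object of class `sbw_landscape`: list of annual layer stacks with
#'   the generator config and generative truth attached as attributes.
#' @export
generate_landscape <- function(cfg) {
  lc <- generate_land_cover(cfg)
  stacks <- generate_severity_series(cfg, lc)
  truth <- attributes(stacks)
  set.seed(cfg$seed + 3L)
  stacks <- lapply(stacks, render_reflectance, noise_sd = cfg$noise_sd)
  structure(stacks, tile_truth = truth$tile_truth,
            front_northing = truth$front_northing,
            infected_by_year = truth$infected_by_year,
            config = cfg, class = "sbw_landscape")
}

#' @export
print.sbw_landscape <- function(x, ...) {
  cfg <- attr(x, "config")
  sev_share <- vapply(x, function(s) mean(s$severity >= 2), 0)
  cat(sprintf("sbw_landscape: %d x %d cells (%g m), years %s\n",
              cfg$grid_height, cfg$grid_width, cfg$cell_size,
              paste(range(cfg$years), collapse = "-")))
  cat(sprintf("  conifer fraction %.2f, fragmentation %.2f, seed %d\n",
              cfg$conifer_fraction, cfg$fragmentation, cfg$seed))
  cat("  moderate/severe cell share by year:",
      paste(sprintf("%.3f", sev_share), collapse = " "), "\n")
  invisible(x)
}
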