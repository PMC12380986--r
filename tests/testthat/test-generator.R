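small_cfg <- function(...) {
  generator_config(grid_height = 100, grid_width = 100, years = 2008:2010,
                   harvest_blocks = 1, fire_blobs = 0, ...)
}

test_that("identical configurations reproduce identical landscapes", {
  a <- generate_landscape(small_cfg(seed = 5))
  b <- generate_landscape(small_cfg(seed = 5))
  expect_identical(a[[2]]$severity, b[[2]]$severity)
  expect_identical(a[[1]]$land_cover, b[[1]]$land_cover)
  expect_identical(a[[3]]$reflectance$nir, b[[3]]$reflectance$nir)
})

test_that("conifer proportion tracks the request", {
  for (f in c(0.3, 0.9)) {
    lc <- generate_land_cover(small_cfg(fragmentation = f,
                                        conifer_fraction = 0.6, seed = 2))
    expect_lt(abs(mean(lc == 1) - 0.6), 0.05)
  }
})

test_that("fragmentation 0 yields a few large blocks, 1 a speckled mosaic", {
  lc0 <- generate_land_cover(small_cfg(fragmentation = 0,
                                       conifer_fraction = 0.7, seed = 1))
  p0 <- oracle_patches(lc0, 1)
  expect_lte(nrow(p0), 3)
  expect_lt(abs(sum(p0$cells) / 1e4 - 0.7), 0.05)
  lc1 <- generate_land_cover(small_cfg(fragmentation = 1,
                                       conifer_fraction = 0.7, seed = 1))
  expect_gt(nrow(oracle_patches(lc1, 1)), nrow(p0))
})

test_that("patch count grows and mean patch area shrinks with fragmentation", {
  # asserted below the 8-connected percolation threshold: at dominant cover
  # fractions a fine-grained mosaic percolates into one giant cluster, so
  # patch counting only orders fragmentation when the class is subcritical
  counts <- areas <- numeric(5)
  for (i in seq_along(f <- c(0, 0.25, 0.5, 0.75, 1))) {
    p <- oracle_patches(generate_land_cover(small_cfg(fragmentation = f[i],
                                                      conifer_fraction = 0.35,
                                                      seed = 4)), 1)
    counts[i] <- nrow(p)
    areas[i] <- mean(p$area_ha)
  }
  expect_true(all(diff(counts) >= 0))
  expect_true(all(diff(areas) <= 0))
})

test_that("severity respects land cover and the front advances north", {
  ls <- generate_landscape(small_cfg(seed = 9))
  for (s in ls) {
    expect_true(all(s$severity %in% 0:3))
    expect_true(all(s$severity[!(s$land_cover %in% 1:3)] == 0))
  }
  front <- attr(ls, "front_northing")
  expect_lt(front[1], front[length(front)])
  expect_true(all(diff(front) >= 0))
})

test_that("null effects leave infestation independent of configuration", {
  cfg <- generator_config(grid_height = 320, grid_width = 320,
                          years = 2008:2010, effect_beta = NULL, seed = 3,
                          harvest_blocks = 0, fire_blobs = 0)
  lc <- generate_land_cover(cfg)
  stacks <- generate_severity_series(cfg, lc)
  truth <- attr(stacks, "tile_truth")
  inf <- attr(stacks, "infected_by_year")[, 3]
  ok <- complete.cases(truth) & truth$modal_cover == 1
  expect_gte(sum(ok), 500)
  rho <- cor(truth$LPI[ok], as.integer(inf[ok]), method = "spearman")
  expect_lt(abs(rho), 0.1)
})

test_that("a negative LPI effect concentrates infestation in fragmented tiles", {
  cfg <- small_cfg(seed = 6, effect_beta = c(LPI = -1))
  lc <- generate_land_cover(cfg)
  stacks <- generate_severity_series(cfg, lc)
  truth <- attr(stacks, "tile_truth")
  inf <- attr(stacks, "infected_by_year")[, 3]
  ok <- complete.cases(truth) & truth$modal_cover == 1
  expect_lt(mean(truth$LPI[ok & inf]), mean(truth$LPI[ok & !inf]))
})

test_that("defoliation brightens red/SWIR, darkens NIR; water is fixed", {
  cfg <- small_cfg(seed = 8)
  ls <- generate_severity_series(cfg, generate_land_cover(cfg))
  st <- render_reflectance(ls[[3]], noise_sd = 0)
  con <- st$land_cover == 1
  s0 <- con & st$severity == 0
  s3 <- con & st$severity == 3
  expect_gt(sum(s3), 0)
  expect_gt(mean(st$reflectance$red[s3]), mean(st$reflectance$red[s0]))
  expect_gt(mean(st$reflectance$swir[s3]), mean(st$reflectance$swir[s0]))
  expect_lt(mean(st$reflectance$nir[s3]), mean(st$reflectance$nir[s0]))
  wat <- st$land_cover == 5
  expect_true(all(st$reflectance$red[wat] == st$reflectance$red[wat][1]))
  expect_true(all(st$reflectance$nir[wat] < 100))
})

test_that("configuration validation rejects degenerate requests", {
  expect_error(generator_config(grid_height = 10), "50|>=")
  expect_error(generator_config(years = c(2010, 2009)), "increasing")
  expect_error(generator_config(conifer_fraction = 1.2), "conifer_fraction")
  expect_error(generator_config(effect_beta = c(FOO = 1)), "named")
})
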