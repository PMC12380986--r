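test_that("tile areas follow the tessellation geometry", {
  expect_equal(tile_area_ha(400), 16)
  expect_equal(tile_area_ha(1200), 144)   # 3 x 3 block
  expect_equal(tile_area_ha(2000), 400)   # 5 x 5 block
  g <- tile_grid(100, 100)
  expect_equal(tile_area_ha(g), 16)
})

test_that("cells join the tile containing their centre", {
  g <- tile_grid(27, 27, cell_size = 30, tile_size = 400)
  # cell 13 centre 375 m -> tile 1; cell 14 centre 405 m -> tile 2;
  # cell 27 centre 795 m still falls in tile 2, so only 2 tile rows carry cells
  expect_equal(g$trow_of_row[13], 1L)
  expect_equal(g$trow_of_row[14], 2L)
  expect_equal(g$n_tile_rows, 2L)
  # tiles partition all cells
  expect_true(all(g$trow_of_row >= 1 & g$trow_of_row <= g$n_tile_rows))
})

stack_with <- function(year, lc, sev = NULL, harvest = 0L, fire = 0L) {
  n <- nrow(lc)
  if (is.null(sev)) sev <- matrix(0L, n, n)
  structure(list(year = year, land_cover = lc, severity = sev,
                 harvest_year = matrix(harvest, n, n),
                 fire_year = matrix(fire, n, n),
                 geo = list(origin = c(0, 0), cell_size = 30)),
            class = "sbw_layer_stack")
}

test_that("mask rules: water always, fire from its year, harvest within lookback", {
  lc <- matrix(1L, 10, 10); lc[1, 1] <- 5L
  s08 <- stack_with(2008, lc); s10 <- stack_with(2010, lc)

  m <- build_mask(list(s08, s10))
  expect_true(m[["2008"]][1, 1])          # water
  expect_false(m[["2008"]][2, 2])

  # harvest 10 years before the series start: masked in every year
  m <- build_mask(list(stack_with(2008, lc, harvest = 1998L),
                       stack_with(2010, lc, harvest = 1998L)))
  expect_true(all(m[["2008"]][2:10, ]))
  expect_true(all(m[["2010"]][2:10, ]))

  # harvest 20 years before: outside the 15-year lookback
  m <- build_mask(list(stack_with(2008, lc, harvest = 1988L)))
  expect_false(m[["2008"]][2, 2])

  # fire in 2010: unmasked in 2008, masked from 2010 on
  m <- build_mask(list(stack_with(2008, lc, fire = 2010L),
                       stack_with(2010, lc, fire = 2010L),
                       stack_with(2011, lc, fire = 2010L)))
  expect_false(m[["2008"]][2, 2])
  expect_true(m[["2010"]][2, 2])
  expect_true(m[["2011"]][2, 2])
})

test_that("disturbed-fraction thresholds label tiles per the 25/50 rules", {
  n <- 13                                 # one tile: 13 cells x 30 m
  g <- tile_grid(n, n)
  lc <- matrix(1L, n, n)
  msk <- matrix(FALSE, n, n)
  lab_at <- function(frac, sev_class = 3L) {
    sev <- matrix(0L, n, n)
    k <- round(frac * n * n)
    if (k > 0) sev[seq_len(k)] <- sev_class
    label_tiles(g, sev, msk, lc, 2010)
  }
  expect_equal(lab_at(0.10)$status[1], "undisturbed")
  expect_equal(lab_at(0.30)$status[1], "excluded")
  expect_equal(lab_at(0.60)$status[1], "disturbed")
  expect_equal(lab_at(0.60, 2L)$status[1], "disturbed")   # moderate counts
  # light defoliation does not count toward the moderate/severe fraction
  expect_equal(lab_at(0.60, 1L)$status[1], "undisturbed")
  expect_equal(lab_at(0.30)$disturbed_fraction[1], 0.30, tolerance = 0.01)
})

test_that("modal cover, masking and the 1 ha MMU gate the undisturbed class", {
  n <- 13
  g <- tile_grid(n, n)
  msk <- matrix(FALSE, n, n)
  sev <- matrix(0L, n, n)

  lc <- matrix(3L, n, n)                  # hardwood-modal tile
  expect_equal(label_tiles(g, sev, msk, lc, 2010)$status[1], "non_conifer")

  lc <- matrix(1L, n, n)
  expect_equal(label_tiles(g, sev, matrix(TRUE, n, n), lc, 2010)$status[1],
               "masked")

  # light defoliation on a 3-cell lattice: clean cells form 2 x 2 islands
  # (0.36 ha each), so no contiguous 1 ha undisturbed extent remains
  sev_l <- matrix(0L, n, n)
  sev_l[row(sev_l) %% 3 == 0 | col(sev_l) %% 3 == 0] <- 1L
  expect_equal(label_tiles(g, sev_l, msk, lc, 2010)$status[1], "excluded")

  # labelling is idempotent
  a <- label_tiles(g, sev_l, msk, lc, 2010)
  b <- label_tiles(g, sev_l, msk, lc, 2010)
  expect_identical(a, b)
})

test_that("onset filtering removes post-onset tile-years from both classes", {
  lab <- data.frame(tile_id = c(1, 1, 1, 2, 2),
                    year = c(2008, 2009, 2010, 2008, 2009),
                    status = c("undisturbed", "disturbed", "disturbed",
                               "undisturbed", "undisturbed"),
                    disturbed_fraction = 0, modal_cover = 1L)
  out <- filter_onset(lab)
  expect_equal(out$status[out$tile_id == 1],
               c("undisturbed", "disturbed", "excluded"))
  expect_equal(out$status[out$tile_id == 2],
               c("undisturbed", "undisturbed"))
  # a tile recovering to undisturbed after onset is excluded too
  lab$status <- c("disturbed", "undisturbed", "disturbed",
                  "undisturbed", "undisturbed")
  out <- filter_onset(lab)
  expect_equal(out$status[out$tile_id == 1],
               c("disturbed", "excluded", "excluded"))
})
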