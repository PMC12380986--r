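fake_metrics <- function(tile_ids, focal = 10, ring3 = 20, ring5 = 30) {
  do.call(rbind, lapply(c("focal", "3x3", "5x5"), function(s) {
    v <- switch(s, focal = focal, "3x3" = ring3, "5x5" = ring5)
    d <- data.frame(tile_id = tile_ids, scale = s)
    for (m in c("PA", "LPI", "COHESION", "LSI", "AREA_CV", "SHAPE")) d[[m]] <- v
    d
  }))
}

fake_labels <- function(tile_ids, status, year = 2010) {
  data.frame(tile_id = tile_ids, year = year, status = status,
             disturbed_fraction = ifelse(status == "disturbed", 0.8, 0.05),
             modal_cover = 1L)
}

test_that("scale weights multiply ring metrics before scaling", {
  feats <- build_features(fake_metrics(1:4), fake_labels(1:4,
            c("disturbed", "undisturbed", "disturbed", "undisturbed")))
  expect_equal(nrow(feats), 4)
  expect_equal(feats$LPI_focal, rep(10, 4))       # weight 1
  expect_equal(feats$`LPI_3x3`, rep(8, 4))        # 20 * 0.4
  expect_equal(feats$`LPI_5x5`, rep(6, 4))        # 30 * 0.2
  expect_equal(feats$label, c(1, 0, 1, 0))
})

test_that("tiles with incomplete rings or non-sample status are dropped", {
  met <- fake_metrics(1:4)
  met[met$tile_id == 2 & met$scale == "5x5",
      c("PA", "LPI", "COHESION", "LSI", "AREA_CV", "SHAPE")] <- NA
  lab <- fake_labels(1:4, c("disturbed", "disturbed", "excluded", "masked"))
  feats <- build_features(met, lab)
  expect_equal(feats$tile_id, 1)
})

test_that("ring metrics are computed on merged windows, not tile averages", {
  # a 3-tile-wide landscape where the centre tile is solid conifer and the
  # flanks are empty: the 3x3 window's LPI reflects the merged window, not
  # the mean of member tiles
  n <- 39                                          # 3 x 3 tiles
  g <- tile_grid(n, n)
  rows2 <- which(g$trow_of_row == 2L)
  cols2 <- which(g$tcol_of_col == 2L)
  lc <- matrix(2L, n, n)
  lc[rows2, cols2] <- 1L
  tm <- tile_metrics(lc, g)
  centre <- g$tiles$tile_id[g$tiles$trow == 2 & g$tiles$tcol == 2]
  row3 <- tm[tm$tile_id == centre & tm$scale == "3x3", ]
  expect_equal(row3$LPI, 100 * length(rows2) * length(cols2) / (n * n),
               tolerance = 1e-9)
  rowf <- tm[tm$tile_id == centre & tm$scale == "focal", ]
  expect_equal(rowf$LPI, 100)
})

test_that("robust scaling centres the median at zero and drops constants", {
  x <- cbind(a = c(1, 2, 3, 4, 100), b = rep(5, 5))
  expect_warning(st <- sbwrisk:::robust_scale_stats(x, c(0.05, 0.95)),
                 "constant")
  expect_equal(st$keep, "a")
  xs <- sbwrisk:::apply_scale(x, st)
  expect_equal(unname(xs[3, "a"]), 0)              # median maps to 0
})

test_that("per-year balancing undersamples the majority class", {
  s <- data.frame(tile_id = 1:140, year = rep(c(2008, 2009), c(140 - 30, 30)),
                  label = c(rep(1, 40), rep(0, 70), rep(1, 15), rep(0, 15)))
  b <- balance_samples(s, seed = 3)
  t08 <- table(b$label[b$year == 2008])
  expect_equal(unname(t08[["1"]]), 40)
  expect_equal(unname(t08[["0"]]), 40)
  # already balanced year is unchanged
  expect_equal(sum(b$year == 2009), 30)
  # a year with no disturbed tiles contributes nothing
  s0 <- data.frame(tile_id = 1:10, year = 2010, label = 0)
  expect_equal(nrow(balance_samples(rbind(s, s0), seed = 3)),
               nrow(b))
})

test_that("search radius reaches the northernmost qualifying polygon plus 75 km", {
  polys <- data.frame(polygon = 1:2, cells = c(1200, 1100),
                      area_ha = c(10, 10),
                      centroid_easting = c(0, 0),
                      centroid_northing = c(10000, -10000),
                      north_easting = c(0, 0),
                      north_northing = c(20000, -5000))
  circ <- search_radius(polys, feature_config())
  expect_equal(circ$northing, 0)                   # area-weighted centroid
  expect_equal(circ$radius, 20000 + 75000)

  # a 4 ha polygon further north does not anchor the radius
  polys2 <- rbind(polys, data.frame(polygon = 3, cells = 444, area_ha = 4,
                                    centroid_easting = 0,
                                    centroid_northing = 30000,
                                    north_easting = 0,
                                    north_northing = 30000))
  w <- polys2$area_ha / sum(polys2$area_ha)
  circ2 <- search_radius(polys2, feature_config())
  expect_equal(circ2$radius,
               sqrt((sum(w * polys2$centroid_northing) - 20000)^2) + 75000)

  # no qualifying polygon: NULL with a warning
  expect_warning(out <- search_radius(polys2[3, , drop = FALSE],
                                      feature_config()), "skipped")
  expect_null(out)
})

test_that("radius filtering keeps tiles whose centre lies inside the circle", {
  g <- tile_grid(52, 52)                           # 4 x 4 tiles
  s <- data.frame(tile_id = g$tiles$tile_id, year = 2010, label = 0)
  circ <- list(easting = 200, northing = 200, radius = 500)
  kept <- filter_by_radius(s, g, circ)
  d2 <- (g$tiles$easting - 200)^2 + (g$tiles$northing - 200)^2
  expect_equal(sort(kept$tile_id), sort(g$tiles$tile_id[d2 <= 500^2]))
  expect_equal(nrow(filter_by_radius(s, g, NULL)), 0)
})

test_that("disturbance polygons carry area, centroid and north vertex", {
  n <- 20
  sev <- matrix(0L, n, n)
  sev[5:8, 3:6] <- 2L                              # 16 cells = 1.44 ha
  g <- tile_grid(n, n)
  p <- disturbance_polygons(sev, g)
  expect_equal(nrow(p), 1)
  expect_equal(p$area_ha, 16 * 900 / 1e4)
  expect_equal(p$centroid_easting, mean((3:6 - 0.5) * 30))
  expect_equal(p$centroid_northing, mean((n - (5:8) + 0.5) * 30))
  # north-west corner of the topmost cell (row 5, col 3)
  expect_equal(p$north_easting, (3 - 1) * 30)
  expect_equal(p$north_northing, (n - 4) * 30)
})
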