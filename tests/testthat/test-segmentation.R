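flat_image <- function(n, value = 1000) {
  m <- matrix(value, n, n)
  list(red = m, nir = m, swir = m)
}

test_that("a uniform image with unbounded scale gives one segment per connected region", {
  img <- flat_image(16)
  sm <- segment_stands(img, params = segmentation_params(scale = Inf,
                                                         min_stand_area_ha = 0))
  expect_equal(max(sm$labels), 1)
  # a nodata band splits the image into two connected regions
  mask <- matrix(FALSE, 16, 16); mask[, 8] <- TRUE
  sm <- segment_stands(img, nodata_mask = mask,
                       params = segmentation_params(scale = Inf,
                                                    min_stand_area_ha = 0))
  expect_equal(max(sm$labels), 2)
  expect_true(all(sm$labels[, 8] == 0))
})

test_that("two homogeneous halves with a large band difference stay separate", {
  m <- matrix(0, 20, 20); m[, 11:20] <- 5000
  img <- list(red = m, nir = m, swir = m)
  sm <- segment_stands(img, params = segmentation_params(scale = 50,
                                                         min_stand_area_ha = 0))
  expect_equal(max(sm$labels), 2)
  expect_equal(length(unique(as.vector(sm$labels[, 1:10]))), 1)
  expect_equal(length(unique(as.vector(sm$labels[, 11:20]))), 1)
})

test_that("segmentation is deterministic and labels partition unmasked cells", {
  img <- synthetic_reflectance(48, seed = 3)
  mask <- matrix(FALSE, 48, 48); mask[1:5, 1:5] <- TRUE
  a <- segment_stands(img, nodata_mask = mask)
  b <- segment_stands(img, nodata_mask = mask)
  expect_identical(a$labels, b$labels)
  expect_true(all(a$labels[!mask] > 0))
  expect_true(all(a$labels[mask] == 0))
})

test_that("segment count is non-increasing in scale", {
  img <- synthetic_reflectance(64, seed = 11)
  counts <- vapply(c(10, 50, 200), function(s) {
    max(segment_stands(img, params = segmentation_params(
      scale = s, min_stand_area_ha = 0))$labels)
  }, 0)
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], counts[3])
})

test_that("small segments merge into the neighbour with the longest boundary", {
  # X (3 cells, 0.27 ha) shares 4 sides with A and 1 with B
  lab <- rbind(c(1L, 1L, 3L, 2L, 2L),
               c(1L, 1L, 3L, 0L, 2L),
               c(1L, 1L, 3L, 0L, 2L),
               c(1L, 1L, 1L, 0L, 2L))
  out <- enforce_min_area(lab, 0.45, cell_size = 30)
  expect_equal(out[1, 3], out[1, 1])     # X absorbed by A
  expect_equal(out[1, 4], out[1, 5])     # B untouched (5 cells = 0.45 ha)
  expect_false(out[1, 4] == out[1, 1])

  # isolated sub-threshold segment becomes nodata
  lab <- matrix(0L, 6, 6); lab[3:4, 3:4] <- 1L   # 4 cells = 0.36 ha
  out <- enforce_min_area(lab, 0.45, 30)
  expect_true(all(out == 0))

  # 6 cells = 0.54 ha: untouched
  lab <- matrix(0L, 6, 6); lab[3:4, 2:4] <- 1L
  out <- enforce_min_area(lab, 0.45, 30)
  expect_equal(sum(out > 0), 6)
})

test_that("iterative aggregation leaves no retained stand below the threshold", {
  img <- synthetic_reflectance(64, seed = 5)
  sm <- segment_stands(img, params = segmentation_params())
  expect_gte(min(sm$attributes$area_ha), 0.45)
})

test_that("modal land cover uses counts with the conifer-first tie rule", {
  lab <- matrix(1L, 1, 10)
  lc <- matrix(c(rep(1L, 7), rep(3L, 3)), 1, 10)
  sm <- structure(list(labels = lab, attributes = data.frame(segment = 1L),
                       cell_size = 30), class = "sbw_stand_map")
  expect_equal(assign_modal_cover(sm, lc)$attributes$modal_cover, 1L)

  lc <- matrix(c(rep(1L, 5), rep(3L, 5)), 1, 10)   # 50/50 tie -> conifer
  expect_equal(assign_modal_cover(sm, lc)$attributes$modal_cover, 1L)

  lc <- matrix(5L, 1, 10); lc[1, 1] <- 2L
  sm1 <- structure(list(labels = matrix(1L, 1, 1),
                        attributes = data.frame(segment = 1L),
                        cell_size = 30), class = "sbw_stand_map")
  expect_equal(assign_modal_cover(sm1, matrix(2L, 1, 1))$attributes$modal_cover,
               2L)   # single-cell coverage of one class
})
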