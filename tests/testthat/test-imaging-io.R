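test_that("PNG and TIFF image round trips are lossless", {
  px <- array(c(0, 64, 128, 255), c(2, 2, 3))
  img <- rgb_image(px)
  f <- withr::local_tempfile(fileext = ".png")
  write_rgb_image(img, f)
  back <- read_rgb_image(f)
  expect_identical(back$pixels, img$pixels)
  expect_identical(back$bits, 8L)

  set.seed(99)
  px16 <- array(sample(0:65535, 64 * 64 * 3, replace = TRUE), c(64, 64, 3))
  img16 <- rgb_image(px16, bits = 16)
  f16 <- withr::local_tempfile(fileext = ".tif")
  write_rgb_image(img16, f16)
  back16 <- read_rgb_image(f16)
  expect_identical(back16$bits, 16L)
  expect_identical(back16$pixels, img16$pixels)
})

test_that("extra bands are dropped with a warning, missing bands error", {
  f <- withr::local_tempfile(fileext = ".png")
  arr <- array(runif(4 * 5 * 4), c(4, 5, 4))  # RGBA
  png::writePNG(arr, f)
  expect_warning(img <- read_rgb_image(f), "bands")
  expect_identical(dim(img$pixels)[3], 3L)
  expect_equal(img$pixels, round(arr[, , 1:3] * 255))

  g <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(runif(12), 3, 4), g)   # single band
  expect_error(read_rgb_image(g), "band")
})

test_that("rgb_image validates shape, range and finiteness", {
  expect_error(rgb_image(array(0, c(2, 2, 2))), "3 bands")
  expect_error(rgb_image(array(-1, c(2, 2, 3))), "range")
  expect_error(rgb_image(array(300, c(2, 2, 3))), "range")
  expect_error(rgb_image(array(NA_real_, c(2, 2, 3))), "finite")
  expect_silent(rgb_image(array(300, c(2, 2, 3)), bits = 16))
})

test_that("class map round trips are bit-identical and previews use scheme colours", {
  sch <- thingvallavatn_scheme()
  m0 <- class_map(matrix(0L, 5, 7), sch)
  f <- withr::local_tempfile(fileext = ".tif")
  write_class_map(m0, f)
  expect_true(map_equal(read_class_map(f, sch), m0))

  set.seed(4)
  m <- class_map(matrix(sample(0:6, 30 * 20, replace = TRUE), 30, 20), sch)
  for (ext in c(".tif", ".png")) {
    g <- withr::local_tempfile(fileext = ext)
    write_class_map(m, g)
    expect_true(map_equal(read_class_map(g, sch), m))
  }

  prev <- withr::local_tempfile(fileext = ".png")
  write_class_map(m, f, preview_path = prev)
  rgb <- png::readPNG(prev)
  cols <- unique(matrix(rgb, ncol = 3))
  expected <- t(grDevices::col2rgb(c("black", sch$colour)) / 255)
  expect_equal(nrow(cols), 7)  # 6 classes + background
  expect_true(all(apply(expected, 1, function(e)
    any(colSums(abs(t(cols) - e)) < 1e-6))))
})

test_that("ROI CSV and GeoJSON round trips are identity", {
  sch <- test_scheme(3)
  df <- data.frame(class_id = c(1, 1, 2, 3), row = c(1, 5, 9, 10),
                   col = c(1, 3, 2, 10))
  rois <- roi_set(df, sch, "training", c(10, 10))
  for (ext in c(".csv", ".geojson")) {
    f <- withr::local_tempfile(fileext = ext)
    write_roi_set(rois, f)
    back <- read_roi_set(f, sch, "training", c(10, 10))
    a <- rois$pixels[order(rois$pixels$class_id, rois$pixels$row, rois$pixels$col), ]
    b <- back$pixels[order(back$pixels$class_id, back$pixels$row, back$pixels$col), ]
    expect_equal(unname(as.matrix(a)), unname(as.matrix(b)))
  }
})

test_that("ROI validation catches out-of-bounds, duplicates, unknown classes", {
  sch <- test_scheme(2)
  ok <- data.frame(class_id = 1, row = 3, col = 3)
  expect_silent(roi_set(ok, sch, "training", c(4, 4)))
  expect_error(roi_set(data.frame(class_id = 1, row = 5, col = 1), sch,
                       "training", c(4, 4)), "bounds")
  expect_error(roi_set(data.frame(class_id = c(1, 1), row = c(2, 2),
                                  col = c(2, 2)), sch, "training", c(4, 4)),
               "duplicate")
  expect_error(roi_set(data.frame(class_id = 7, row = 1, col = 1), sch,
                       "training", c(4, 4)), "unknown class")
  # empty set is valid
  empty <- roi_set(data.frame(class_id = integer(), row = integer(),
                              col = integer()), sch, "training", c(4, 4))
  expect_identical(sum(roi_pixel_counts(empty)), 0L)
})

test_that("GeoJSON polygons rasterize by pixel-centre containment", {
  sch <- test_scheme(2)
  # 15 axis-aligned rectangles per class, ~65 pixels each, on disjoint grid
  # cells: per-class pixel counts must equal the summed rectangle areas
  set.seed(11)
  dim <- c(400, 400)
  cells <- expand.grid(gr = 0:5, gc = 0:4)          # 30 disjoint 60 x 60 cells
  feats <- list()
  areas <- c(class1 = 0L, class2 = 0L)
  for (i in seq_len(30)) {
    k <- if (i <= 15) 1L else 2L
    hgt <- sample(5:8, 1); wid <- sample(8:12, 1)   # ~40-96 px, mean ~65
    r0 <- 5 + 60 * cells$gr[i]; c0 <- 5 + 60 * cells$gc[i]
    ring <- list(list(c0 - 0.5, r0 - 0.5), list(c0 + wid - 0.5, r0 - 0.5),
                 list(c0 + wid - 0.5, r0 + hgt - 0.5),
                 list(c0 - 0.5, r0 + hgt - 0.5), list(c0 - 0.5, r0 - 0.5))
    feats[[length(feats) + 1]] <- list(
      type = "Feature", properties = list(class = paste0("class", k)),
      geometry = list(type = "Polygon", coordinates = list(ring)))
    areas[k] <- areas[k] + hgt * wid
  }
  f <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(list(type = "FeatureCollection", features = feats), f,
                       auto_unbox = TRUE, digits = NA)
  rois <- read_roi_set(f, sch, "training", dim)
  expect_identical(unname(roi_pixel_counts(rois)), unname(areas))
})
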