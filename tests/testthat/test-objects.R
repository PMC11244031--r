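test_that("object aggregation takes exact per-object means", {
  seg <- matrix(c(1, 1, 2,
                  1, 2, 2), 2, 3, byrow = TRUE)
  layer <- matrix(c(1, 2, 3,
                    4, 5, 6), 2, 3, byrow = TRUE)
  maps <- array(layer, c(2, 3, 1))
  dimnames(maps) <- list(NULL, NULL, "f")
  tab <- aggregate_by_object(maps, seg)
  expect_equal(tab$sample_id, c(1, 2))
  expect_equal(tab$f, c(mean(c(1, 2, 4)), mean(c(3, 5, 6))))
})

test_that("majority labelling breaks ties toward the lowest class ID", {
  seg <- matrix(1, 2, 2)
  truth <- matrix(c(3, 3, 1, 1), 2, 2)  # classes 1 and 3 tied 2-2
  maps <- array(0, c(2, 2, 1))
  tab <- aggregate_by_object(maps, seg, truth)
  expect_equal(tab$label, 1L)
})

test_that("background pixels and empty objects are excluded", {
  seg <- matrix(c(0, 1, 1, 0), 2, 2)
  maps <- array(c(9, 1, 3, 9), c(2, 2, 1))
  tab <- aggregate_by_object(maps, seg)
  expect_equal(nrow(tab), 1)
  expect_equal(tab[[2]], 2)  # mean of 1 and 3; the 9s are background
  # an object whose every pixel is NA is dropped with a warning
  maps[c(2, 3)] <- NA
  expect_warning(out <- aggregate_by_object(maps, seg), "no valid pixels")
  expect_equal(nrow(out), 0)
})

test_that("an axis-aligned rectangle yields its exact geometry", {
  seg <- matrix(0L, 10, 12)
  seg[3:6, 2:9] <- 1L  # 4 rows x 8 cols
  gf <- geometric_features(seg)
  expect_equal(names(gf), c("sample_id", "area", "length", "compactness",
                            "convexity", "solidity", "roundness",
                            "form_factor", "elongation", "rectangularity",
                            "main_direction", "major_axis", "minor_axis",
                            "n_holes", "solid_area"))
  expect_equal(gf$area, 32)
  expect_equal(gf$length, 24)           # perimeter of a 4 x 8 rectangle
  expect_equal(gf$elongation, 2)        # 8 / 4 exactly (unit-square model)
  expect_equal(gf$rectangularity, 1, tolerance = 1e-10)
  expect_equal(gf$solidity, 1, tolerance = 1e-10)
  expect_equal(gf$convexity, 1, tolerance = 1e-10)
  expect_equal(gf$main_direction, 0)    # long axis along columns
  expect_equal(gf$major_axis, 8 * 4 / sqrt(12), tolerance = 1e-10)
  expect_equal(gf$form_factor, 4 * pi * 32 / 24^2, tolerance = 1e-12)
  expect_equal(gf$n_holes, 0)
  expect_equal(gf$solid_area, 32)
})

test_that("pixel size scales lengths and areas consistently", {
  seg <- matrix(0L, 8, 8); seg[2:5, 2:7] <- 1L
  g1 <- geometric_features(seg, pixel_size = 1)
  g2 <- geometric_features(seg, pixel_size = 0.4)
  expect_equal(g2$area, g1$area * 0.16)
  expect_equal(g2$length, g1$length * 0.4)
  expect_equal(g2$elongation, g1$elongation)      # dimensionless
  expect_equal(g2$form_factor, g1$form_factor)
  expect_equal(g2$rectangularity, g1$rectangularity)
})

test_that("holes are counted and filled into the solid area", {
  seg <- matrix(0L, 9, 9)
  seg[2:6, 2:6] <- 1L
  seg[4, 4] <- 0L  # one interior hole
  gf <- geometric_features(seg)
  expect_equal(gf$n_holes, 1)
  expect_equal(gf$area, 24)
  expect_equal(gf$solid_area, 25)
  # total boundary includes the hole boundary; outer perimeter does not
  expect_equal(gf$length, 20 + 4)
})

test_that("a tilted bar reports its main direction", {
  seg <- matrix(0L, 12, 12)
  for (i in 1:8) seg[i + 2, i + 2] <- 1L  # 45-degree diagonal
  gf <- geometric_features(seg)
  expect_equal(gf$main_direction, 45, tolerance = 1)
  expect_gt(gf$elongation, 3)
})

test_that("the stand-in segmentation recovers piecewise-constant blocks", {
  arr <- array(0.1, c(12, 12, 4))
  arr[, 7:12, ] <- 0.8
  cube <- hyper_cube(arr + 1e-4 * array(seq_len(12 * 12 * 4), c(12, 12, 4)),
                     c(500, 600, 700, 800))
  seg <- segment_stand_in(cube, merge_threshold = 0.3)
  expect_equal(max(seg), 2)
  expect_true(all(seg[, 1:6] == seg[1, 1]))
  expect_true(all(seg[, 7:12] == seg[1, 7]))
  # threshold 0 leaves every pixel its own object
  seg0 <- segment_stand_in(cube, merge_threshold = 0)
  expect_equal(max(seg0), 144)
})

test_that("feature tables survive a CSV round trip", {
  tab <- small_table()
  path <- tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(names(back), names(tab))
  expect_equal(back$label, tab$label)
  expect_equal(as.matrix(back[, -1]), as.matrix(tab[, -1]),
               tolerance = 1e-12)
})
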