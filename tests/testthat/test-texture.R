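test_that("principal components are orthonormal with reproducible signs", {
  sc <- small_scene()
  pcs <- pca_components(sc$cube, k = 3)
  expect_equal(crossprod(pcs$loadings), diag(3), tolerance = 1e-10)
  expect_true(all(pcs$explained >= 0) && sum(pcs$explained) <= 1 + 1e-12)
  expect_true(pcs$explained[1] >= pcs$explained[2])
  for (j in 1:3) {
    i <- which.max(abs(pcs$loadings[, j]))
    expect_gt(pcs$loadings[i, j], 0)
  }
  # rerunning gives bit-identical scores (deterministic eigen + sign rule)
  expect_identical(pcs$images, pca_components(sc$cube, k = 3)$images)
})

test_that("GLCM statistics on a constant image are degenerate as expected", {
  img <- matrix(5, 8, 8)
  st <- glcm_statistics(img, glcm_spec(window = 3, levels = 4))
  expect_equal(unname(st[4, 4, "contrast"]), 0)
  expect_equal(unname(st[4, 4, "entropy"]), 0)
  expect_equal(unname(st[4, 4, "second_moment"]), 1)
  expect_equal(unname(st[4, 4, "homogeneity"]), 1)
  expect_equal(unname(st[4, 4, "correlation"]), 0)  # zero-variance convention
})

test_that("GLCM statistics match the brute-force oracle on a random image", {
  set.seed(9)
  img <- matrix(runif(12 * 10), 12, 10)
  spec <- glcm_spec(window = 5, levels = 8)
  got <- glcm_statistics(img, spec)
  want <- glcm_bruteforce(img, 5, 8, spec$offsets)
  expect_equal(unname(got), want, tolerance = 1e-12)
})

test_that("missing pixels are excluded from co-occurrence counting", {
  set.seed(10)
  img <- matrix(runif(64), 8, 8)
  img[3, 3] <- NA
  spec <- glcm_spec(window = 3, levels = 4)
  got <- glcm_statistics(img, spec)
  want <- glcm_bruteforce(img, 3, 4, spec$offsets)
  expect_equal(unname(got), want, tolerance = 1e-12)
})

test_that("a window larger than the image is rejected", {
  expect_error(glcm_statistics(matrix(1, 5, 5), glcm_spec(window = 5)),
               "window exceeds image extent")
  expect_error(glcm_spec(window = 4), "odd")
  expect_error(glcm_spec(window = 3, levels = 1), "levels")
})

test_that("the texture stack carries 24 named layers", {
  sc <- small_scene()
  st <- texture_stack(sc$cube, small_glcm())
  expect_equal(dim(st)[3], 24)
  expect_equal(dimnames(st)[[3]][1:3], c("PC1_mean", "PC1_variance",
                                         "PC1_homogeneity"))
  expect_equal(sum(grepl("^PC2_", dimnames(st)[[3]])), 8)
  expect_false(anyNA(st))
})

test_that("J-M distance is zero for identical classes, symmetric, bounded", {
  set.seed(11)
  a <- matrix(rnorm(200), 100, 2)
  b <- matrix(rnorm(200, mean = 1), 100, 2)
  expect_equal(jm_distance(a, a), 0, tolerance = 1e-10)
  expect_equal(jm_distance(a, b), jm_distance(b, a), tolerance = 1e-12)
  jm <- jm_distance(a, b)
  expect_true(jm > 0 && jm <= 2)
  far <- matrix(rnorm(200, mean = 100), 100, 2)
  expect_equal(jm_distance(a, far), 2, tolerance = 1e-6)
})

test_that("J-M rejects mismatched dimensionality and tiny samples", {
  expect_error(jm_distance(matrix(1:4, 2), matrix(1:9, 3)), "dimensionality")
  expect_error(jm_distance(matrix(1, 1, 2), matrix(1, 5, 2)), "2 samples")
})

test_that("the window sweep records every candidate and picks one of them", {
  sc <- small_scene()
  windows <- c(3, 5, 7, 9, 11)
  res <- select_window(sc$cube, sc$class_truth, windows = windows,
                       spec = glcm_spec(levels = 16), max_per_class = 150)
  expect_true(res$window %in% windows)
  expect_equal(sort(unique(res$separability$window)), windows)
  # 4 classes -> 6 pairs per window
  expect_equal(nrow(res$separability), length(windows) * 6)
  expect_true(all(res$separability$jm >= 0 & res$separability$jm <= 2))
  expect_error(select_window(sc$cube, sc$class_truth, windows = c(4, 6)),
               "odd")
})
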