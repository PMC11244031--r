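test_that("scene generation is deterministic in the seed", {
  cfg <- scene_config(rows = 30, cols = 30,
                      wavelengths = seq(450, 950, length.out = 12),
                      patch_scale = 8, seed = 5)
  a <- make_scene(cfg)
  b <- make_scene(cfg)
  expect_identical(a$cube$data, b$cube$data)
  expect_identical(a$class_truth, b$class_truth)
  cfg2 <- cfg; cfg2$seed <- 6L
  expect_false(identical(make_scene(cfg2)$cube$data, a$cube$data))
})

test_that("scenes honour the configured geometry and class structure", {
  sc <- small_scene()
  cfg <- sc$config
  expect_equal(dim(sc$cube), c(cfg$rows, cfg$cols,
                               length(cfg$wavelengths)))
  expect_setequal(unique(as.vector(sc$class_truth)), 1:4)
  # every class owns at least two objects
  oc <- table(hyperobia:::object_classes(sc$object_truth, sc$class_truth))
  expect_true(all(oc >= 2))
  # objects are class-pure: class is constant within each object
  for (id in unique(as.vector(sc$object_truth)))
    expect_length(unique(sc$class_truth[sc$object_truth == id]), 1)
  # reflectance stays physical: positive, bounded
  expect_true(all(sc$cube$data > 0 & sc$cube$data <= 1.5))
})

test_that("default spectra are vegetation-like and group pairwise", {
  wl <- seq(430.4, 991.3, length.out = 200)
  sp <- default_spectra(wl)
  expect_equal(dim(sp), c(4, 200))
  expect_true(all(sp >= 0 & sp <= 1))
  nir <- wl > 800; red <- wl > 660 & wl < 690
  for (i in 1:4)  # red edge: NIR plateau well above red absorption
    expect_gt(mean(sp[i, nir]), 3 * mean(sp[i, red]))
  # classes 1-2 and 3-4 are spectrally closer within than across groups
  d <- as.matrix(dist(sp))
  expect_lt(d[1, 2], min(d[1, 3], d[1, 4]))
  expect_lt(d[3, 4], min(d[1, 3], d[2, 3]))
})

test_that("the object split is stratified, disjoint and exhaustive", {
  sc <- small_scene()
  split <- split_objects(sc, seed = 3)
  ids <- sort(unique(as.vector(sc$object_truth)))
  expect_setequal(c(split$train, split$test), ids)
  expect_length(intersect(split$train, split$test), 0)
  oc <- hyperobia:::object_classes(sc$object_truth, sc$class_truth)
  for (cl in 1:4) {
    n_cl <- sum(oc == cl)
    n_tr <- sum(oc[as.character(split$train)] == cl)
    expect_equal(n_tr, max(1, min(floor(0.30 * n_cl + 0.5), n_cl - 1)),
                 label = sprintf("class %d", cl))
  }
  # same seed reproduces the split; another seed changes it
  expect_identical(split, split_objects(sc, seed = 3))
  expect_false(identical(split, split_objects(sc, seed = 4)))
})

test_that("scene configuration rejects inconsistent inputs", {
  expect_error(scene_config(noise_sd = -1), "noise_sd")
  expect_error(scene_config(train_fraction = 1.2), "train_fraction")
  expect_error(scene_config(n_classes = 3), "spectra")
  expect_error(scene_config(texture_len = c(1, 2)), "per class")
  expect_error(make_scene(scene_config(rows = 10, cols = 10,
                                       patch_scale = 20)),
               "patch_scale")
})
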