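# two well-separated Gaussian blobs in 2-D, as a sanity dataset
blobs <- function(n_per = 40, gap = 4, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n_per), ncol = 2),
             matrix(rnorm(2 * n_per, mean = gap), ncol = 2))
  data.frame(`F:a` = x[, 1], `F:b` = x[, 2],
             label = rep(1:2, each = n_per), check.names = FALSE)
}

test_that("confusion-matrix metrics match hand-computed values", {
  rep <- eval_report(matrix(c(50, 10, 10, 30), 2, byrow = TRUE))
  expect_equal(rep$oa, 0.80, tolerance = 1e-12)
  expect_equal(rep$aa, mean(c(50 / 60, 30 / 40)), tolerance = 1e-12)
  expect_equal(rep$kappa, (0.80 - 0.52) / (1 - 0.52), tolerance = 1e-12)
  expect_equal(rep$per_class, c(50 / 60, 30 / 40))
})

test_that("a perfect diagonal confusion gives all-ones metrics", {
  rep <- eval_report(diag(c(7, 3, 12)))
  expect_equal(rep$oa, 1)
  expect_equal(rep$aa, 1)
  expect_equal(rep$kappa, 1)
})

test_that("degenerate confusion matrices are handled", {
  expect_error(eval_report(matrix(1, 2, 3)), "square")
  expect_error(eval_report(matrix(c(1, -1, 0, 2), 2)), "non-negative")
  # a class absent from the test set yields NA recall, excluded from AA
  rep <- eval_report(matrix(c(5, 0, 0, 0), 2, byrow = TRUE))
  expect_true(is.na(rep$per_class[2]))
  expect_equal(rep$aa, 1)
})

test_that("every classifier separates well-separated blobs", {
  tab <- blobs()
  test <- blobs(seed = 2)
  for (kind in c("knn", "svm", "rf", "ann")) {
    model <- train_classifier(tab, classifier_spec(kind))
    rep <- evaluate(model, test)
    expect_gt(rep$oa, 0.95)
  }
})

test_that("KNN vote ties resolve to the nearest neighbour's class", {
  train <- data.frame(`F:x` = c(0, 2), label = c(1L, 2L),
                      check.names = FALSE)
  model <- train_classifier(train, classifier_spec("knn", k = 2))
  # both neighbours vote once; the closer training point decides
  expect_equal(predict(model, data.frame(`F:x` = 0.9, check.names = FALSE)), 1L)
  expect_equal(predict(model, data.frame(`F:x` = 1.1, check.names = FALSE)), 2L)
})

test_that("stochastic learners are reproducible through their seed", {
  tab <- blobs(gap = 1.5)
  for (kind in c("rf", "ann")) {
    m1 <- train_classifier(tab, classifier_spec(kind, seed = 7))
    m2 <- train_classifier(tab, classifier_spec(kind, seed = 7))
    expect_identical(predict(m1, tab), predict(m2, tab), label = kind)
  }
})

test_that("prediction refuses tables missing trained features", {
  tab <- blobs()
  model <- train_classifier(tab, classifier_spec("knn"))
  expect_error(predict(model, tab[, "F:a", drop = FALSE]),
               "feature columns missing")
})

test_that("standardization is fitted on the training split only", {
  tab <- blobs()
  model <- train_classifier(tab, classifier_spec("knn"))
  expect_equal(unname(model$scaler$center),
               unname(colMeans(as.matrix(tab[, 1:2]))))
  # shifting the test set does not silently re-standardize it
  shifted <- tab; shifted[, 1:2] <- shifted[, 1:2] + 100
  expect_lt(evaluate(model, shifted)$oa, 1)
})

test_that("cross-validation is stratified, seeded and guarded", {
  tab <- blobs(n_per = 25, gap = 1.5)
  cv1 <- cross_validate(tab, classifier_spec("knn", k = 5), folds = 5,
                        seed = 2)
  cv2 <- cross_validate(tab, classifier_spec("knn", k = 5), folds = 5,
                        seed = 2)
  expect_identical(cv1$oa, cv2$oa)
  expect_length(cv1$folds, 5)
  # stratification: every fold holds both classes
  for (f in 1:5)
    expect_setequal(unique(tab$label[cv1$fold_of == f]), 1:2)
  expect_error(cross_validate(tab, classifier_spec("knn"), folds = 26),
               "fewer samples than folds")
})
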