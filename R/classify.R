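#' Specify a classifier
#'
#' The four classifiers of the pipeline with their pinned hyperparameters:
#' KNN with k = 17, RBF-kernel SVM with C = 200, random forest with 500
#' trees, and a single-hidden-layer neural network with 64 sigmoid units
#' trained by full-batch Adam with cross-entropy for 100 iterations. KNN,
#' SVM and the network operate on z-score standardized features (fitted on
#' the training split only); the forest uses raw features.
#'
#' @param classifier `"knn"`, `"svm"`, `"rf"` or `"ann"`.
#' @param ... hyperparameter overrides: `k` (knn), `cost` (svm), `trees`
#'   (rf), `hidden`, `epochs`, `learning_rate` (ann).
#' @param seed integer seed for the stochastic learners (rf, ann).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(classifier = c("knn", "svm", "rf", "ann"), ...,
                            seed = 1) {
  kind <- match.arg(classifier)
  dots <- list(...)
  hp <- switch(kind,
    knn = list(k = dots$k %||% 17),
    svm = list(cost = dots$cost %||% 200),
    rf  = list(trees = dots$trees %||% 500),
    ann = list(hidden = dots$hidden %||% 64, epochs = dots$epochs %||% 100,
               learning_rate = dots$learning_rate %||% 0.05))
  stop_if_not(all(unlist(hp) > 0), "hyperparameters must be positive")
  structure(c(list(kind = kind, seed = as.integer(seed)), hp),
            class = "classifier_spec")
}

#' Train a classifier on a feature table
#'
#' @param train feature table: data.frame with feature columns and a `label`
#'   column of class IDs.
#' @param spec a [classifier_spec()].
#' @return An object of class `hyperobia_model` with a [predict][stats::predict]
#'   method.
#' @export
train_classifier <- function(train, spec) {
  stop_if_not(inherits(spec, "classifier_spec"),
              "`spec` must be a classifier_spec")
  stop_if_not("label" %in% names(train), "training table needs a `label`")
  feats <- feature_columns(train)
  x <- as.matrix(train[, feats, drop = FALSE])
  y <- train$label
  levels_ <- sort(unique(y))
  if (length(levels_) < 2) stop("single-class training set", call. = FALSE)
  scaled <- spec$kind %in% c("knn", "svm", "ann")
  scaler <- NULL
  if (scaled) {
    ctr <- colMeans(x)
    scl <- sqrt(colSums(sweep(x, 2, ctr)^2) / max(1, nrow(x) - 1))
    scl[scl == 0 | !is.finite(scl)] <- 1
    scaler <- list(center = ctr, scale = scl)
    x <- scale(x, ctr, scl)
  }
  fit <- switch(spec$kind,
    knn = list(x = x, y = y),
    svm = e1071::svm(x, factor(y, levels = levels_), kernel = "radial",
                     cost = spec$cost, scale = FALSE),
    rf  = with_seed(spec$seed,
            randomForest::randomForest(x, factor(y, levels = levels_),
                                       ntree = spec$trees)),
    ann = mlp_train(x, match(y, levels_), n_class = length(levels_),
                    hidden = spec$hidden, epochs = spec$epochs,
                    lr = spec$learning_rate, seed = spec$seed))
  structure(list(spec = spec, fit = fit, scaler = scaler,
                 schema = feats, levels = levels_),
            class = "hyperobia_model")
}

#' @export
print.hyperobia_model <- function(x, ...) {
  cat(sprintf("<hyperobia_model> %s, %d features, %d classes\n",
              x$spec$kind, length(x$schema), length(x$levels)))
  invisible(x)
}

#' Predict class labels
#'
#' @param object a [train_classifier()] model.
#' @param newdata feature table or matrix with the training feature columns.
#' @param ... unused.
#' @return Integer vector of predicted class IDs.
#' @export
predict.hyperobia_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    miss <- setdiff(object$schema, names(newdata))
    if (length(miss) > 0)
      stop(sprintf("feature columns missing from newdata: %s",
                   paste(head(miss, 5), collapse = ", ")), call. = FALSE)
    newdata <- as.matrix(newdata[, object$schema, drop = FALSE])
  } else {
    stop_if_not(ncol(newdata) == length(object$schema),
                "newdata column count does not match training schema")
  }
  x <- if (!is.null(object$scaler))
    scale(newdata, object$scaler$center, object$scaler$scale) else newdata
  switch(object$spec$kind,
    knn = knn_predict(object$fit$x, object$fit$y, x, object$spec$k),
    svm = object$levels[as.integer(predict(object$fit, x))],
    rf  = object$levels[as.integer(predict(object$fit, x))],
    ann = object$levels[mlp_predict(object$fit, x)])
}

# KNN with deterministic tie-break: among the tied majority classes, pick
# the class of the nearest neighbour belonging to one of them
knn_predict <- function(train_x, train_y, test_x, k) {
  k <- min(k, nrow(train_x))
  d2 <- outer(rowSums(test_x^2), rep(1, nrow(train_x))) +
    outer(rep(1, nrow(test_x)), rowSums(train_x^2)) -
    2 * tcrossprod(test_x, train_x)
  lev <- sort(unique(train_y))
  yi <- match(train_y, lev)
  pred <- integer(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    nn_y <- yi[order(d2[i, ])[seq_len(k)]]
    cnt <- tabulate(nn_y, length(lev))
    top <- which(cnt == max(cnt))
    pred[i] <- if (length(top) == 1L) top
      # tie: nearest neighbour among the tied classes decides
      else nn_y[match(TRUE, nn_y %in% top)]
  }
  lev[pred]
}

# ---- single-hidden-layer MLP, full-batch Adam, cross-entropy --------------

mlp_train <- function(x, y_idx, n_class, hidden, epochs, lr, seed) {
  n <- nrow(x); d <- ncol(x)
  yk <- matrix(0, n, n_class); yk[cbind(seq_len(n), y_idx)] <- 1
  with_seed(seed, {
    w1 <- matrix(stats::rnorm(d * hidden, sd = 1 / sqrt(d)), d, hidden)
    b1 <- numeric(hidden)
    w2 <- matrix(stats::rnorm(hidden * n_class, sd = 1 / sqrt(hidden)),
                 hidden, n_class)
    b2 <- numeric(n_class)
    params <- list(w1 = w1, b1 = b1, w2 = w2, b2 = b2)
    m <- lapply(params, function(p) p * 0)
    v <- lapply(params, function(p) p * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    sigmoid <- function(z) 1 / (1 + exp(-z))
    for (t in seq_len(epochs)) {
      h <- sigmoid(sweep(x %*% params$w1, 2, params$b1, `+`))
      logits <- sweep(h %*% params$w2, 2, params$b2, `+`)
      logits <- logits - apply(logits, 1, max)
      p <- exp(logits); p <- p / rowSums(p)
      dlogits <- (p - yk) / n
      grads <- list(
        w1 = crossprod(x, (dlogits %*% t(params$w2)) * h * (1 - h)),
        b1 = colSums((dlogits %*% t(params$w2)) * h * (1 - h)),
        w2 = crossprod(h, dlogits),
        b2 = colSums(dlogits))
      for (nm in names(params)) {
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * grads[[nm]]
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * grads[[nm]]^2
        mh <- m[[nm]] / (1 - beta1^t)
        vh <- v[[nm]] / (1 - beta2^t)
        params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
      }
    }
    params
  })
}

mlp_predict <- function(params, x) {
  sigmoid <- function(z) 1 / (1 + exp(-z))
  h <- sigmoid(sweep(x %*% params$w1, 2, params$b1, `+`))
  logits <- sweep(h %*% params$w2, 2, params$b2, `+`)
  max.col(logits, ties.method = "first")
}

# ---- confusion-matrix metrics ----------------------------------------------

#' Build an evaluation report from a confusion matrix
#'
#' Metrics: overall accuracy OA = trace/total; average accuracy AA = mean of
#' per-class recalls; Cohen's kappa = (OA - pe) / (1 - pe) with chance
#' agreement pe = sum_c(row_c * col_c) / total^2.
#'
#' @param confusion square count matrix, rows = truth, columns = predicted.
#' @return An object of class `eval_report`: list with `confusion`,
#'   `per_class` (recalls), `oa`, `aa`, `kappa`.
#' @examples
#' eval_report(matrix(c(50, 10, 10, 30), 2, byrow = TRUE))
#' @export
eval_report <- function(confusion) {
  confusion <- as.matrix(confusion)
  stop_if_not(nrow(confusion) == ncol(confusion),
              "confusion matrix must be square")
  stop_if_not(all(confusion >= 0), "confusion entries must be non-negative")
  total <- sum(confusion)
  oa <- sum(diag(confusion)) / total
  rows <- rowSums(confusion)
  per_class <- ifelse(rows > 0, diag(confusion) / rows, NA_real_)
  aa <- mean(per_class, na.rm = TRUE)
  pe <- sum(rows * colSums(confusion)) / total^2
  kappa <- if (pe < 1) (oa - pe) / (1 - pe) else 1
  structure(list(confusion = confusion, per_class = per_class, oa = oa,
                 aa = aa, kappa = kappa),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> OA %.4f, AA %.4f, kappa %.4f (n = %d)\n",
              x$oa, x$aa, x$kappa, sum(x$confusion)))
  invisible(x)
}

#' Evaluate a trained classifier on a test table
#'
#' @param model a [train_classifier()] model.
#' @param test feature table with the training feature columns and `label`.
#' @return An [eval_report()].
#' @export
evaluate <- function(model, test) {
  stop_if_not("label" %in% names(test), "test table needs a `label`")
  pred <- predict(model, test)
  lev <- sort(unique(c(model$levels, test$label)))
  cm <- table(factor(test$label, levels = lev), factor(pred, levels = lev))
  eval_report(unclass(as.matrix(cm)))
}

#' Stratified k-fold cross-validation
#'
#' Stratified folds; standardization and model refitted inside every fold;
#' OA/AA/kappa averaged across folds.
#'
#' @param table feature table with `label`.
#' @param spec a [classifier_spec()].
#' @param folds number of folds (default 10). Every class must have at least
#'   `folds` samples.
#' @param seed integer seed controlling fold assignment.
#' @return List with mean `oa`, `aa`, `kappa` and the per-fold reports.
#' @export
cross_validate <- function(table, spec, folds = 10, seed = 1) {
  y <- table$label
  counts <- table(y)
  if (any(counts < folds))
    stop(sprintf("class %s has fewer samples than folds",
                 names(counts)[which.min(counts)]), call. = FALSE)
  fold_of <- integer(nrow(table))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  reports <- lapply(seq_len(folds), function(f) {
    model <- train_classifier(table[fold_of != f, , drop = FALSE], spec)
    evaluate(model, table[fold_of == f, , drop = FALSE])
  })
  list(oa = mean(vapply(reports, `[[`, 0, "oa")),
       aa = mean(vapply(reports, `[[`, 0, "aa")),
       kappa = mean(vapply(reports, `[[`, 0, "kappa")),
       folds = reports, fold_of = fold_of)
}
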