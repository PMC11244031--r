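FAMILIES <- c("OS", "FOD", "SOD", "TF", "VI", "GF")

#' The ten feature-combination schemes
#'
#' Fixed catalogue of family combinations compared by the pipeline:
#' 1 OS+FOD, 2 FOD+TF, 3 OS+FOD+TF, 4 OS+SOD+TF, 5 OS+FOD+TF+VI,
#' 6 OS+FOD+TF+GF, 7 FOD+TF+VI, 8 FOD+TF+GF, 9 FOD+TF+VI+GF,
#' 10 OS+FOD+TF+VI+GF. OS = original spectra, FOD/SOD = first/second-order
#' differentiated spectra, TF = GLCM texture, VI = vegetation indices,
#' GF = geometric features.
#'
#' @return Named list of character vectors, names `"1"`-`"10"`.
#' @export
scheme_table <- function() {
  list(`1`  = c("OS", "FOD"),
       `2`  = c("FOD", "TF"),
       `3`  = c("OS", "FOD", "TF"),
       `4`  = c("OS", "SOD", "TF"),
       `5`  = c("OS", "FOD", "TF", "VI"),
       `6`  = c("OS", "FOD", "TF", "GF"),
       `7`  = c("FOD", "TF", "VI"),
       `8`  = c("FOD", "TF", "GF"),
       `9`  = c("FOD", "TF", "VI", "GF"),
       `10` = c("OS", "FOD", "TF", "VI", "GF"))
}

#' Build the six feature families from a cube
#'
#' Object mode: one row per segment with per-object means of the original
#' spectra (OS), first- and second-order Grünwald-Letnikov derivative bands
#' (FOD/SOD), the 24 GLCM texture layers (TF), the 15 vegetation indices
#' computed on the object-mean spectrum (VI), and the 14 geometric features
#' (GF). Pixel mode: the same per-pixel families with GF omitted (geometry
#' is undefined for single pixels). Column names carry the family prefix,
#' e.g. `"VI:NDVI"`.
#'
#' @param cube a [hyper_cube()].
#' @param segments integer segment map (required in object mode).
#' @param class_truth optional integer class raster; adds a `label` column
#'   (object mode: majority pixel class per object).
#' @param glcm a [glcm_spec()].
#' @param fod,sod [fracdiff_spec()]s for the two derivative families.
#' @param mode `"object"` or `"pixel"`.
#' @return A feature table (data.frame with `sample_id`, prefixed feature
#'   columns, optional `label`).
#' @export
build_feature_families <- function(cube, segments = NULL, class_truth = NULL,
                                   glcm = glcm_spec(),
                                   fod = fracdiff_spec(1),
                                   sod = fracdiff_spec(2),
                                   mode = c("object", "pixel")) {
  mode <- match.arg(mode)
  wl_names <- sprintf("b%.1f", cube$wavelengths)
  os <- cube$data
  fodc <- transform_cube(cube, fod)$data
  sodc <- transform_cube(cube, sod)$data
  tf <- texture_stack(cube, glcm)
  d <- dim(cube$data)
  layers <- array(c(os, fodc, sodc, tf), c(d[1], d[2], 3 * d[3] + 24))
  dimnames(layers) <- list(NULL, NULL, c(
    paste0("OS:", wl_names), paste0("FOD:", wl_names),
    paste0("SOD:", wl_names), paste0("TF:", dimnames(tf)[[3]])))
  if (mode == "object") {
    stop_if_not(!is.null(segments), "object mode needs a segment map")
    tab <- aggregate_by_object(layers, segments, class_truth)
    os_cols <- grepl("^OS:", names(tab))
    vi <- compute_all_vis(as.matrix(tab[, os_cols, drop = FALSE]),
                          cube$wavelengths)
    colnames(vi) <- paste0("VI:", colnames(vi))
    gf <- geometric_features(segments, cube$pixel_size)
    stopifnot(all(gf$sample_id == tab$sample_id))
    gf_m <- as.matrix(gf[, -1, drop = FALSE])
    colnames(gf_m) <- paste0("GF:", colnames(gf_m))
    out <- cbind(tab[, !(names(tab) %in% "label"), drop = FALSE],
                 as.data.frame(vi), as.data.frame(gf_m))
    if ("label" %in% names(tab)) out$label <- tab$label
    out
  } else {
    fm <- matrix(layers, d[1] * d[2], dim(layers)[3])
    colnames(fm) <- dimnames(layers)[[3]]
    vi <- compute_all_vis(matrix(os, d[1] * d[2], d[3]), cube$wavelengths)
    colnames(vi) <- paste0("VI:", colnames(vi))
    out <- data.frame(sample_id = seq_len(d[1] * d[2]), fm,
                      as.data.frame(vi), check.names = FALSE)
    if (!is.null(class_truth)) out$label <- as.vector(class_truth)
    out[as.vector(cube$mask), , drop = FALSE]
  }
}

# restrict a feature table to the named families (plus bookkeeping columns)
restrict_families <- function(table, families) {
  stop_if_not(all(families %in% FAMILIES),
              sprintf("unknown family; valid: %s",
                      paste(FAMILIES, collapse = ", ")))
  present <- unique(sub(":.*", "", feature_columns(table)))
  miss <- setdiff(families, present)
  if (length(miss) > 0)
    stop(sprintf("feature family missing from table: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  keep <- names(table) %in% c("sample_id", "label") |
    sub(":.*", "", names(table)) %in% families
  table[, keep, drop = FALSE]
}

#' Run one feature-combination scheme
#'
#' Restricts the feature table to the scheme's families, optionally runs GA
#' feature selection per family on the training rows only, trains the
#' classifier on the training objects and evaluates on the test objects.
#'
#' @param table object-mode feature table with `label`.
#' @param scheme scheme id (1-10), or a character vector of families.
#' @param classifier a [classifier_spec()].
#' @param split list with `train` and `test` sample_id vectors
#'   ([split_objects()]).
#' @param selection optional [ga_config()]; when given, [ga_select()] runs
#'   separately per family on the training rows and the union of masks is
#'   applied.
#' @return An [eval_report()] with attribute `"selected"` (per-family mask
#'   list) when selection ran.
#' @export
run_scheme <- function(table, scheme, classifier, split, selection = NULL) {
  families <- if (is.character(scheme) && all(scheme %in% FAMILIES)) scheme
    else scheme_table()[[as.character(scheme)]]
  stop_if_not(!is.null(families), "unknown scheme id")
  tab <- restrict_families(table, families)
  train <- tab[tab$sample_id %in% split$train, , drop = FALSE]
  test <- tab[tab$sample_id %in% split$test, , drop = FALSE]
  masks <- NULL
  if (!is.null(selection)) {
    masks <- lapply(families, function(fam) {
      sub <- restrict_families(train, fam)
      ga_select(sub, selection)$mask
    })
    names(masks) <- families
    full_mask <- stats::setNames(integer(length(feature_columns(tab))),
                                 feature_columns(tab))
    for (m in masks) full_mask[names(m)] <- m
    train <- apply_mask(train, full_mask)
    test <- apply_mask(test, full_mask)
  }
  model <- train_classifier(train, classifier)
  rep <- evaluate(model, test)
  attr(rep, "selected") <- masks
  rep
}

#' Salt-and-pepper index of a label map
#'
#' Fraction of pixels whose label differs from the majority label of their
#' 8-neighbourhood (ties broken toward the lowest class ID). Isolated
#' mislabelled pixels scattered through a classification map push this up;
#' object-based maps, being piecewise constant on segments, keep it low.
#'
#' @param labels integer matrix of predicted class labels.
#' @return Scalar in \[0, 1\].
#' @export
salt_pepper_index <- function(labels) {
  cls <- sort(unique(as.vector(labels)))
  nr <- nrow(labels); nc <- ncol(labels)
  counts <- array(0L, c(nr, nc, length(cls)))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    src_r <- seq_len(nr) + dr; src_c <- seq_len(nc) + dc
    ok_r <- src_r >= 1 & src_r <= nr; ok_c <- src_c >= 1 & src_c <= nc
    sh <- labels[src_r[ok_r], src_c[ok_c], drop = FALSE]
    for (k in seq_along(cls))
      counts[ok_r, ok_c, k] <- counts[ok_r, ok_c, k] + (sh == cls[k])
  }
  maj <- max.col(matrix(counts, nr * nc, length(cls)), ties.method = "first")
  mean(as.vector(labels) != cls[maj])
}

#' Compare object-based and pixel-based classification
#'
#' For every seed, generates a scene, runs the full pipeline in object mode
#' (per-object features, train/test split over objects) and in pixel mode
#' (per-pixel features for the pixels of the same train/test objects), and
#' records paired test overall accuracies and the salt-and-pepper index of
#' each full predicted map.
#'
#' @param classifier a [classifier_spec()].
#' @param seeds integer vector of scene seeds.
#' @param config_fn function(seed) returning a [scene_config()]; defaults to
#'   `scene_config(seed = seed)`.
#' @param glcm a [glcm_spec()].
#' @param families families used for classification (default scheme 10; GF
#'   dropped automatically in pixel mode).
#' @param max_train_pixels,max_test_pixels caps on pixels used to train and
#'   score the pixel-mode model (deterministic strided subsample); the full
#'   map is always predicted for the salt-and-pepper index.
#' @return data.frame with columns `seed, object_oa, pixel_oa, object_spi,
#'   pixel_spi`.
#' @export
compare_object_pixel <- function(classifier, seeds,
                                 config_fn = function(s) scene_config(seed = s),
                                 glcm = glcm_spec(),
                                 families = scheme_table()[["10"]],
                                 max_train_pixels = 2000,
                                 max_test_pixels = 4000) {
  stop_if_not(length(seeds) >= 1, "need >= 1 seed")
  res <- lapply(seeds, function(s) {
    scene <- make_scene(config_fn(s))
    segments <- scene$object_truth
    split <- split_objects(scene, seed = s)
    # object mode
    otab <- build_feature_families(scene$cube, segments, scene$class_truth,
                                   glcm = glcm, mode = "object")
    orep <- run_scheme(otab, families, classifier, split)
    omodel <- train_classifier(
      restrict_families(otab, families)[otab$sample_id %in% split$train, ],
      classifier)
    opred <- predict(omodel, restrict_families(otab, families))
    omap <- matrix(opred[segments], nrow(segments))
    # pixel mode (GF undefined per pixel)
    pfam <- setdiff(families, "GF")
    ptab <- build_feature_families(scene$cube, class_truth = scene$class_truth,
                                   glcm = glcm, mode = "pixel")
    ptab <- restrict_families(ptab, pfam)
    obj_of_pixel <- as.vector(segments)
    tr_rows <- which(obj_of_pixel[ptab$sample_id] %in% split$train)
    te_rows <- which(obj_of_pixel[ptab$sample_id] %in% split$test)
    stride <- function(idx, cap) if (length(idx) > cap)
      idx[round(seq(1, length(idx), length.out = cap))] else idx
    pmodel <- train_classifier(ptab[stride(tr_rows, max_train_pixels), ],
                               classifier)
    prep <- evaluate(pmodel, ptab[stride(te_rows, max_test_pixels), ])
    pmap <- matrix(predict(pmodel, ptab), nrow(segments))
    data.frame(seed = s, object_oa = orep$oa, pixel_oa = prep$oa,
               object_spi = salt_pepper_index(omap),
               pixel_spi = salt_pepper_index(pmap))
  })
  do.call(rbind, res)
}

#' Learning curves over training-set size
#'
#' Stratified subsampling of the training rows at each fraction; evaluation
#' on the fixed test rows. Fractions that leave fewer than one sample in a
#' class are skipped with a warning.
#'
#' @param table object-mode feature table with `label`.
#' @param specs list of [classifier_spec()]s (or one spec).
#' @param split list with `train` and `test` sample_id vectors.
#' @param fractions numeric vector in (0, 1\].
#' @param seeds integer vector of subsampling seeds.
#' @return data.frame with columns `classifier, fraction, seed, oa`.
#' @export
learning_curve <- function(table, specs, split, fractions = c(0.25, 0.5, 0.75, 1),
                           seeds = 1) {
  stop_if_not(all(fractions > 0 & fractions <= 1),
              "fractions must lie in (0, 1]")
  if (inherits(specs, "classifier_spec")) specs <- list(specs)
  train <- table[table$sample_id %in% split$train, , drop = FALSE]
  test <- table[table$sample_id %in% split$test, , drop = FALSE]
  out <- list()
  for (spec in specs) for (f in fractions) for (s in seeds) {
    sub <- if (f == 1) train else with_seed(s, {
      idx <- unlist(lapply(split(seq_len(nrow(train)), train$label),
                           function(i) {
        n <- max(1L, floor(f * length(i) + 0.5))
        sample(i, n)
      }))
      train[sort(idx), , drop = FALSE]
    })
    if (length(unique(sub$label)) < length(unique(train$label))) {
      warning(sprintf("fraction %.2f drops a class; skipped", f))
      next
    }
    rep <- evaluate(train_classifier(sub, spec), test)
    out[[length(out) + 1L]] <- data.frame(classifier = spec$kind,
                                          fraction = f, seed = s, oa = rep$oa)
  }
  do.call(rbind, out)
}

#' Write a deterministic JSON report
#'
#' Serializes a result list to JSON with fixed numeric formatting so that a
#' rerun with the same config and seed is byte-identical.
#'
#' @param x a list (reports, metrics, provenance).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
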