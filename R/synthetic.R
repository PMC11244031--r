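#' Configure a synthetic labelled hyperspectral scene
#'
#' The simulator emulates the statistical structure a canopy-species OBIA
#' pipeline has to cope with: four vegetation classes whose mean reflectance
#' curves are pairwise similar within two groups (classes 1-2 and classes
#' 3-4 differ only by a small red-edge shift and amplitude, while the groups
#' differ strongly), class-specific texture roughness (multiplicative
#' smoothed-noise fields with per-class correlation length and amplitude:
#' class 1 near-smooth through class 4 coarse-grained), a multiplicative
#' illumination gradient, additive sensor noise, and a patchwise object
#' layout (Voronoi cells of a seeded Poisson point process).
#'
#' @param rows,cols scene size in pixels (default 100 x 100).
#' @param n_classes number of vegetation classes (default 4; the default
#'   spectral library covers exactly 4).
#' @param wavelengths band grid in nm; default 253 evenly spaced bands on
#'   430.4-991.3 nm.
#' @param spectra optional n_classes x bands matrix of class mean
#'   reflectance curves in \[0, 1\]; default [default_spectra()].
#' @param texture_len per-class spatial correlation length of the texture
#'   field, px (default 1, 2, 4, 8).
#' @param texture_amp per-class texture amplitude as a fraction of the mean
#'   spectrum (default 0.03, 0.06, 0.12, 0.12).
#' @param illumination amplitude of the across-scene multiplicative
#'   illumination ramp (default 0.1, i.e. +-10%).
#' @param noise_sd additive per-band reflectance noise s.d. (default 0.03,
#'   a few percent of full scale — typical of narrow-band UAV push-broom
#'   sensors, and the source of the salt-and-pepper effect that object
#'   averaging removes).
#' @param patch_scale expected object diameter in px (default 20).
#' @param train_fraction fraction of objects allocated to training
#'   (default 0.30).
#' @param seed integer RNG seed (default 1).
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(rows = 100, cols = 100, n_classes = 4,
                         wavelengths = seq(430.4, 991.3, length.out = 253),
                         spectra = NULL,
                         texture_len = c(1, 2, 4, 8),
                         texture_amp = c(0.03, 0.06, 0.12, 0.12),
                         illumination = 0.1, noise_sd = 0.03,
                         patch_scale = 20, train_fraction = 0.30, seed = 1) {
  stop_if_not(noise_sd >= 0, "noise_sd must be >= 0")
  stop_if_not(train_fraction > 0 && train_fraction < 1,
              "train_fraction must be in (0, 1)")
  if (is.null(spectra)) {
    stop_if_not(n_classes == 4,
                "default spectral library covers 4 classes; supply `spectra`")
    spectra <- default_spectra(wavelengths)
  }
  stop_if_not(nrow(spectra) == n_classes &&
                ncol(spectra) == length(wavelengths),
              "`spectra` must be n_classes x length(wavelengths)")
  stop_if_not(all(spectra >= 0 & spectra <= 1), "spectra must lie in [0, 1]")
  stop_if_not(length(texture_len) == n_classes &&
                length(texture_amp) == n_classes,
              "texture parameters must have one entry per class")
  structure(list(rows = rows, cols = cols, n_classes = n_classes,
                 wavelengths = wavelengths, spectra = spectra,
                 texture_len = texture_len, texture_amp = texture_amp,
                 illumination = illumination, noise_sd = noise_sd,
                 patch_scale = patch_scale, train_fraction = train_fraction,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Default class mean reflectance curves
#'
#' Four vegetation-like reflectance curves built from a green peak (Gaussian
#' bump at 550 nm), a chlorophyll absorption minimum near 680 nm, a logistic
#' red edge through 700-750 nm, and an NIR plateau. Classes 1-2 share shape
#' and differ by a small red-edge shift and amplitude; classes 3-4 likewise;
#' the two groups differ strongly — mirroring how co-occurring mangrove
#' species pair up spectrally.
#'
#' @param wavelengths band grid in nm (within 400-1000 nm).
#' @return 4 x length(wavelengths) matrix of reflectance in \[0, 1\].
#' @export
default_spectra <- function(wavelengths) {
  stop_if_not(all(wavelengths >= 400 & wavelengths <= 1000),
              "wavelengths must lie within 400-1000 nm")
  curve <- function(green_amp, nir, edge)
    0.04 + green_amp * exp(-(wavelengths - 550)^2 / (2 * 30^2)) +
      nir / (1 + exp(-(wavelengths - edge) / 12))
  rbind(curve(0.080, 0.48, 712),
        curve(0.072, 0.45, 717),
        curve(0.050, 0.62, 722),
        curve(0.057, 0.58, 727))
}

# separable Gaussian smoothing with edge renormalization; returns sd-1 field
smooth_field <- function(noise, sigma) {
  if (sigma <= 0.5) return(noise / stats::sd(noise))
  kern1 <- function(n) {
    idx <- seq_len(n)
    k <- outer(idx, idx, function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
    k / rowSums(k)
  }
  sm <- kern1(nrow(noise)) %*% noise %*% t(kern1(ncol(noise)))
  sm / stats::sd(sm)
}

#' Generate a labelled synthetic scene
#'
#' Draws a patch partition (Voronoi cells of Poisson points with intensity
#' set by `patch_scale`), assigns every patch a class (each class guaranteed
#' at least two patches), and synthesises each pixel spectrum as
#' `class_mean * illumination * (1 + texture_field) + noise`. Identical
#' config + seed gives an identical scene.
#'
#' @param config a [scene_config()].
#' @return An object of class `synthetic_scene`: list with `cube`
#'   ([hyper_cube()]), `class_truth` and `object_truth` (integer matrices,
#'   0 = background — all pixels are foreground here), and `config`.
#' @export
make_scene <- function(config = scene_config()) {
  stop_if_not(inherits(config, "scene_config"), "`config` must be scene_config")
  rows <- config$rows; cols <- config$cols; k <- config$n_classes
  stop_if_not(config$patch_scale < min(rows, cols),
              "patch_scale must be smaller than the scene extent")
  with_seed(config$seed, {
    n_pts <- max(2L * k, stats::rpois(1, rows * cols / config$patch_scale^2))
    pr <- stats::runif(n_pts, 0.5, rows + 0.5)
    pc <- stats::runif(n_pts, 0.5, cols + 0.5)
    # Voronoi assignment: nearest seed point per pixel
    gr <- rep(seq_len(rows), cols); gc <- rep(seq_len(cols), each = rows)
    d2 <- outer(gr, pr, `-`)^2 + outer(gc, pc, `-`)^2
    cell <- max.col(-d2, ties.method = "first")
    object_truth <- matrix(cell, rows, cols)
    # some Voronoi generators may own zero pixels; relabel contiguously
    ids <- sort(unique(cell))
    object_truth <- matrix(match(cell, ids), rows, cols)
    n_obj <- length(ids)
    stop_if_not(n_obj >= 2L * k, "too few patches; reduce patch_scale")
    # class assignment: two guaranteed patches per class, rest uniform
    cls <- c(rep(seq_len(k), 2),
             sample.int(k, n_obj - 2L * k, replace = TRUE))
    cls <- cls[sample.int(n_obj)]
    class_truth <- matrix(cls[object_truth], rows, cols)
    # illumination ramp (zero-mean plane, unit-amplitude corners)
    ramp <- outer(seq(-1, 1, length.out = rows),
                  seq(-1, 1, length.out = cols), `+`) / 2
    illum <- 1 + config$illumination * ramp
    # per-class multiplicative texture fields
    tex <- matrix(0, rows, cols)
    for (ci in seq_len(k)) {
      f <- smooth_field(matrix(stats::rnorm(rows * cols), rows, cols),
                        config$texture_len[ci])
      sel <- class_truth == ci
      tex[sel] <- config$texture_amp[ci] * f[sel]
    }
    nb <- length(config$wavelengths)
    gain <- as.vector(illum * (1 + tex))
    data <- config$spectra[as.vector(class_truth), , drop = FALSE] * gain
    if (config$noise_sd > 0)
      data <- data + stats::rnorm(length(data), sd = config$noise_sd)
    # calibrated vegetation reflectance never reaches exactly 0; a small
    # positive floor keeps ratio indices (1/rho terms) finite under noise
    data <- pmin(pmax(data, 1e-3), 1.5)
    cube <- hyper_cube(array(data, c(rows, cols, nb)), config$wavelengths,
                       pixel_size = 0.4)
    structure(list(cube = cube, class_truth = class_truth,
                   object_truth = object_truth, config = config),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d px, %d bands, %d classes, %d objects\n",
              x$config$rows, x$config$cols, length(x$config$wavelengths),
              x$config$n_classes, max(x$object_truth)))
  invisible(x)
}

#' Stratified train/test split of scene objects
#'
#' Randomly allocates `round-half-up(train_fraction * n_class)` objects of
#' every class to training; the rest are test. Disjoint and exhaustive.
#'
#' @param scene a [make_scene()] result, or any list with `object_truth` and
#'   `class_truth` matrices.
#' @param train_fraction training fraction (default the scene config's,
#'   0.30 otherwise).
#' @param seed integer seed.
#' @return List with integer vectors `train` and `test` of object IDs.
#' @export
split_objects <- function(scene, train_fraction = NULL, seed = 1) {
  train_fraction <- train_fraction %||%
    (if (!is.null(scene$config)) scene$config$train_fraction else 0.30)
  stop_if_not(train_fraction > 0 && train_fraction < 1,
              "train_fraction must be in (0, 1)")
  obj_cls <- object_classes(scene$object_truth, scene$class_truth)
  counts <- table(obj_cls)
  if (any(counts < 2)) stop("every class needs >= 2 objects", call. = FALSE)
  with_seed(seed, {
    train <- integer(0)
    for (cl in sort(unique(obj_cls))) {
      ids <- as.integer(names(obj_cls)[obj_cls == cl])
      n_train <- floor(train_fraction * length(ids) + 0.5)  # round half up
      n_train <- max(1L, min(n_train, length(ids) - 1L))
      train <- c(train, sort(sample(ids, n_train)))
    }
    list(train = sort(train),
         test = sort(setdiff(as.integer(names(obj_cls)), train)))
  })
}

# majority class per object (objects in a synthetic scene are class-pure)
object_classes <- function(object_truth, class_truth) {
  seg <- as.vector(object_truth); ct <- as.vector(class_truth)
  keep <- seg > 0
  seg <- seg[keep]; ct <- ct[keep]
  ids <- sort(unique(seg))
  cls <- sort(unique(ct))
  out <- vapply(ids, function(i) {
    cnt <- vapply(cls, function(k) sum(ct[seg == i] == k), integer(1))
    as.integer(cls[which.max(cnt)])
  }, integer(1))
  names(out) <- ids
  out
}
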