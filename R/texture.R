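GLCM_STATS <- c("mean", "variance", "homogeneity", "contrast",
                "dissimilarity", "entropy", "second_moment", "correlation")

#' Specify GLCM texture extraction
#'
#' Grey-level co-occurrence matrix (GLCM) texture statistics are computed in
#' a sliding window on each of the first three principal-component images of
#' the cube. The default window of 23 px is where inter-class separability
#' typically stabilizes for tree canopies at ~0.4 m resolution; the window
#' sweep in [select_window()] makes that choice data-driven.
#'
#' @param window odd window size in pixels, 3-45 (default 23).
#' @param levels grey quantization levels (default 32; linear min-max over
#'   the whole image).
#' @param offsets integer matrix of (row, col) displacements; default the
#'   four unit directions 0, 45, 90, 135 degrees at distance 1, accumulated
#'   symmetrically into one co-occurrence matrix.
#' @return An object of class `glcm_spec`.
#' @export
glcm_spec <- function(window = 23, levels = 32,
                      offsets = rbind(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))) {
  stop_if_not(window >= 3 && window %% 2 == 1, "window must be odd and >= 3")
  stop_if_not(levels >= 2, "levels must be >= 2")
  offsets <- matrix(as.integer(offsets), ncol = 2)
  structure(list(window = as.integer(window), levels = as.integer(levels),
                 offsets = offsets, statistics = GLCM_STATS),
            class = "glcm_spec")
}

#' Principal-component images of a cube
#'
#' Eigen-decomposition of the band-space covariance of the mean-centred
#' unmasked pixels. Components are ordered by decreasing eigenvalue, and each
#' component's largest-magnitude loading is made positive so signs are
#' reproducible.
#'
#' @param cube a [hyper_cube()].
#' @param k number of components (default 3).
#' @return List with `images` (rows x cols x k array; masked pixels `NA`),
#'   `loadings` (bands x k), and `explained` (variance fractions).
#' @export
pca_components <- function(cube, k = 3) {
  stop_if_not(inherits(cube, "hyper_cube"), "`cube` must be a hyper_cube")
  nb <- n_bands(cube)
  stop_if_not(k <= nb, "k must not exceed the number of bands")
  xm <- cube_to_matrix(cube)
  ok <- as.vector(cube$mask)
  xs <- xm[ok, , drop = FALSE]
  ctr <- colMeans(xs)
  xs <- sweep(xs, 2, ctr)
  cv <- crossprod(xs) / (nrow(xs) - 1L)
  eig <- eigen(cv, symmetric = TRUE)
  load <- eig$vectors[, seq_len(k), drop = FALSE]
  # sign convention: largest-|loading| entry positive
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  scores <- sweep(xm, 2, ctr) %*% load
  scores[!ok, ] <- NA_real_
  d <- dim(cube$data)
  list(images = array(scores, c(d[1], d[2], k)),
       loadings = load,
       explained = pmax(eig$values[seq_len(k)], 0) /
         sum(pmax(eig$values, 0)))
}

# linear min-max quantization to {0, ..., levels-1}; NA -> -1 (missing)
quantize_image <- function(image, levels) {
  rng <- range(image, na.rm = TRUE)
  q <- if (rng[2] > rng[1])
    pmin(floor((image - rng[1]) / (rng[2] - rng[1]) * levels), levels - 1L)
  else image * 0
  q[is.na(q)] <- -1
  matrix(as.integer(q), nrow(image), ncol(image))
}

#' Sliding-window GLCM statistics of one image
#'
#' For every pixel, the window (clipped at the image border) is quantized
#' grey levels (min-max over the whole image) and the symmetric
#' co-occurrence matrix P over the offset set is normalised to sum 1, from
#' which eight statistics follow: mean, variance, homogeneity
#' `sum P/(1+(i-j)^2)`, contrast `sum (i-j)^2 P`, dissimilarity
#' `sum |i-j| P`, entropy `-sum P ln P`, second moment `sum P^2`, and
#' correlation (0 when either marginal is constant).
#'
#' @param image numeric matrix; `NA` cells are treated as missing.
#' @param spec a [glcm_spec()].
#' @return rows x cols x 8 array with statistic names on the third dimension.
#' @export
glcm_statistics <- function(image, spec = glcm_spec()) {
  stop_if_not(is.matrix(image), "`image` must be a matrix")
  stop_if_not(spec$window < nrow(image) && spec$window < ncol(image),
              "window exceeds image extent")
  q <- quantize_image(image, spec$levels)
  out <- glcm_stats_cpp(q, spec$window, spec$levels, spec$offsets)
  dimnames(out) <- list(NULL, NULL, GLCM_STATS)
  out
}

#' Texture feature stack of a cube
#'
#' The first three principal-component images of the cube, each summarised
#' by the eight GLCM statistics: 24 named texture layers ("PC1_mean", ...).
#'
#' @param cube a [hyper_cube()].
#' @param spec a [glcm_spec()].
#' @return rows x cols x 24 array, layer names `PCk_<statistic>`.
#' @export
texture_stack <- function(cube, spec = glcm_spec()) {
  pcs <- pca_components(cube, k = 3)
  layers <- lapply(1:3, function(j)
    glcm_statistics(pcs$images[, , j], spec))
  d <- dim(cube$data)
  out <- array(unlist(layers, use.names = FALSE), c(d[1], d[2], 24L))
  dimnames(out) <- list(NULL, NULL,
    as.vector(t(outer(paste0("PC", 1:3), GLCM_STATS, paste, sep = "_"))))
  out
}

#' Jeffries-Matusita distance between two sample sets
#'
#' Class separability under a multivariate-Gaussian assumption:
#' `JM = 2 (1 - exp(-B))`, with the Bhattacharyya distance
#' \deqn{B = \tfrac18 (\mu_a-\mu_b)^\top \left[\tfrac{\Sigma_a+\Sigma_b}2
#' \right]^{-1}(\mu_a-\mu_b) + \tfrac12 \ln \frac{|(\Sigma_a+\Sigma_b)/2|}
#' {\sqrt{|\Sigma_a||\Sigma_b|}}.}
#' JM is bounded in \[0, 2\]; 2 means complete separability. Covariances are
#' regularized by `+ eps I` with `eps = 1e-6 * mean(diag)`.
#'
#' @param samples_a,samples_b numeric matrices (rows = samples, columns =
#'   features), at least 2 rows each, equal column count.
#' @return Scalar J-M distance.
#' @export
jm_distance <- function(samples_a, samples_b) {
  samples_a <- as.matrix(samples_a); samples_b <- as.matrix(samples_b)
  stop_if_not(ncol(samples_a) == ncol(samples_b),
              "sample sets must have equal dimensionality")
  stop_if_not(nrow(samples_a) >= 2 && nrow(samples_b) >= 2,
              "need >= 2 samples per class")
  mu_a <- colMeans(samples_a); mu_b <- colMeans(samples_b)
  reg <- function(S) {
    eps <- 1e-6 * mean(diag(S))
    if (!is.finite(eps) || eps <= 0) eps <- 1e-12
    S + diag(eps, ncol(S))
  }
  Sa <- reg(stats::cov(samples_a)); Sb <- reg(stats::cov(samples_b))
  Sm <- (Sa + Sb) / 2
  ld <- function(S) determinant(S, logarithm = TRUE)$modulus
  sol <- tryCatch(solve(Sm, mu_a - mu_b),
                  error = function(e) stop("singular regularized covariance",
                                           call. = FALSE))
  B <- sum((mu_a - mu_b) * sol) / 8 +
    0.5 * as.numeric(ld(Sm) - (ld(Sa) + ld(Sb)) / 2)
  2 * (1 - exp(-B))
}

#' Select the GLCM window by a separability sweep
#'
#' Computes the texture stack for every candidate window, samples per-class
#' texture vectors at labelled pixels, and records all pairwise J-M
#' distances. The chosen window is the smallest `w` whose minimum pairwise
#' J-M increases by less than `eps_plateau` at each of the next two larger
#' windows (the separability "plateau"); if no window satisfies this, the
#' largest is returned.
#'
#' @param cube a [hyper_cube()].
#' @param class_truth integer matrix of class labels (0 = background).
#' @param windows odd window sizes to sweep (default 3, 5, ..., 45; 22
#'   windows).
#' @param spec a [glcm_spec()]; its window field is overridden per sweep
#'   step.
#' @param eps_plateau plateau tolerance on the minimum pairwise J-M
#'   (default 0.01).
#' @param max_per_class cap on labelled pixels sampled per class (default
#'   500; deterministic strided subsample).
#' @return List with `window` (chosen size) and `separability`, a data frame
#'   of columns `window, class_i, class_j, jm`.
#' @export
select_window <- function(cube, class_truth, windows = seq(3, 45, by = 2),
                          spec = glcm_spec(), eps_plateau = 0.01,
                          max_per_class = 500) {
  stop_if_not(length(windows) > 0, "windows list is empty")
  stop_if_not(all(windows %% 2 == 1), "windows must be odd")
  windows <- sort(as.integer(windows))
  classes <- sort(setdiff(unique(as.vector(class_truth)), 0L))
  stop_if_not(length(classes) >= 2, "need >= 2 classes present")
  pairs <- utils::combn(classes, 2)
  rows <- list()
  min_jm <- numeric(length(windows))
  for (wi in seq_along(windows)) {
    sp <- spec; sp$window <- windows[wi]
    st <- texture_stack(cube, sp)
    fm <- matrix(st, prod(dim(st)[1:2]), dim(st)[3])
    lab <- as.vector(class_truth)
    jms <- apply(pairs, 2, function(pr) {
      ia <- which(lab == pr[1]); ib <- which(lab == pr[2])
      if (length(ia) > max_per_class)
        ia <- ia[round(seq(1, length(ia), length.out = max_per_class))]
      if (length(ib) > max_per_class)
        ib <- ib[round(seq(1, length(ib), length.out = max_per_class))]
      jm_distance(fm[ia, , drop = FALSE], fm[ib, , drop = FALSE])
    })
    rows[[wi]] <- data.frame(window = windows[wi], class_i = pairs[1, ],
                             class_j = pairs[2, ], jm = jms)
    min_jm[wi] <- min(jms)
  }
  chosen <- windows[length(windows)]
  for (wi in seq_along(windows)) {
    if (wi + 1L > length(windows)) { chosen <- windows[wi]; break }
    ahead <- seq(wi + 1L, min(wi + 2L, length(windows)))
    if (all(min_jm[ahead] - min_jm[wi] < eps_plateau)) {
      chosen <- windows[wi]; break
    }
  }
  list(window = chosen, separability = do.call(rbind, rows))
}
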