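#' Stand-in region-merging segmentation
#'
#' A simple, deterministic object extractor used when no externally produced
#' segmentation raster is available: starting from single-pixel regions on
#' the first principal-component image, 4-adjacent regions are merged while
#' their mean intensities differ by less than `merge_threshold` times the
#' global intensity range. Higher thresholds give fewer, larger objects.
#' Externally produced segment rasters (via [read_labels()]) are the
#' fidelity-preserving alternative and are accepted everywhere a segment map
#' is consumed.
#'
#' @param cube a [hyper_cube()].
#' @param merge_threshold fraction of the global PC1 intensity range
#'   (default 0.05). 0 leaves every pixel its own object.
#' @param seed unused (the algorithm is deterministic); accepted for
#'   interface uniformity.
#' @return Integer matrix of object IDs, contiguous 1..K in scan order;
#'   0 marks masked pixels.
#' @export
segment_stand_in <- function(cube, merge_threshold = 0.05, seed = NULL) {
  stop_if_not(inherits(cube, "hyper_cube"), "`cube` must be a hyper_cube")
  pc1 <- pca_components(cube, k = 1)$images[, , 1]
  rng <- diff(range(pc1, na.rm = TRUE))
  valid <- matrix(as.integer(cube$mask & !is.na(pc1)), nrow(pc1))
  pc1[is.na(pc1)] <- 0
  merge_regions_cpp(pc1, valid, merge_threshold * rng, 1000L)
}

#' Aggregate per-pixel feature layers by object
#'
#' One row per object; each feature is the arithmetic mean over the object's
#' unmasked pixels. When a class-truth raster is supplied, each object gets
#' the majority pixel class (ties broken toward the lowest class ID).
#'
#' @param maps per-pixel features: a rows x cols x L array (or matrix for
#'   L = 1), layer names used as column names.
#' @param segments integer matrix of object IDs (0 = background).
#' @param class_truth optional integer matrix of pixel class labels.
#' @return data.frame with `sample_id`, one column per layer, and `label`
#'   when truth is given. Objects with zero valid pixels are dropped with a
#'   warning.
#' @export
aggregate_by_object <- function(maps, segments, class_truth = NULL) {
  if (is.matrix(maps)) maps <- array(maps, c(dim(maps), 1L))
  d <- dim(maps)
  stop_if_not(all(d[1:2] == dim(segments)), "shape mismatch")
  fm <- matrix(maps, d[1] * d[2], d[3])
  colnames(fm) <- dimnames(maps)[[3]] %||% paste0("f", seq_len(d[3]))
  seg <- as.vector(segments)
  keep <- seg > 0
  fm <- fm[keep, , drop = FALSE]; seg <- seg[keep]
  ids <- sort(unique(seg))
  sums <- rowsum(fm, seg, na.rm = TRUE)
  cnts <- rowsum((!is.na(fm)) + 0, seg)
  means <- sums / cnts
  empty <- rowSums(cnts) == 0
  if (any(empty)) {
    warning(sprintf("%d object(s) with no valid pixels dropped", sum(empty)))
    means <- means[!empty, , drop = FALSE]
    ids <- ids[!empty]
  }
  out <- data.frame(sample_id = ids, means, check.names = FALSE)
  if (!is.null(class_truth)) {
    ct <- as.vector(class_truth)[keep]
    cls <- sort(unique(ct))
    out$label <- vapply(ids, function(i) {
      cnt <- vapply(cls, function(k) sum(ct[seg == i] == k), integer(1))
      as.integer(cls[which.max(cnt)])  # ties -> lowest class ID
    }, integer(1))
  }
  rownames(out) <- NULL
  out
}

#' The 14 geometric features of image objects
#'
#' Per object (4-connected; background 8-connected for hole counting):
#' area (pixel count x pixel_size^2), length (total boundary length, outer
#' plus hole boundaries, by pixel-edge counting), compactness
#' `sqrt(4 area / pi) / major_axis`, convexity (convex-hull perimeter /
#' outer perimeter), solidity (area / convex-hull area), roundness
#' `4 area / (pi major_axis^2)`, form factor `4 pi area / length^2`,
#' elongation (major / minor axis), rectangularity fit (area / oriented
#' bounding-box area), main direction (major-axis angle, degrees in
#' \[0, 180)), major and minor axis lengths of the second-moment ellipse
#' (pixels modelled as unit squares, so a w x h rectangle yields axes
#' proportional to w and h exactly), number of holes, and solid area
#' (area + hole area). Definitions are modelled on ENVI's attribute
#' semantics; exact equivalence with any proprietary tool is not claimed.
#'
#' @param segments integer matrix of object IDs (0 = background).
#' @param pixel_size ground sampling distance in metres (default 1).
#' @return data.frame, one row per object ID, 14 feature columns.
#' @export
geometric_features <- function(segments, pixel_size = 1) {
  ids <- sort(setdiff(unique(as.vector(segments)), 0L))
  stop_if_not(length(ids) >= 1, "no objects present")
  ps <- pixel_size
  res <- lapply(ids, function(id) {
    px <- which(segments == id, arr.ind = TRUE)  # (row, col), 1-based
    n <- nrow(px)
    r0 <- min(px[, 1]); r1 <- max(px[, 1])
    c0 <- min(px[, 2]); c1 <- max(px[, 2])
    # local binary mask with 1-pixel pad
    h <- r1 - r0 + 3L; w <- c1 - c0 + 3L
    m <- matrix(0L, h, w)
    m[cbind(px[, 1] - r0 + 2L, px[, 2] - c0 + 2L)] <- 1L
    # holes: 8-connected background components not touching the pad border
    bg <- label_components_cpp(1L - m, 8L)
    border_ids <- unique(c(bg[1, ], bg[h, ], bg[, 1], bg[, w]))
    hole_ids <- setdiff(setdiff(unique(as.vector(bg)), 0L), border_ids)
    n_holes <- length(hole_ids)
    hole_px <- sum(bg %in% hole_ids)
    # total boundary: pixel edges adjacent to non-object cells
    up    <- m[-1, ] & !m[-h, ]; down  <- m[-h, ] & !m[-1, ]
    left  <- m[, -1] & !m[, -w]; right <- m[, -w] & !m[, -1]
    length_tot <- sum(up) + sum(down) + sum(left) + sum(right)
    # outer perimeter: boundary of the hole-filled object
    mf <- m; mf[bg %in% hole_ids] <- 1L
    upf    <- mf[-1, ] & !mf[-h, ]; downf  <- mf[-h, ] & !mf[-1, ]
    leftf  <- mf[, -1] & !mf[, -w]; rightf <- mf[, -w] & !mf[, -1]
    outer_per <- sum(upf) + sum(downf) + sum(leftf) + sum(rightf)
    # convex hull over pixel corners (x = col, y = row)
    corners <- unique(rbind(
      cbind(px[, 2] - 0.5, px[, 1] - 0.5), cbind(px[, 2] + 0.5, px[, 1] - 0.5),
      cbind(px[, 2] - 0.5, px[, 1] + 0.5), cbind(px[, 2] + 0.5, px[, 1] + 0.5)))
    hull <- corners[grDevices::chull(corners), , drop = FALSE]
    hull_area <- polygon_area(hull)
    hull_per <- polygon_perimeter(hull)
    # second-moment ellipse; each pixel a unit square (+1/12 per axis)
    xy <- cbind(px[, 2], px[, 1])
    cv <- crossprod(sweep(xy, 2, colMeans(xy))) / n + diag(1 / 12, 2)
    eg <- eigen(cv, symmetric = TRUE)
    major <- 4 * sqrt(eg$values[1]); minor <- 4 * sqrt(eg$values[2])
    v <- eg$vectors[, 1]
    ang <- (atan2(v[2], v[1]) * 180 / pi) %% 180
    area <- n * ps^2
    len <- length_tot * ps
    maj <- major * ps; mnr <- minor * ps
    bbox_area <- oriented_bbox_area(hull) * ps^2
    data.frame(
      sample_id = id,
      area = area,
      length = len,
      compactness = sqrt(4 * area / pi) / maj,
      convexity = hull_per / outer_per,
      solidity = n / hull_area,
      roundness = 4 * area / (pi * maj^2),
      form_factor = 4 * pi * area / len^2,
      elongation = maj / mnr,
      rectangularity = n / bbox_area * ps^2,
      main_direction = ang,
      major_axis = maj,
      minor_axis = mnr,
      n_holes = n_holes,
      solid_area = (n + hole_px) * ps^2)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Read or write a feature table as CSV
#'
#' Plain CSV with header `sample_id,<family:feature>,...,label`; feature
#' column names keep their family prefix.
#'
#' @param table feature table (data.frame).
#' @param path CSV path.
#' @return `read_feature_table`: the data.frame. `write_feature_table`:
#'   `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

polygon_perimeter <- function(p) {
  q <- rbind(p, p[1, ])
  sum(sqrt(rowSums(diff(q)^2)))
}

# minimum-area rectangle over a convex hull: one edge is always collinear
# with a hull edge, so scan hull-edge directions
oriented_bbox_area <- function(hull) {
  if (nrow(hull) == 1) return(0)
  q <- rbind(hull, hull[1, ])
  e <- diff(q)
  best <- Inf
  for (i in seq_len(nrow(e))) {
    len <- sqrt(sum(e[i, ]^2))
    if (len == 0) next
    u <- e[i, ] / len; v <- c(-u[2], u[1])
    pu <- hull %*% u; pv <- hull %*% v
    a <- diff(range(pu)) * diff(range(pv))
    if (a < best) best <- a
  }
  best
}
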