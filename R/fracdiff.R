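#' Specify a Grünwald-Letnikov fractional derivative
#'
#' The Grünwald-Letnikov construction generalises discrete differencing to
#' arbitrary order nu >= 0 through a weighted backward sum
#' \deqn{d^\nu f(x) \approx h^{-\nu} \sum_{m \ge 0} w_m f(x - mh),\quad
#'       w_m = (-1)^m \frac{\Gamma(\nu+1)}{m!\,\Gamma(\nu-m+1)}.}
#' Orders 1 and 2 recover the ordinary first and second backward differences;
#' non-integer orders interpolate between them. Applied along the spectral
#' axis it sharpens subtle reflectance differences between similar species
#' while damping smooth illumination effects.
#'
#' @param order differentiation order nu >= 0 (dimensionless). 1 = FOD,
#'   2 = SOD.
#' @param step sample spacing h > 0 in band-index units (default 1; the
#'   derivative is computed on the band grid, not in nm).
#' @param memory maximum number of trailing samples per output point;
#'   `Inf` (default) uses all samples to the left.
#' @param boundary `"truncate"` computes leading samples from the shorter
#'   available history; `"mark_invalid"` sets them to `NA` (the first
#'   `ceiling(order)` samples, where the difference stencil is incomplete).
#' @return An object of class `fracdiff_spec`.
#' @export
fracdiff_spec <- function(order, step = 1, memory = Inf,
                          boundary = c("truncate", "mark_invalid")) {
  stop_if_not(is.numeric(order) && length(order) == 1 && order >= 0,
              "`order` must be a single number >= 0")
  stop_if_not(step > 0, "`step` must be > 0")
  stop_if_not(memory >= 1, "`memory` must be >= 1")
  structure(list(order = order, step = step, memory = memory,
                 boundary = match.arg(boundary)),
            class = "fracdiff_spec")
}

#' Grünwald-Letnikov weight sequence
#'
#' Computes w_0 ... w_n via the stable multiplicative recurrence
#' `w_m = w_{m-1} * (m - 1 - nu) / m`, which is algebraically identical to
#' the Gamma-ratio form `(-1)^m Gamma(nu+1) / (m! Gamma(nu-m+1))` but avoids
#' Gamma poles at non-positive integers and overflow for large m. For
#' integer nu all weights beyond index nu are exactly zero.
#'
#' @param order nu >= 0.
#' @param n_terms highest index n (returns n + 1 weights).
#' @return Numeric vector `c(w0, ..., wn)` with `w0 = 1`.
#' @examples
#' gl_weights(1, 3)    # 1 -1  0  0
#' gl_weights(0.5, 3)  # 1 -0.5 -0.125 -0.0625
#' @export
gl_weights <- function(order, n_terms) {
  stop_if_not(order >= 0, "`order` must be >= 0")
  stop_if_not(n_terms >= 0, "`n_terms` must be >= 0")
  w <- numeric(n_terms + 1L)
  w[1L] <- 1
  if (n_terms >= 1) for (m in 1:n_terms)
    w[m + 1L] <- w[m] * (m - 1 - order) / m
  w
}

#' Fractional derivative of a reflectance spectrum
#'
#' Applies the Grünwald-Letnikov backward sum along a single spectrum:
#' `out[k] = h^(-nu) * sum_{m=0}^{min(k-1, memory)} w_m * x[k - m]`.
#' Order 0 returns the input unchanged.
#'
#' @param reflectance numeric vector (one value per band).
#' @param spec a [fracdiff_spec()].
#' @return Numeric vector of the same length (the derivative attributed to
#'   each band); leading samples are `NA` under `boundary = "mark_invalid"`.
#' @examples
#' fractional_derivative(c(0, 1, 2, 3), fracdiff_spec(1))
#' @export
fractional_derivative <- function(reflectance, spec) {
  stop_if_not(inherits(spec, "fracdiff_spec"), "`spec` must be fracdiff_spec")
  x <- as.numeric(reflectance)
  if (length(x) == 0) stop("empty spectrum", call. = FALSE)
  out <- fracdiff_matrix(length(x), spec) %*% x
  out <- drop(out)
  if (spec$boundary == "mark_invalid" && spec$order > 0)
    out[seq_len(min(length(x), ceiling(spec$order)))] <- NA_real_
  out
}

# lower-triangular Toeplitz operator implementing the GL sum
fracdiff_matrix <- function(n, spec) {
  mem <- min(n - 1L, if (is.finite(spec$memory)) spec$memory else n - 1L)
  w <- gl_weights(spec$order, mem) / spec$step^spec$order
  tm <- matrix(0, n, n)
  for (m in 0:mem) {
    idx <- seq_len(n - m)
    tm[cbind(idx + m, idx)] <- w[m + 1L]
  }
  tm
}

#' Fractional derivative of every pixel spectrum in a cube
#'
#' Applies [fractional_derivative()] along the spectral axis of every
#' unmasked pixel, implemented as one matrix product with the band-space
#' differencing operator. Band count and wavelengths are preserved (the
#' derivative is attributed to the band at which the backward sum ends).
#'
#' @param cube a [hyper_cube()].
#' @param spec a [fracdiff_spec()].
#' @return A `hyper_cube` of derivative bands.
#' @export
transform_cube <- function(cube, spec) {
  stop_if_not(inherits(cube, "hyper_cube"), "`cube` must be a hyper_cube")
  d <- dim(cube$data)
  xm <- cube_to_matrix(cube)                    # pixels x bands
  out <- xm %*% t(fracdiff_matrix(d[3L], spec)) # pixels x bands
  if (spec$boundary == "mark_invalid" && spec$order > 0)
    out[, seq_len(min(d[3L], ceiling(spec$order)))] <- NA_real_
  out[!cube$mask, ] <- NA_real_
  res <- cube
  res$data <- array(out, d)
  res
}
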