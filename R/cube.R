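#' Construct a hyperspectral reflectance cube
#'
#' A `hyper_cube` bundles a rows x cols x bands reflectance array with its
#' wavelength vector (nm), an optional per-pixel validity mask, and the ground
#' sampling distance. It is the unit every stage of the pipeline consumes.
#'
#' @param data numeric array, rows x cols x bands. Reflectance, expected in
#'   roughly \[0, 1\] after calibration.
#' @param wavelengths numeric vector of band-centre wavelengths in nm,
#'   strictly increasing, one per band.
#' @param mask optional logical matrix (rows x cols); `TRUE` marks valid
#'   pixels. Defaults to all valid.
#' @param pixel_size ground sampling distance in metres (default 0.4).
#' @param meta optional list of opaque metadata (e.g. geo-registration tags);
#'   carried through, never used in computation.
#' @return An object of class `hyper_cube`.
#' @examples
#' cube <- hyper_cube(array(runif(5 * 4 * 3), c(5, 4, 3)), c(450, 550, 650))
#' dim(cube)
#' @export
hyper_cube <- function(data, wavelengths, mask = NULL, pixel_size = 0.4,
                       meta = list()) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  stop_if_not(is.array(data) && length(dim(data)) == 3L,
              "`data` must be a rows x cols x bands array")
  wavelengths <- as.numeric(wavelengths)
  stop_if_not(length(wavelengths) == dim(data)[3L],
              "length(wavelengths) must equal the number of bands")
  stop_if_not(all(diff(wavelengths) > 0),
              "wavelengths must be strictly increasing")
  if (is.null(mask)) mask <- matrix(TRUE, dim(data)[1L], dim(data)[2L])
  stop_if_not(is.logical(mask) && all(dim(mask) == dim(data)[1:2]),
              "mask must be a logical rows x cols matrix")
  if (any(mask) && !all(is.finite(data[rep(mask, dim(data)[3L])])))
    stop("unmasked cube values must be finite", call. = FALSE)
  structure(list(data = data, wavelengths = wavelengths, mask = mask,
                 pixel_size = pixel_size, meta = meta),
            class = "hyper_cube")
}

#' @export
dim.hyper_cube <- function(x) dim(x$data)

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyper_cube> %d x %d pixels, %d bands (%.1f-%.1f nm), %.2g m/px\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              x$pixel_size))
  invisible(x)
}

#' Number of bands of a cube
#' @param cube a [hyper_cube()].
#' @return integer band count.
#' @export
n_bands <- function(cube) dim(cube$data)[3L]

#' Restrict a cube to a wavelength interval
#'
#' Keeps exactly the bands whose wavelength lies in the closed interval
#' \[`keep_min`, `keep_max`\]. Sensor bands at both spectral ends are commonly
#' dropped this way because of low signal-to-noise; the pipeline default
#' interval is 430.4-991.3 nm.
#'
#' @param cube a [hyper_cube()].
#' @param keep_min,keep_max interval bounds in nm, `keep_min < keep_max`.
#' @return A `hyper_cube` with the retained bands, order preserved.
#' @examples
#' cube <- hyper_cube(array(1, c(2, 2, 4)), c(400, 500, 600, 700))
#' filter_bands(cube, 450, 650)$wavelengths
#' @export
filter_bands <- function(cube, keep_min = 430.4, keep_max = 991.3) {
  stop_if_not(inherits(cube, "hyper_cube"), "`cube` must be a hyper_cube")
  stop_if_not(keep_min < keep_max, "keep_min must be < keep_max")
  keep <- cube$wavelengths >= keep_min & cube$wavelengths <= keep_max
  if (!any(keep)) stop("no bands fall inside the requested interval",
                       call. = FALSE)
  hyper_cube(cube$data[, , keep, drop = FALSE], cube$wavelengths[keep],
             mask = cube$mask, pixel_size = cube$pixel_size, meta = cube$meta)
}

# rows x cols x bands array -> (n_pixels x bands) matrix, row-major pixel order
cube_to_matrix <- function(cube) {
  d <- dim(cube$data)
  matrix(cube$data, d[1L] * d[2L], d[3L])
}
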