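#' The hyperspectral vegetation index catalogue
#'
#' Fifteen narrow-band vegetation indices useful for discriminating
#' vegetation species: NDVI, BGI2, RDVI, TCARI, GOSAVI, TCARIOSAVI, MCARI2,
#' PRI, TDVI, CRI2, PSRI, GLI, RENDVI, SIPI and NLI. Each entry names the
#' reflectance wavelengths it needs (nm) and its arithmetic expression over
#' `r<lambda>` symbols. The catalogue ships as JSON under
#' `inst/extdata/vi_catalogue.json`.
#'
#' @return A list of index definitions, each a list with elements
#'   `abbreviation`, `name`, `wavelengths`, `expression`, in fixed catalogue
#'   order.
#' @export
vi_catalogue <- function() {
  path <- system.file("extdata", "vi_catalogue.json", package = "hyperobia",
                      mustWork = TRUE)
  jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
}

#' Nearest band lookup
#'
#' Returns the index of the band whose centre wavelength is closest to
#' `target`, ties broken toward the lower wavelength. Narrow-band index
#' formulas assume exact wavelength availability; with 2.8 nm sampling the
#' nearest-band approximation error is negligible.
#'
#' @param wavelengths band-centre wavelengths in nm.
#' @param target requested wavelength in nm.
#' @param tolerance maximum acceptable |lambda - target| in nm (default 15).
#' @return Integer band index.
#' @export
nearest_band <- function(wavelengths, target, tolerance = 15) {
  stop_if_not(length(wavelengths) > 0, "empty wavelength grid")
  d <- abs(wavelengths - target)
  idx <- which(d == min(d))[1L]  # wavelengths increasing: first = lower
  if (d[idx] > tolerance)
    stop(sprintf("band unavailable: no band within %g nm of %g nm",
                 tolerance, target), call. = FALSE)
  idx
}

#' Compute one vegetation index
#'
#' Evaluates an index definition on one spectrum or on a matrix of spectra
#' (rows = samples, columns = bands). Division by zero follows the policy:
#' `"nan"` propagates non-finite values, `"error"` aborts.
#'
#' @param reflectance numeric vector, or samples x bands matrix.
#' @param wavelengths band wavelengths (nm), length = number of bands.
#' @param definition one element of [vi_catalogue()].
#' @param tolerance nearest-band tolerance in nm.
#' @param zero_div `"nan"` (default) or `"error"`.
#' @return Numeric scalar (vector input) or vector with one value per row.
#' @export
compute_vi <- function(reflectance, wavelengths, definition, tolerance = 15,
                       zero_div = c("nan", "error")) {
  zero_div <- match.arg(zero_div)
  if (is.null(dim(reflectance)))
    reflectance <- matrix(reflectance, nrow = 1L)
  stop_if_not(ncol(reflectance) == length(wavelengths),
              "spectrum length must equal wavelength count")
  env <- new.env(parent = baseenv())
  for (wl in definition$wavelengths) {
    b <- tryCatch(nearest_band(wavelengths, wl, tolerance),
                  error = function(e)
                    stop(sprintf("%s: %s", definition$abbreviation,
                                 conditionMessage(e)), call. = FALSE))
    assign(paste0("r", wl), reflectance[, b], envir = env)
  }
  val <- eval(parse(text = definition$expression)[[1]], envir = env)
  if (zero_div == "error" && any(!is.finite(val)))
    stop(sprintf("%s: non-finite value (division by zero?)",
                 definition$abbreviation), call. = FALSE)
  as.numeric(val)
}

#' Compute the full vegetation index vector
#'
#' Evaluates all 15 catalogue indices on a spectrum (or per row of a matrix
#' of spectra), in fixed catalogue order.
#'
#' @inheritParams compute_vi
#' @return Named numeric vector of length 15 (vector input), or an n x 15
#'   matrix with index abbreviations as column names.
#' @examples
#' wl <- seq(430, 991, by = 3)
#' sp <- default_spectra(wl)[1, ]
#' compute_all_vis(sp, wl)
#' @export
compute_all_vis <- function(reflectance, wavelengths, tolerance = 15,
                            zero_div = c("nan", "error")) {
  zero_div <- match.arg(zero_div)
  vec_in <- is.null(dim(reflectance))
  if (vec_in) reflectance <- matrix(reflectance, nrow = 1L)
  cat_ <- vi_catalogue()
  out <- vapply(cat_, function(def)
    compute_vi(reflectance, wavelengths, def, tolerance, zero_div),
    numeric(nrow(reflectance)))
  if (nrow(reflectance) == 1L) out <- matrix(out, nrow = 1L)
  colnames(out) <- vapply(cat_, `[[`, "", "abbreviation")
  if (vec_in) out[1L, ] else out
}
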