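#' Read a hyperspectral cube from disk
#'
#' Supports two on-disk layouts: ENVI (flat binary data file plus a `.hdr`
#' text header; BSQ, BIL and BIP interleaves; the header must carry a
#' `wavelength` list) and multi-band TIFF (one page per band, 32-bit float)
#' with a wavelengths CSV sidecar named `<file>_wavelengths.csv` holding
#' columns `band_index, wavelength_nm`.
#'
#' @param path path to the ENVI data file or the TIFF file.
#' @param format `"envi"` or `"geotiff"`.
#' @return A [hyper_cube()]. Band order follows wavelength order.
#' @seealso [write_cube()]
#' @export
read_cube <- function(path, format = c("envi", "geotiff")) {
  format <- match.arg(format)
  stop_if_not(file.exists(path), sprintf("file not found: %s", path))
  if (format == "envi") read_cube_envi(path) else read_cube_tiff(path)
}

#' Write a hyperspectral cube to disk
#'
#' ENVI output is BSQ, 64-bit float, little-endian, so a write/read round
#' trip is bit-identical. TIFF output is one 32-bit float page per band with
#' the wavelengths CSV sidecar next to it.
#'
#' @param cube a [hyper_cube()].
#' @param path output path (data file for ENVI; the header is `<path>.hdr`).
#' @param format `"envi"` or `"geotiff"`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, format = c("envi", "geotiff")) {
  format <- match.arg(format)
  stop_if_not(inherits(cube, "hyper_cube"), "`cube` must be a hyper_cube")
  if (format == "envi") write_cube_envi(cube, path) else
    write_cube_tiff(cube, path)
  invisible(path)
}

# ---- ENVI ------------------------------------------------------------------

envi_header_path <- function(path) paste0(path, ".hdr")

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  stop_if_not(grepl("^ENVI", txt), "not an ENVI header (missing ENVI magic)")
  fields <- list()
  # match "key = value" where value is either a { } block or the rest of line
  pat <- "(?m)^\\s*([a-zA-Z ][a-zA-Z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  if (m[1] != -1) {
    starts <- m; lens <- attr(m, "match.length")
    for (i in seq_along(starts)) {
      piece <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
      key <- trimws(sub("=.*", "", piece))
      val <- trimws(sub("^[^=]*=", "", piece))
      fields[[tolower(key)]] <- val
    }
  }
  fields
}

envi_num_list <- function(val) {
  val <- gsub("[{}]", "", val)
  as.numeric(trimws(strsplit(val, ",")[[1]]))
}

read_cube_envi <- function(path) {
  hdr <- envi_header_path(path)
  stop_if_not(file.exists(hdr), sprintf("ENVI header not found: %s", hdr))
  h <- parse_envi_header(hdr)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(h))
  stop_if_not(length(miss) == 0,
              sprintf("ENVI header missing field(s): %s",
                      paste(miss, collapse = ", ")))
  if (is.null(h[["wavelength"]]))
    stop("wavelengths unavailable: ENVI header has no `wavelength` field",
         call. = FALSE)
  cols <- as.integer(h[["samples"]]); rows <- as.integer(h[["lines"]])
  bands <- as.integer(h[["bands"]])
  dtype <- as.integer(h[["data type"]])
  interleave <- tolower(trimws(h[["interleave"]]))
  wl <- envi_num_list(h[["wavelength"]])
  stop_if_not(length(wl) == bands,
              "wavelength list length does not match band count")
  reader <- switch(as.character(dtype),
    "1"  = list(what = "integer", size = 1, signed = FALSE),
    "2"  = list(what = "integer", size = 2, signed = TRUE),
    "3"  = list(what = "integer", size = 4, signed = TRUE),
    "4"  = list(what = "double",  size = 4, signed = TRUE),
    "5"  = list(what = "double",  size = 8, signed = TRUE),
    "12" = list(what = "integer", size = 2, signed = FALSE),
    stop(sprintf("unsupported ENVI data type %d", dtype), call. = FALSE))
  n <- rows * cols * bands
  endian <- if (!is.null(h[["byte order"]]) &&
                as.integer(h[["byte order"]]) == 1) "big" else "little"
  con <- file(path, "rb"); on.exit(close(con))
  raw <- readBin(con, reader$what, n = n, size = reader$size,
                 signed = reader$signed, endian = endian)
  stop_if_not(length(raw) == n, "ENVI data file shorter than header implies")
  arr <- switch(interleave,
    bsq = aperm(array(raw, c(cols, rows, bands)), c(2, 1, 3)),
    bil = aperm(array(raw, c(cols, bands, rows)), c(3, 1, 2)),
    bip = aperm(array(raw, c(bands, cols, rows)), c(3, 2, 1)),
    stop(sprintf("unsupported interleave '%s'", interleave), call. = FALSE))
  ord <- order(wl)
  hyper_cube(arr[, , ord, drop = FALSE], wl[ord])
}

write_cube_envi <- function(cube, path) {
  d <- dim(cube$data)
  con <- file(path, "wb")
  # BSQ: band-major, within band row-major scanlines (samples fastest)
  writeBin(as.numeric(aperm(cube$data, c(2, 1, 3))), con, size = 8,
           endian = "little")
  close(con)
  hdr <- c(
    "ENVI",
    "description = {hyperobia reflectance cube}",
    sprintf("samples = %d", d[2]), sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0", "file type = ENVI Standard",
    "data type = 5", "interleave = bsq", "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = {%s}",
            paste(format(cube$wavelengths, digits = 12, trim = TRUE,
                         scientific = FALSE), collapse = ", ")))
  writeLines(hdr, envi_header_path(path))
  path
}

# ---- TIFF ------------------------------------------------------------------

tiff_sidecar_path <- function(path) paste0(path, "_wavelengths.csv")

read_cube_tiff <- function(path) {
  sidecar <- tiff_sidecar_path(path)
  if (!file.exists(sidecar))
    stop(sprintf("wavelengths unavailable: sidecar %s not found", sidecar),
         call. = FALSE)
  wl_tab <- utils::read.csv(sidecar)
  stop_if_not(all(c("band_index", "wavelength_nm") %in% names(wl_tab)),
              "sidecar must have columns band_index, wavelength_nm")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  stop_if_not(nrow(wl_tab) == length(pages),
              "sidecar band count does not match TIFF page count")
  wl <- wl_tab$wavelength_nm[order(wl_tab$band_index)]
  arr <- array(unlist(pages, use.names = FALSE),
               c(dim(pages[[1]])[1:2], length(pages)))
  ord <- order(wl)
  hyper_cube(arr[, , ord, drop = FALSE], sort(wl))
}

write_cube_tiff <- function(cube, path) {
  pages <- lapply(seq_len(n_bands(cube)), function(b) cube$data[, , b])
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  utils::write.csv(data.frame(band_index = seq_along(cube$wavelengths),
                              wavelength_nm = cube$wavelengths),
                   tiff_sidecar_path(path), row.names = FALSE)
  path
}

# ---- label rasters ---------------------------------------------------------

#' Read or write an integer label raster
#'
#' Label rasters (class truth or segment maps) are single-band integer
#' images. `"geotiff"` stores 16-bit unsigned TIFF (IDs up to 65535);
#' `"envi"` stores 32-bit signed integers.
#'
#' @param labels integer matrix of class or object IDs (0 = background).
#' @param path file path.
#' @param format `"geotiff"` or `"envi"`.
#' @return `read_labels`: an integer matrix. `write_labels`: `path`,
#'   invisibly.
#' @export
write_labels <- function(labels, path, format = c("geotiff", "envi")) {
  format <- match.arg(format)
  stop_if_not(is.matrix(labels), "`labels` must be a matrix")
  stop_if_not(all(labels >= 0), "label IDs must be non-negative")
  if (format == "geotiff") {
    stop_if_not(max(labels) <= 65535L, "geotiff labels limited to 65535")
    tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16,
                    reduce = FALSE)
  } else {
    con <- file(path, "wb")
    writeBin(as.integer(t(labels)), con, size = 4, endian = "little")
    close(con)
    writeLines(c("ENVI", sprintf("samples = %d", ncol(labels)),
                 sprintf("lines = %d", nrow(labels)), "bands = 1",
                 "header offset = 0", "data type = 3", "interleave = bsq",
                 "byte order = 0"), envi_header_path(path))
  }
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path, format = c("geotiff", "envi")) {
  format <- match.arg(format)
  stop_if_not(file.exists(path), sprintf("file not found: %s", path))
  if (format == "geotiff") {
    m <- tiff::readTIFF(path, as.is = TRUE)
    storage.mode(m) <- "integer"
    m
  } else {
    h <- parse_envi_header(envi_header_path(path))
    cols <- as.integer(h[["samples"]]); rows <- as.integer(h[["lines"]])
    con <- file(path, "rb"); on.exit(close(con))
    v <- readBin(con, "integer", n = rows * cols, size = 4,
                 endian = "little")
    matrix(v, rows, cols, byrow = TRUE)
  }
}
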