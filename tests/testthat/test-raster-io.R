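make_cube <- function(rows = 4, cols = 5, bands = 6, seed = 1) {
  set.seed(seed)
  hyper_cube(array(runif(rows * cols * bands), c(rows, cols, bands)),
             seq(450, 900, length.out = bands))
}

test_that("ENVI write/read round trip is bit-identical", {
  cube <- make_cube()
  path <- tempfile(fileext = ".dat")
  write_cube(cube, path, "envi")
  back <- read_cube(path, "envi")
  expect_identical(back$data, cube$data)
  expect_equal(back$wavelengths, cube$wavelengths)
})

test_that("ENVI BIL and BIP interleaves read back the same cube", {
  cube <- make_cube(3, 4, 5)
  d <- dim(cube)
  for (il in c("bil", "bip")) {
    path <- tempfile(fileext = ".dat")
    perm <- if (il == "bil") c(2, 3, 1) else c(3, 2, 1)
    con <- file(path, "wb")
    writeBin(as.numeric(aperm(cube$data, perm)), con, size = 8,
             endian = "little")
    close(con)
    writeLines(c("ENVI",
                 sprintf("samples = %d", d[2]), sprintf("lines = %d", d[1]),
                 sprintf("bands = %d", d[3]), "header offset = 0",
                 "data type = 5", sprintf("interleave = %s", il),
                 "byte order = 0",
                 sprintf("wavelength = {%s}",
                         paste(cube$wavelengths, collapse = ", "))),
               paste0(path, ".hdr"))
    back <- read_cube(path, "envi")
    expect_identical(back$data, cube$data, label = il)
  }
})

test_that("an ENVI header without wavelengths is rejected", {
  cube <- make_cube()
  path <- tempfile(fileext = ".dat")
  write_cube(cube, path, "envi")
  hdr <- readLines(paste0(path, ".hdr"))
  writeLines(hdr[!grepl("^wavelength =", hdr)], paste0(path, ".hdr"))
  expect_error(read_cube(path, "envi"), "wavelengths unavailable")
})

test_that("ENVI reader reorders bands by wavelength", {
  cube <- make_cube(2, 2, 3)
  path <- tempfile(fileext = ".dat")
  write_cube(cube, path, "envi")
  hdr <- readLines(paste0(path, ".hdr"))
  # scramble: header claims the bands are stored in reversed wavelength order
  wl <- rev(cube$wavelengths)
  hdr[grepl("^wavelength =", hdr)] <-
    sprintf("wavelength = {%s}", paste(wl, collapse = ", "))
  writeLines(hdr, paste0(path, ".hdr"))
  back <- read_cube(path, "envi")
  expect_equal(back$wavelengths, sort(wl))
  expect_identical(back$data[, , 1], cube$data[, , 3])
})

test_that("TIFF cube round trip preserves values at float32 precision", {
  cube <- make_cube()
  path <- tempfile(fileext = ".tif")
  write_cube(cube, path, "geotiff")
  back <- read_cube(path, "geotiff")
  expect_equal(back$data, cube$data, tolerance = 1e-6)
  expect_equal(back$wavelengths, cube$wavelengths)
})

test_that("a TIFF cube without its wavelength sidecar is rejected", {
  cube <- make_cube()
  path <- tempfile(fileext = ".tif")
  write_cube(cube, path, "geotiff")
  file.remove(paste0(path, "_wavelengths.csv"))
  expect_error(read_cube(path, "geotiff"), "wavelengths unavailable")
})

test_that("label rasters round trip exactly in both formats", {
  labels <- matrix(sample(0:7, 30, replace = TRUE), 5, 6)
  p1 <- tempfile(fileext = ".tif")
  write_labels(labels, p1, "geotiff")
  expect_identical(read_labels(p1, "geotiff"), labels)
  p2 <- tempfile(fileext = ".dat")
  write_labels(labels, p2, "envi")
  expect_identical(read_labels(p2, "envi"), labels)
})

test_that("reading a missing file fails clearly", {
  expect_error(read_cube(tempfile(), "envi"), "not found")
  expect_error(read_labels(tempfile(), "geotiff"), "not found")
})
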