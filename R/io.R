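## Image and report I/O. Images travel as single-channel 32-bit float
## TIFFs; reading goes through the tiff package, while writing uses a
## minimal uncompressed float32 writer (the CRAN tiff writer stores
## float samples clamped to [0, 1], which cannot hold detector
## intensities).

#' Write a floating-point image as a 32-bit float TIFF
#'
#' Single strip, little-endian, uncompressed, SampleFormat = IEEE float.
#' Values are stored as float32 (the round trip is exact at float32
#' precision).
#'
#' @param image A [speckle_image()] or numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  m <- as_image_matrix(image)
  stopifnot(all(is.finite(m)))
  n <- nrow(m); p <- ncol(m)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)                     # little-endian
  writeBin(c(42L), con, size = 2, endian = "little")
  writeBin(8L, con, size = 4, endian = "little")     # IFD offset
  tags <- list(
    c(256L, 3L, 1L, p),          # ImageWidth
    c(257L, 3L, 1L, n),          # ImageLength
    c(258L, 3L, 1L, 32L),        # BitsPerSample
    c(259L, 3L, 1L, 1L),         # Compression: none
    c(262L, 3L, 1L, 1L),         # Photometric: BlackIsZero
    c(273L, 4L, 1L, 0L),         # StripOffsets (patched below)
    c(277L, 3L, 1L, 1L),         # SamplesPerPixel
    c(278L, 3L, 1L, n),          # RowsPerStrip
    c(279L, 4L, 1L, 4L * n * p), # StripByteCounts
    c(339L, 3L, 1L, 3L))         # SampleFormat: IEEE float
  n_tags <- length(tags)
  data_off <- 8L + 2L + n_tags * 12L + 4L
  tags[[6]][4] <- data_off
  writeBin(n_tags, con, size = 2, endian = "little")
  for (tg in tags) {
    writeBin(tg[1], con, size = 2, endian = "little")
    writeBin(tg[2], con, size = 2, endian = "little")
    writeBin(tg[3], con, size = 4, endian = "little")
    writeBin(tg[4], con, size = 4, endian = "little")
  }
  writeBin(0L, con, size = 4, endian = "little")     # next IFD: none
  ## row-major pixel order
  writeBin(as.vector(t(m)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an image from TIFF
#'
#' Float TIFFs are read as-is. Integer TIFFs are promoted to floating
#' point (with a warning), rescaled to their native integer range.
#'
#' @param path File path.
#' @param pixel_pitch Optional pixel pitch (um) recorded on the result.
#' @return A [speckle_image()].
#' @export
read_image <- function(path, pixel_pitch = NA_real_) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ## as.is = TRUE yields raw integer sample values (and errors on float
  ## storage, which we then read natively)
  m <- tryCatch(tiff::readTIFF(path, as.is = TRUE), error = function(e) NULL)
  if (is.null(m)) {
    m <- tiff::readTIFF(path)                  # float samples, as stored
  } else {
    warning("integer TIFF promoted to float")
    m <- m * 1.0
  }
  if (length(dim(m)) == 3L) m <- m[, , 1]
  speckle_image(m, pixel_pitch, meta = list(source = path))
}

#' Write an evaluation report
#'
#' Writes a metric table as CSV plus a JSON summary embedding the
#' condition (config, seed) and a version stamp, so reports regenerate
#' identically from their recorded seeds.
#'
#' @param table A data.frame (e.g. from [accuracy_sweep()]).
#' @param path_stem Output stem; writes `<stem>.csv` and `<stem>.json`.
#' @param extra Optional named list merged into the JSON summary.
#' @return Named list of the two paths, invisibly.
#' @export
write_report <- function(table, path_stem, extra = list()) {
  csv <- paste0(path_stem, ".csv")
  js <- paste0(path_stem, ".json")
  utils::write.csv(as.data.frame(table), csv, row.names = FALSE)
  summary <- c(list(
    package = "speckletrack",
    version = as.character(utils::packageVersion("speckletrack")),
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    condition = attr(table, "condition"),
    n_rows = nrow(table)), extra)
  jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(list(csv = csv, json = js))
}

#' Read a JSON report summary
#' @param path JSON path.
#' @return Named list.
#' @export
read_report <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Read a geometry/diffuser configuration from YAML
#'
#' Keys mirror the [imaging_geometry()] and [diffuser_spec()] argument
#' names under `geometry:` and `diffuser:` blocks; missing keys take the
#' defaults.
#'
#' @param path YAML file.
#' @return List with `geometry` and `diffuser` objects.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  geometry <- do.call(imaging_geometry, as.list(y$geometry))
  diffuser <- do.call(diffuser_spec, as.list(y$diffuser))
  list(geometry = geometry, diffuser = diffuser)
}
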