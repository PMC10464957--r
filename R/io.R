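#' Read an RGB raster image
#'
#' Reads TIFF (including GeoTIFF pixel data) and PNG. Images with more than
#' three bands keep bands 1-3 with a warning (alpha or extra bands dropped);
#' fewer than three bands is an error. The file's bit depth is recorded on the
#' returned object. GeoTIFF georeferencing tags are not parsed; use the
#' `geotransform` field of [rgb_image()] to carry such metadata through a run.
#'
#' @param path file path (`.tif`, `.tiff`, `.png`).
#' @return An [rgb_image()].
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(arr, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
  } else if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    info <- attr(arr, "info")
    bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
  } else {
    stopf("unsupported raster format: .%s", ext)
  }
  bits <- as.integer(bits[1])
  if (length(dim(arr)) == 2) stopf("%s has a single band; 3 required", path)
  nb <- dim(arr)[3]
  if (nb < 3) stopf("%s has %d bands; 3 required", path, nb)
  if (nb > 3) {
    warnf("%s has %d bands; keeping bands 1-3, dropping the rest", path, nb)
    arr <- arr[, , 1:3, drop = FALSE]
  }
  maxval <- 2^bits - 1
  rgb_image(round(arr * maxval), bits = bits)
}

#' Write an RGB raster image
#'
#' TIFF supports 8- and 16-bit output; PNG output is 8-bit only. Round trips
#' through either format are bit-identical at the recorded depth.
#'
#' @param image an [rgb_image()].
#' @param path destination (`.tif`, `.tiff`, `.png`).
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(image, path) {
  stopifnot(inherits(image, "rgb_image"))
  ext <- tolower(tools::file_ext(path))
  unit <- image$pixels / (2^image$bits - 1)
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(unit, path, bits.per.sample = image$bits)
  } else if (ext == "png") {
    if (image$bits != 8) stopf("PNG output supports 8-bit images only")
    png::writePNG(unit, path)
  } else {
    stopf("unsupported raster format: .%s", ext)
  }
  invisible(path)
}

#' Write and read classified label maps
#'
#' The label map is stored as a single-band 8-bit raster whose pixel values
#' are the class ids (0 = unclassified); this limits a file-backed scheme to
#' 255 classes. `preview_path`, if given, additionally writes a colourized
#' PNG using the scheme's display colours (unclassified pixels black).
#'
#' @param map a [class_map()].
#' @param path destination (`.tif`, `.tiff`, `.png`).
#' @param preview_path optional PNG path for the colourized preview.
#' @return `path`, invisibly.
#' @export
write_class_map <- function(map, path, preview_path = NULL) {
  stopifnot(inherits(map, "class_map"))
  sch <- map_scheme(map)
  if (nrow(sch) > 255) stopf("file-backed class maps support at most 255 classes")
  ext <- tolower(tools::file_ext(path))
  unit <- unclass(map) / 255
  attr(unit, "scheme") <- NULL
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(unit, path, bits.per.sample = 8L)
  } else if (ext == "png") {
    png::writePNG(unit, path)
  } else {
    stopf("unsupported raster format: .%s", ext)
  }
  if (!is.null(preview_path)) {
    pal <- grDevices::col2rgb(c("black", sch$colour)) / 255
    idx <- as.vector(map) + 1L
    arr <- array(0, c(nrow(map), ncol(map), 3))
    for (b in 1:3) arr[, , b] <- matrix(pal[b, idx], nrow(map), ncol(map))
    png::writePNG(arr, preview_path)
  }
  invisible(path)
}

#' @rdname write_class_map
#' @param scheme the [class_scheme()] the stored labels refer to.
#' @export
read_class_map <- function(path, scheme) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path) else
    if (ext == "png") png::readPNG(path) else
      stopf("unsupported raster format: .%s", ext)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  class_map(round(arr * 255), scheme)
}
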