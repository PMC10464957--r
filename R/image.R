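#' RGB raster image
#'
#' The classifier input: an `H x W x 3` array of band intensities on the
#' camera's native integer scale (`0 .. 2^bits - 1`). Both classifiers rescale
#' to unit range internally (see [as_unit_scale()]) so 8-bit and 16-bit
#' cameras behave identically.
#'
#' @param pixels numeric `H x W x 3` array, finite, within the declared depth.
#' @param bits bit depth, 8 or 16.
#' @param geotransform optional opaque georeferencing metadata, passed through
#'   untouched; the package does no georeferencing math.
#' @return An `rgb_image` object.
#' @export
rgb_image <- function(pixels, bits = 8L, geotransform = NULL) {
  bits <- as.integer(bits)
  if (!bits %in% c(8L, 16L)) stopf("bits must be 8 or 16")
  if (!is.array(pixels) || length(dim(pixels)) != 3) {
    stopf("pixels must be an H x W x 3 array")
  }
  if (dim(pixels)[3] != 3) stopf("exactly 3 bands required, got %d", dim(pixels)[3])
  if (dim(pixels)[1] < 1 || dim(pixels)[2] < 1) stopf("image must be at least 1 x 1")
  if (!all(is.finite(pixels))) stopf("non-finite pixel values")
  maxval <- 2^bits - 1
  if (min(pixels) < 0 || max(pixels) > maxval) {
    stopf("pixel values outside declared %d-bit range [0, %d]", bits, maxval)
  }
  # canonical storage: bare double array, no decoder attributes
  d <- dim(pixels)
  pixels <- as.double(pixels)
  dim(pixels) <- d
  structure(
    list(pixels = pixels, height = dim(pixels)[1], width = dim(pixels)[2],
         bits = bits, geotransform = geotransform),
    class = "rgb_image"
  )
}

#' Rescale an image to unit range
#'
#' @param image an [rgb_image()].
#' @return `H x W x 3` array in `[0, 1]` (`pixels / (2^bits - 1)`).
#' @export
as_unit_scale <- function(image) {
  stopifnot(inherits(image, "rgb_image"))
  image$pixels / (2^image$bits - 1)
}

# N x 3 matrix of unit-scale band values, rows in column-major pixel order so
# that linear_index(row, col, H) addresses the matching row.
pixel_matrix <- function(image) {
  u <- as_unit_scale(image)
  dim(u) <- c(image$height * image$width, 3L)
  colnames(u) <- c("r", "g", "b")
  u
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image> %d x %d, %d-bit%s\n", x$height, x$width, x$bits,
              if (is.null(x$geotransform)) "" else ", georeferenced"))
  invisible(x)
}

#' Classified label map
#'
#' The classifier output: an `H x W` integer matrix of class labels in
#' `0..K`, where `0` means unclassified and nonzero labels index the scheme.
#'
#' @param labels integer `H x W` matrix.
#' @param scheme the [class_scheme()] the labels refer to.
#' @return A `class_map` object (integer matrix with a `scheme` attribute).
#' @export
class_map <- function(labels, scheme) {
  stopifnot(inherits(scheme, "class_scheme"))
  if (!is.matrix(labels)) stopf("labels must be a matrix")
  lab <- labels
  storage.mode(lab) <- "integer"
  if (anyNA(lab)) stopf("labels must not contain NA")
  bad <- setdiff(unique(as.vector(lab)), c(0L, scheme$id))
  if (length(bad)) stopf("labels outside scheme: %s", paste(bad, collapse = ", "))
  structure(lab, scheme = scheme, class = c("class_map", "matrix", "array"))
}

map_scheme <- function(map) attr(map, "scheme")

#' @export
print.class_map <- function(x, ...) {
  sch <- map_scheme(x)
  cat(sprintf("<class_map> %d x %d, %d classes\n", nrow(x), ncol(x), nrow(sch)))
  tab <- table(factor(as.vector(x), levels = c(0L, sch$id),
                      labels = c("unclassified", sch$name)))
  print(tab)
  invisible(x)
}
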