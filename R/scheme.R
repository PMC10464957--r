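#' Endmember class scheme
#'
#' An ordered set of thematic classes ("endmembers") into which every image
#' pixel is classified. Label ids are contiguous `1..K`; label `0` is reserved
#' everywhere in the package for "unclassified". Display colours are used only
#' for map previews.
#'
#' @param names character vector of unique class names (`K >= 2`).
#' @param colours optional character vector of R colours, recycled from a
#'   default palette when missing.
#' @return A `class_scheme`: a data frame with columns `id`, `name`, `colour`.
#' @examples
#' class_scheme(c("water", "land"))
#' @export
class_scheme <- function(names, colours = NULL) {
  names <- as.character(names)
  if (length(names) < 2) stopf("a class scheme needs at least 2 classes")
  if (anyDuplicated(names)) stopf("class names must be unique")
  if (is.null(colours)) {
    colours <- grDevices::hcl.colors(length(names), palette = "Dark 3")
  }
  if (length(colours) != length(names)) {
    stopf("colours must match the number of classes")
  }
  # validate colours eagerly so previews cannot fail later
  grDevices::col2rgb(colours)
  out <- data.frame(
    id = seq_along(names), name = names, colour = colours,
    stringsAsFactors = FALSE
  )
  class(out) <- c("class_scheme", "data.frame")
  out
}

#' @export
print.class_scheme <- function(x, ...) {
  cat(sprintf("<class_scheme> %d classes (0 = unclassified)\n", nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

n_classes <- function(scheme) nrow(scheme)

# Accept a class name or id, return the integer id.
resolve_class <- function(scheme, class) {
  if (is.character(class)) {
    id <- scheme$id[match(class, scheme$name)]
  } else {
    id <- as.integer(class)
    id[!(id %in% scheme$id)] <- NA_integer_
  }
  if (anyNA(id)) stopf("unknown class: %s", paste(class[is.na(id)], collapse = ", "))
  id
}

#' Class schemes of the two Icelandic study lakes
#'
#' The six-endmember schemes used on the UAV spawning-ground imagery of lake
#' Thingvallavatn and lake Ellidavatn, with the display colours of the
#' published classification maps. In both lakes, spawning redds are dark
#' patches of gravel cleaned by Arctic charr females, contrasting with the
#' lighter undisturbed substrate.
#'
#' @return A [class_scheme()].
#' @export
thingvallavatn_scheme <- function() {
  class_scheme(
    c("spawning_redds", "vegetation", "underwater_rocks",
      "deep_water", "shoreline", "surface_rocks"),
    c("red", "green3", "cyan", "blue", "yellow", "purple")
  )
}

#' @rdname thingvallavatn_scheme
#' @export
ellidavatn_scheme <- function() {
  class_scheme(
    c("spawning_redds", "vegetation", "underwater_rocks",
      "aquatic_vegetation", "anthropogenic_feature", "sediment"),
    c("red", "green3", "cyan", "yellow", "white", "blue")
  )
}
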