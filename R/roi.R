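#' Regions of interest: labelled pixel sets
#'
#' Analyst-selected pixels of known class, used either to train a classifier
#' (`role = "training"`) or to score the classified map
#' (`role = "ground_truth"`). A training set and a ground-truth set over the
#' same image must not share any pixel; [build_confusion_matrix()] enforces
#' this when both are supplied.
#'
#' Coordinates are 1-based `(row, col)` with row 1 at the top, the native R
#' matrix convention. File formats carrying x/y are converted on read
#' (x = column, y = row).
#'
#' @param pixels data frame with columns `class_id` (or `class` names),
#'   `row`, `col`.
#' @param scheme the [class_scheme()].
#' @param role `"training"` or `"ground_truth"`.
#' @param dim image dimensions `c(H, W)` used for bounds validation.
#' @return A `roi_set` object.
#' @export
roi_set <- function(pixels, scheme, role = c("training", "ground_truth"), dim) {
  stopifnot(inherits(scheme, "class_scheme"))
  role <- match.arg(role)
  dim <- as.integer(dim)
  if (length(dim) != 2 || any(dim < 1)) stopf("dim must be c(H, W)")
  pixels <- as.data.frame(pixels)
  if ("class" %in% names(pixels) && !"class_id" %in% names(pixels)) {
    pixels$class_id <- resolve_class(scheme, pixels$class)
    pixels$class <- NULL
  }
  need <- c("class_id", "row", "col")
  if (!all(need %in% names(pixels))) {
    stopf("pixels must have columns class_id (or class), row, col")
  }
  pixels <- pixels[need]
  pixels$class_id <- resolve_class(scheme, pixels$class_id)
  pixels$row <- as.integer(pixels$row)
  pixels$col <- as.integer(pixels$col)
  if (nrow(pixels)) {
    oob <- pixels$row < 1 | pixels$row > dim[1] | pixels$col < 1 | pixels$col > dim[2]
    if (any(oob)) {
      stopf("%d ROI pixel(s) out of image bounds %d x %d (first: row %d, col %d)",
            sum(oob), dim[1], dim[2],
            pixels$row[which(oob)[1]], pixels$col[which(oob)[1]])
    }
    if (anyDuplicated(pixels)) stopf("duplicate pixel within a class")
  }
  structure(list(pixels = pixels, scheme = scheme, role = role, dim = dim),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> role=%s, image %d x %d\n", x$role, x$dim[1], x$dim[2]))
  print(roi_pixel_counts(x))
  invisible(x)
}

#' Per-class ROI pixel counts
#'
#' @param rois a [roi_set()].
#' @return named integer vector over all scheme classes.
#' @export
roi_pixel_counts <- function(rois) {
  stopifnot(inherits(rois, "roi_set"))
  counts <- table(factor(rois$pixels$class_id, levels = rois$scheme$id))
  stats::setNames(as.integer(counts), rois$scheme$name)
}

# (row, col) matrix for one class
roi_pixels <- function(rois, class_id) {
  p <- rois$pixels[rois$pixels$class_id == class_id, c("row", "col")]
  as.matrix(p)
}

#' Do two ROI sets share any pixel?
#'
#' @param a,b [roi_set()] objects over the same image.
#' @return TRUE if the pixel coordinate sets are disjoint.
#' @export
rois_disjoint <- function(a, b) {
  ka <- linear_index(a$pixels$row, a$pixels$col, a$dim[1])
  kb <- linear_index(b$pixels$row, b$pixels$col, b$dim[1])
  !any(ka %in% kb)
}

#' Read and write ROI files
#'
#' Two dialects are supported bidirectionally, chosen by file extension:
#' * CSV with columns `class,row,col` (class name or id; 1-based row/col);
#' * GeoJSON `FeatureCollection` whose features carry a `"class"` property and
#'   either `Polygon` geometry (rasterized by pixel-centre containment, with
#'   x = column and y = row in pixel units) or `Point`/`MultiPoint` geometry
#'   (pixels directly). [write_roi_set()] writes each pixel as a unit-square
#'   polygon so a GeoJSON round trip is exact.
#'
#' @param path file path ending in `.csv`, `.geojson` or `.json`.
#' @param scheme the [class_scheme()].
#' @param role passed to [roi_set()].
#' @param dim image dimensions `c(H, W)`.
#' @return [read_roi_set()] returns a [roi_set()]; [write_roi_set()] returns
#'   `path` invisibly.
#' @export
read_roi_set <- function(path, scheme, role = c("training", "ground_truth"), dim) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0) {
      df <- data.frame(class_id = integer(), row = integer(), col = integer())
    }
    return(roi_set(df, scheme, role, dim))
  }
  if (ext %in% c("geojson", "json")) {
    gj <- jsonlite::read_json(path)
    feats <- gj$features
    rows <- list()
    for (f in feats) {
      cls <- f$properties$class
      if (is.null(cls)) stopf("GeoJSON feature without a 'class' property")
      geom <- f$geometry
      pix <- switch(geom$type,
        Point = {
          xy <- unlist(geom$coordinates)
          cbind(row = round(xy[2]), col = round(xy[1]))
        },
        MultiPoint = {
          xy <- do.call(rbind, lapply(geom$coordinates, unlist))
          cbind(row = round(xy[, 2]), col = round(xy[, 1]))
        },
        Polygon = {
          ring <- do.call(rbind, lapply(geom$coordinates[[1]], unlist))
          rasterize_ring(ring, dim)
        },
        stopf("unsupported GeoJSON geometry: %s", geom$type)
      )
      if (nrow(pix)) {
        rows[[length(rows) + 1L]] <- data.frame(
          class = cls, row = pix[, "row"], col = pix[, "col"]
        )
      }
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(class_id = integer(), row = integer(), col = integer())
    df <- unique(df)
    return(roi_set(df, scheme, role, dim))
  }
  stopf("unsupported ROI format: .%s", ext)
}

# Pixel-centre containment of one polygon ring: a pixel (r, c) belongs to the
# polygon iff its centre, at x = c, y = r, lies inside the ring.
rasterize_ring <- function(ring, dim) {
  colnames(ring) <- c("x", "y")
  r0 <- max(1L, floor(min(ring[, "y"]))); r1 <- min(dim[1], ceiling(max(ring[, "y"])))
  c0 <- max(1L, floor(min(ring[, "x"]))); c1 <- min(dim[2], ceiling(max(ring[, "x"])))
  if (r0 > r1 || c0 > c1) return(cbind(row = integer(0), col = integer(0)))
  rs <- r0:r1
  cs <- c0:c1
  centres <- cbind(x = rep(cs, each = length(rs)), y = rep(rs, times = length(cs)))
  inside <- mgcv::in.out(ring, centres)
  cbind(row = centres[inside, "y"], col = centres[inside, "x"])
}

#' @rdname read_roi_set
#' @param rois a [roi_set()] to write.
#' @export
write_roi_set <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  ext <- tolower(tools::file_ext(path))
  p <- rois$pixels
  if (ext == "csv") {
    out <- data.frame(class = rois$scheme$name[p$class_id], row = p$row, col = p$col)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else if (ext %in% c("geojson", "json")) {
    feats <- lapply(seq_len(nrow(p)), function(i) {
      r <- p$row[i]; cc <- p$col[i]
      ring <- list(
        list(cc - 0.5, r - 0.5), list(cc + 0.5, r - 0.5),
        list(cc + 0.5, r + 0.5), list(cc - 0.5, r + 0.5),
        list(cc - 0.5, r - 0.5)
      )
      list(
        type = "Feature",
        properties = list(class = rois$scheme$name[p$class_id[i]]),
        geometry = list(type = "Polygon", coordinates = list(ring))
      )
    })
    jsonlite::write_json(
      list(type = "FeatureCollection", features = feats),
      path, auto_unbox = TRUE, digits = NA
    )
  } else {
    stopf("unsupported ROI format: .%s", ext)
  }
  invisible(path)
}
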