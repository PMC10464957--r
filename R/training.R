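#' Per-class spectral statistics from training ROIs
#'
#' Estimates, for every class in the scheme, the mean band vector and the
#' unbiased (n-1) sample covariance of the training pixels on the unit scale
#' (`[0, 1]`, see [as_unit_scale()]). These parameterize the Gaussian
#' maximum-likelihood discriminant. Classes whose covariance is (numerically)
#' singular — e.g. constant-colour training areas — are flagged; the
#' classifier regularizes them before inversion.
#'
#' @param image an [rgb_image()].
#' @param training_rois a [roi_set()] with `role = "training"` covering every
#'   scheme class with at least 4 pixels.
#' @return A `class_statistics` object: per class `n`, `mean` (3-vector),
#'   `cov` (3x3), `singular` flag.
#' @export
compute_class_statistics <- function(image, training_rois) {
  stopifnot(inherits(image, "rgb_image"), inherits(training_rois, "roi_set"))
  if (!all(training_rois$dim == c(image$height, image$width))) {
    stopf("ROI set was defined on a %d x %d image, got %d x %d",
          training_rois$dim[1], training_rois$dim[2], image$height, image$width)
  }
  X <- pixel_matrix(image)
  sch <- training_rois$scheme
  classes <- lapply(sch$id, function(k) {
    px <- roi_pixels(training_rois, k)
    if (nrow(px) == 0) stopf("class '%s' absent from training ROIs", sch$name[k])
    if (nrow(px) < 4) {
      stopf("class '%s' has %d training pixels; at least 4 required",
            sch$name[k], nrow(px))
    }
    v <- X[linear_index(px[, "row"], px[, "col"], image$height), , drop = FALSE]
    m <- colMeans(v)
    S <- stats::cov(v)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    list(id = k, name = sch$name[k], n = nrow(px), mean = m, cov = S,
         singular = min(ev) <= 1e-12)
  })
  structure(list(classes = classes, scheme = sch, scaling = "unit"),
            class = "class_statistics")
}

#' @export
print.class_statistics <- function(x, ...) {
  cat("<class_statistics> band scale: [0,1]\n")
  for (cl in x$classes) {
    cat(sprintf("  %d %-22s n=%-6d mean=(%.3f, %.3f, %.3f)%s\n",
                cl$id, cl$name, cl$n, cl$mean[1], cl$mean[2], cl$mean[3],
                if (cl$singular) " [singular cov]" else ""))
  }
  invisible(x)
}

#' Training-sample balance report
#'
#' Classifier training is sensitive to strongly unequal class sample sizes;
#' pixel counts per class should be similar. This report gives per-class
#' counts and the max/min ratio, and warns (without failing) when the ratio
#' exceeds 2.
#'
#' @param training_rois a [roi_set()].
#' @param ratio_warn warn when max/min count ratio exceeds this (default 2).
#' @return A list with `counts` (named integer vector), `ratio`, and
#'   `balanced` (logical).
#' @export
check_class_balance <- function(training_rois, ratio_warn = 2) {
  counts <- roi_pixel_counts(training_rois)
  if (sum(counts) == 0) stopf("empty ROI set")
  ratio <- if (min(counts) == 0) Inf else max(counts) / min(counts)
  balanced <- is.finite(ratio) && ratio <= ratio_warn
  if (!balanced) {
    warnf("unbalanced training samples: max/min pixel ratio %.2f > %.1f",
          ratio, ratio_warn)
  }
  list(counts = counts, ratio = ratio, balanced = balanced)
}

#' Serialize class statistics
#'
#' Plain-text YAML sidecar with per-class sample count, mean vector and
#' covariance entries, for inspection and reuse across runs.
#'
#' @param stats a `class_statistics` object.
#' @param path destination `.yml`/`.yaml` file.
#' @return `path` invisibly; [read_class_statistics()] returns the object.
#' @export
write_class_statistics <- function(stats, path) {
  stopifnot(inherits(stats, "class_statistics"))
  doc <- list(
    scaling = stats$scaling,
    classes = lapply(stats$classes, function(cl) {
      list(id = cl$id, name = cl$name, n = cl$n,
           mean = as.numeric(cl$mean), cov = as.numeric(cl$cov),
           singular = cl$singular)
    })
  )
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' @rdname write_class_statistics
#' @param scheme the [class_scheme()] the statistics refer to.
#' @export
read_class_statistics <- function(path, scheme) {
  doc <- yaml::read_yaml(path)
  classes <- lapply(doc$classes, function(cl) {
    list(id = as.integer(cl$id), name = cl$name, n = as.integer(cl$n),
         mean = as.numeric(cl$mean), cov = matrix(as.numeric(cl$cov), 3, 3),
         singular = isTRUE(cl$singular))
  })
  ids <- vapply(classes, `[[`, integer(1), "id")
  if (!setequal(ids, scheme$id)) stopf("statistics file does not match scheme")
  structure(list(classes = classes[order(ids)], scheme = scheme,
                 scaling = doc$scaling),
            class = "class_statistics")
}
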