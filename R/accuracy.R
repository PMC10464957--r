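#' Confusion matrix for thematic accuracy assessment
#'
#' A `(K+1) x K` integer matrix of pixel counts: rows are the classifier's
#' predictions, with row 1 ("unclassified") holding ground-truth pixels the
#' map left unclassified, and columns are the true classes of the ground-truth
#' ROI pixels.
#'
#' @param counts `(K+1) x K` matrix of nonnegative integer counts, rows
#'   ordered unclassified, class 1, ..., class K.
#' @param scheme the [class_scheme()].
#' @return A `confusion_matrix` object.
#' @export
confusion_matrix <- function(counts, scheme) {
  stopifnot(inherits(scheme, "class_scheme"))
  K <- n_classes(scheme)
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(K + 1, K))) {
    stopf("counts must be (K+1) x K = %d x %d", K + 1, K)
  }
  storage.mode(counts) <- "integer"
  if (anyNA(counts) || any(counts < 0)) stopf("counts must be nonnegative integers")
  dimnames(counts) <- list(predicted = c("unclassified", scheme$name),
                           true = scheme$name)
  structure(list(counts = counts, scheme = scheme), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d ground-truth pixels\n", sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Build the confusion matrix from a classified map and ground-truth ROIs
#'
#' Counts, for every ground-truth ROI pixel, its true class (column) against
#' the label the map assigned (row); map label 0 fills the unclassified row.
#' Ground-truth pixels must be disjoint from the training pixels, otherwise
#' the assessment would score the classifier on its own training data; supply
#' `training_rois` to enforce this.
#'
#' @param predicted_map a [class_map()].
#' @param ground_truth_rois a [roi_set()] with `role = "ground_truth"`,
#'   covering every scheme class.
#' @param training_rois optional [roi_set()]; overlap with the ground truth is
#'   an error.
#' @return A [confusion_matrix()].
#' @export
build_confusion_matrix <- function(predicted_map, ground_truth_rois,
                                   training_rois = NULL) {
  stopifnot(inherits(predicted_map, "class_map"),
            inherits(ground_truth_rois, "roi_set"))
  sch <- map_scheme(predicted_map)
  if (!all(ground_truth_rois$dim == dim(predicted_map))) {
    stopf("ground-truth ROIs and map dimensions differ")
  }
  if (!is.null(training_rois) && !rois_disjoint(ground_truth_rois, training_rois)) {
    stopf("ground-truth ROIs overlap the training ROIs")
  }
  counts <- roi_pixel_counts(ground_truth_rois)
  if (any(counts == 0)) {
    stopf("class '%s' absent from ground-truth ROIs", names(counts)[counts == 0][1])
  }
  p <- ground_truth_rois$pixels
  pred <- unclass(predicted_map)[linear_index(p$row, p$col, nrow(predicted_map))]
  K <- n_classes(sch)
  tab <- table(factor(pred, levels = 0:K), factor(p$class_id, levels = sch$id))
  confusion_matrix(matrix(as.integer(tab), K + 1, K), sch)
}

#' Accuracy metrics from a confusion matrix
#'
#' * Producer's accuracy (PA): the probability that a true pixel of the class
#'   is classified correctly — diagonal count over column total (complement of
#'   omission error).
#' * User's accuracy (UA): the probability that a pixel mapped as the class
#'   truly is that class — diagonal count over row total (complement of
#'   commission error).
#' * Overall accuracy (OA): correctly classified fraction of all ground-truth
#'   pixels, unclassified predictions included in the total.
#' * Kappa: chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with
#'   `p_o` the overall accuracy and `p_e = sum_c row_c * col_c / N^2` over the
#'   named classes (the unclassified row counts in `N` and has no matching
#'   column, so it contributes nothing to `p_e`). The statistic can be
#'   negative for worse-than-chance maps even though it is commonly read on a
#'   0-1 scale.
#'
#' A class with an empty column (PA) or row (UA) has an undefined metric:
#' `NA` is returned with a warning.
#'
#' @param cm a [confusion_matrix()].
#' @param class class name or id.
#' @return A fraction in `[0, 1]` (kappa in `[-1, 1]`).
#' @export
producer_accuracy <- function(cm, class) {
  stopifnot(inherits(cm, "confusion_matrix"))
  k <- resolve_class(cm$scheme, class)
  total <- sum(cm$counts[, k])
  if (total == 0) {
    warnf("class '%s' has no ground-truth pixels; PA undefined", cm$scheme$name[k])
    return(NA_real_)
  }
  cm$counts[k + 1, k] / total
}

#' @rdname producer_accuracy
#' @export
user_accuracy <- function(cm, class) {
  stopifnot(inherits(cm, "confusion_matrix"))
  k <- resolve_class(cm$scheme, class)
  total <- sum(cm$counts[k + 1, ])
  if (total == 0) {
    warnf("class '%s' was never predicted; UA undefined", cm$scheme$name[k])
    return(NA_real_)
  }
  cm$counts[k + 1, k] / total
}

#' @rdname producer_accuracy
#' @export
overall_accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  N <- sum(cm$counts)
  if (N == 0) stopf("empty confusion matrix")
  K <- n_classes(cm$scheme)
  sum(cm$counts[cbind(2:(K + 1), 1:K)]) / N
}

#' @rdname producer_accuracy
#' @export
kappa_coefficient <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  N <- sum(cm$counts)
  if (N == 0) stopf("empty confusion matrix")
  K <- n_classes(cm$scheme)
  po <- overall_accuracy(cm)
  row_tot <- rowSums(cm$counts)[2:(K + 1)]
  col_tot <- colSums(cm$counts)
  pe <- sum(row_tot * col_tot) / N^2
  if (abs(1 - pe) < .Machine$double.eps) stopf("degenerate matrix: expected agreement 1")
  (po - pe) / (1 - pe)
}

#' Full accuracy report
#'
#' Assembles overall accuracy, kappa and per-class producer's and user's
#' accuracy from a confusion matrix. Percentages are displayed half-up-rounded
#' at two decimals, kappa at two decimals; the stored fractions are exact.
#'
#' @param cm a [confusion_matrix()].
#' @return An `accuracy_report`: list with `overall_accuracy`, `kappa`,
#'   `per_class` (data frame of class, n_true, PA, UA fractions) and the
#'   scheme.
#' @export
accuracy_report <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  sch <- cm$scheme
  pa <- vapply(sch$id, function(k) suppressWarnings(producer_accuracy(cm, k)),
               numeric(1))
  ua <- vapply(sch$id, function(k) suppressWarnings(user_accuracy(cm, k)),
               numeric(1))
  per_class <- data.frame(
    class = sch$name,
    n_true = colSums(cm$counts),
    producer_accuracy = pa,
    user_accuracy = ua,
    row.names = NULL
  )
  structure(list(overall_accuracy = overall_accuracy(cm),
                 kappa = kappa_coefficient(cm),
                 per_class = per_class, scheme = sch),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> OA %.2f%%  kappa %.2f\n",
              round_half_up(100 * x$overall_accuracy), round_half_up(x$kappa)))
  df <- x$per_class
  df$producer_accuracy <- round_half_up(100 * df$producer_accuracy)
  df$user_accuracy <- round_half_up(100 * df$user_accuracy)
  names(df)[3:4] <- c("PA (%)", "UA (%)")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write accuracy artefacts
#'
#' `write_confusion_matrix()` writes the count matrix as CSV in the
#' predictions-as-rows orientation. `write_accuracy_report()` writes a
#' per-class CSV (fractions and display percentages) and, optionally, a
#' human-readable text summary.
#'
#' @param cm a [confusion_matrix()].
#' @param report an `accuracy_report`.
#' @param path destination CSV path.
#' @param text_path optional text summary path.
#' @return `path`, invisibly.
#' @export
write_confusion_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "confusion_matrix"))
  df <- data.frame(predicted = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_confusion_matrix
#' @export
write_accuracy_report <- function(report, path, text_path = NULL) {
  stopifnot(inherits(report, "accuracy_report"))
  df <- report$per_class
  df$pa_pct <- round_half_up(100 * df$producer_accuracy)
  df$ua_pct <- round_half_up(100 * df$user_accuracy)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(text_path)) {
    lines <- c(
      sprintf("Overall accuracy: %.2f%%", round_half_up(100 * report$overall_accuracy)),
      sprintf("Kappa coefficient: %.2f", round_half_up(report$kappa)),
      "",
      sprintf("%-24s %8s %8s", "class", "PA (%)", "UA (%)"),
      sprintf("%-24s %8.2f %8.2f", df$class, df$pa_pct, df$ua_pct)
    )
    writeLines(lines, text_path)
  }
  invisible(path)
}
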