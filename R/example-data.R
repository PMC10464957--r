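#' Read a confusion matrix from CSV
#'
#' Reads the predictions-as-rows CSV format written by
#' [write_confusion_matrix()]: a `predicted` column naming the rows
#' (`unclassified` first, then the classes in scheme order) followed by one
#' column of counts per true class.
#'
#' @param path CSV file path.
#' @param scheme optional [class_scheme()]; built from the column names when
#'   omitted.
#' @return A [confusion_matrix()].
#' @export
read_confusion_matrix <- function(path, scheme = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "predicted") stopf("first column must be 'predicted'")
  if (is.null(scheme)) scheme <- class_scheme(names(df)[-1])
  want <- c("unclassified", scheme$name)
  if (!identical(df$predicted, want)) {
    df <- df[match(want, df$predicted), ]
    if (anyNA(df$predicted)) stopf("prediction rows do not match the scheme")
  }
  confusion_matrix(as.matrix(df[, -1]), scheme)
}

#' Published error matrices of the two lake surveys
#'
#' The post-classification error matrices obtained on the UAV imagery of the
#' two Icelandic study lakes — lake Thingvallavatn (heterogeneous, contrasting
#' spawning grounds of Ólafsdráttur) and lake Ellidavatn (homogeneous, low
#' contrast) — for both classifiers. These bundled matrices are the exact
#' worked examples for the accuracy module: recomputing metrics from the raw
#' counts reproduces the reported producer's/user's accuracy, overall accuracy
#' and kappa of each survey at two-decimal rounding. (The full drone imagery
#' and analyst ROI choices behind these counts are not shipped; reproducing
#' the matrices themselves requires the original survey data.)
#'
#' @param lake `"thingvallavatn"` or `"ellidavatn"`.
#' @param classifier `"mlc"` (maximum likelihood) or `"nn"` (neural net).
#' @return A [confusion_matrix()] with the matching lake scheme.
#' @examples
#' cm <- example_error_matrix("thingvallavatn", "mlc")
#' accuracy_report(cm)
#' @export
example_error_matrix <- function(lake = c("thingvallavatn", "ellidavatn"),
                                 classifier = c("mlc", "nn")) {
  lake <- match.arg(lake)
  classifier <- match.arg(classifier)
  path <- system.file("extdata",
                      sprintf("error_matrix_%s_%s.csv", lake, classifier),
                      package = "reddmap", mustWork = TRUE)
  scheme <- if (lake == "thingvallavatn") thingvallavatn_scheme() else ellidavatn_scheme()
  read_confusion_matrix(path, scheme)
}
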