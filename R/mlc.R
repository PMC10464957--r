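#' Maximum-likelihood classifier configuration
#'
#' @param priors per-class prior probabilities summing to 1; `NULL` (default)
#'   means equal priors, so only the spectral evidence drives the decision.
#' @param probability_threshold optional minimum posterior probability in
#'   (0, 1); pixels whose best class falls below it are left unclassified
#'   (label 0). The default, `NULL`, classifies every pixel.
#' @param cov_regularization_eps relative ridge added to the diagonal of a
#'   singular class covariance before inversion: `eps * trace(cov) / 3`
#'   (or `eps` itself when the trace is zero, the constant-colour case).
#' @return An `mlc_config` object.
#' @export
mlc_config <- function(priors = NULL, probability_threshold = NULL,
                       cov_regularization_eps = 1e-6) {
  if (!is.null(priors)) {
    if (any(priors < 0) || abs(sum(priors) - 1) > 1e-8) {
      stopf("priors must be nonnegative and sum to 1")
    }
  }
  if (!is.null(probability_threshold)) {
    if (probability_threshold <= 0 || probability_threshold >= 1) {
      stopf("probability_threshold must lie in (0, 1)")
    }
  }
  if (cov_regularization_eps <= 0) stopf("cov_regularization_eps must be positive")
  structure(list(priors = priors, probability_threshold = probability_threshold,
                 cov_regularization_eps = cov_regularization_eps),
            class = "mlc_config")
}

# Ridge-regularize a covariance until it is Cholesky-decomposable, escalating
# the ridge tenfold if the first attempt still fails numerically.
regularize_cov <- function(S, eps) {
  ridge <- eps * mean(diag(S))
  if (ridge <= 0) ridge <- eps
  for (i in 1:20) {
    Si <- S + diag(ridge, 3)
    U <- tryCatch(chol(Si), error = function(e) NULL)
    if (!is.null(U)) return(list(chol = U, cov = Si))
    ridge <- ridge * 10
  }
  stopf("covariance could not be regularized")
}

#' Gaussian maximum-likelihood classification
#'
#' Assigns each pixel `x` (unit-scale band vector) to the class maximizing the
#' Gaussian discriminant
#' `g_c(x) = ln p_c - 1/2 ln|S_c| - 1/2 (x - m_c)' S_c^{-1} (x - m_c)`,
#' with `m_c`, `S_c` the class mean and covariance from
#' [compute_class_statistics()] and `p_c` the prior. With no probability
#' threshold (the default) every pixel receives a class; with a threshold,
#' pixels whose best-class posterior falls below it become unclassified.
#' Discriminant ties break to the lowest class id.
#'
#' @param image an [rgb_image()].
#' @param stats a `class_statistics` object covering every scheme class.
#' @param config an [mlc_config()].
#' @return A [class_map()] of the same dimensions as `image`.
#' @export
classify_maximum_likelihood <- function(image, stats, config = mlc_config()) {
  stopifnot(inherits(image, "rgb_image"), inherits(stats, "class_statistics"))
  sch <- stats$scheme
  K <- n_classes(sch)
  ids <- vapply(stats$classes, `[[`, integer(1), "id")
  if (!setequal(ids, sch$id)) stopf("statistics missing for some scheme classes")
  priors <- if (is.null(config$priors)) rep(1 / K, K) else config$priors
  if (length(priors) != K) stopf("priors must have one entry per class")

  X <- pixel_matrix(image)
  G <- matrix(NA_real_, nrow(X), K)
  for (cl in stats$classes) {
    S <- cl$cov
    reg <- if (cl$singular) regularize_cov(S, config$cov_regularization_eps)
    else tryCatch(list(chol = chol(S), cov = S),
                  error = function(e) regularize_cov(S, config$cov_regularization_eps))
    U <- reg$chol
    logdet <- 2 * sum(log(diag(U)))
    Z <- backsolve(U, t(X) - cl$mean, transpose = TRUE)
    d2 <- colSums(Z^2)
    G[, cl$id] <- log(priors[cl$id]) - 0.5 * logdet - 0.5 * d2
  }
  if (!all(is.finite(G))) stopf("non-finite discriminant values")
  lab <- max.col(G, ties.method = "first")
  if (!is.null(config$probability_threshold)) {
    gmax <- G[cbind(seq_len(nrow(G)), lab)]
    post <- 1 / rowSums(exp(G - gmax))   # posterior of the best class
    lab[post < config$probability_threshold] <- 0L
  }
  class_map(matrix(lab, image$height, image$width), sch)
}
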