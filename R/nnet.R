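#' Neural-network classifier configuration
#'
#' Configuration of the one-hidden-layer logistic backpropagation classifier.
#' The defaults are the settings used on the lake imagery: logistic
#' activation, training threshold contribution 0.9, training rate 0.2,
#' momentum 0.9, RMS exit criterion 0.1, one hidden layer, 1000 iterations.
#'
#' "Training threshold contribution" follows the ENVI-style reading: it scales
#' the gradient part of the bias ("threshold") weight updates, i.e. biases
#' learn at `threshold_contribution * training_rate` while interconnection
#' weights learn at `training_rate`.
#'
#' @param hidden_units width of the single hidden layer; `NULL` (default)
#'   means one unit per class.
#' @param training_rate gradient step size in (0, 1].
#' @param momentum fraction of the previous weight update carried over, in
#'   \[0, 1).
#' @param threshold_contribution multiplier on bias-update gradients, (0, 1].
#' @param rms_exit stop early once training RMS error falls to this value.
#' @param max_iterations maximum full-batch iterations (>= 1).
#' @param rng_seed seed for the uniform weight initialisation; training is
#'   fully deterministic given the seed.
#' @return An `nn_config` object.
#' @export
nn_config <- function(hidden_units = NULL, training_rate = 0.2, momentum = 0.9,
                      threshold_contribution = 0.9, rms_exit = 0.1,
                      max_iterations = 1000, rng_seed = 1) {
  if (!is.null(hidden_units) && hidden_units < 1) stopf("hidden_units must be >= 1")
  if (training_rate <= 0 || training_rate > 1) stopf("training_rate must be in (0, 1]")
  if (momentum < 0 || momentum >= 1) stopf("momentum must be in [0, 1)")
  if (threshold_contribution <= 0 || threshold_contribution > 1) {
    stopf("threshold_contribution must be in (0, 1]")
  }
  if (rms_exit <= 0) stopf("rms_exit must be positive")
  if (max_iterations < 1) stopf("max_iterations must be >= 1")
  structure(list(activation = "logistic", hidden_layers = 1L,
                 hidden_units = hidden_units, training_rate = training_rate,
                 momentum = momentum, threshold_contribution = threshold_contribution,
                 rms_exit = rms_exit, max_iterations = as.integer(max_iterations),
                 rng_seed = as.integer(rng_seed)),
            class = "nn_config")
}

logistic <- function(z) 1 / (1 + exp(-z))

# Forward pass through a trained model: X is an n x 3 unit-scale matrix.
# Returns hidden and output activations (n x hidden, n x K).
nn_forward <- function(model, X) {
  H <- logistic(sweep(X %*% model$W1, 2, model$b1, `+`))
  O <- logistic(sweep(H %*% model$W2, 2, model$b2, `+`))
  list(hidden = H, output = O)
}

#' Train the logistic neural-network classifier
#'
#' Full-batch gradient descent with momentum on the sum-of-squares error of a
#' 3-input, one-hidden-layer, K-output logistic network against one-hot class
#' targets. The gradient is averaged over training pixels so the training rate
#' is independent of sample size. Weight updates follow
#' `dw(t) = -rate * grad + momentum * dw(t-1)`, with bias gradients
#' additionally scaled by `threshold_contribution`. Training stops when the
#' RMS output error reaches `rms_exit` or after `max_iterations`, whichever
#' comes first; non-convergence returns the model with a warning.
#'
#' @param image an [rgb_image()].
#' @param training_rois a [roi_set()] covering every scheme class.
#' @param config an [nn_config()].
#' @return An `nn_model`: weight matrices `W1` (3 x hidden), `W2`
#'   (hidden x K), bias vectors `b1`, `b2`, per-iteration RMS `history`, the
#'   `config` and the class `scheme`.
#' @export
train_neural_net <- function(image, training_rois, config = nn_config()) {
  stopifnot(inherits(image, "rgb_image"), inherits(training_rois, "roi_set"))
  sch <- training_rois$scheme
  K <- n_classes(sch)
  counts <- roi_pixel_counts(training_rois)
  if (any(counts == 0)) {
    stopf("class '%s' absent from training ROIs", names(counts)[counts == 0][1])
  }
  Xall <- pixel_matrix(image)
  p <- training_rois$pixels
  X <- Xall[linear_index(p$row, p$col, image$height), , drop = FALSE]
  n <- nrow(X)
  Tg <- matrix(0, n, K)
  Tg[cbind(seq_len(n), p$class_id)] <- 1

  nh <- if (is.null(config$hidden_units)) K else as.integer(config$hidden_units)
  init <- with_local_seed(config$rng_seed, {
    list(W1 = matrix(stats::runif(3 * nh, -0.05, 0.05), 3, nh),
         b1 = stats::runif(nh, -0.05, 0.05),
         W2 = matrix(stats::runif(nh * K, -0.05, 0.05), nh, K),
         b2 = stats::runif(K, -0.05, 0.05))
  })
  W1 <- init$W1; b1 <- init$b1; W2 <- init$W2; b2 <- init$b2
  dW1 <- matrix(0, 3, nh); db1 <- numeric(nh)
  dW2 <- matrix(0, nh, K); db2 <- numeric(K)
  rate <- config$training_rate; mom <- config$momentum
  tc <- config$threshold_contribution
  history <- numeric(config$max_iterations)
  converged <- FALSE

  for (it in seq_len(config$max_iterations)) {
    H <- logistic(sweep(X %*% W1, 2, b1, `+`))
    O <- logistic(sweep(H %*% W2, 2, b2, `+`))
    err <- O - Tg
    history[it] <- sqrt(mean(err^2))
    if (history[it] <= config$rms_exit) {
      history <- history[seq_len(it)]
      converged <- TRUE
      break
    }
    d2 <- err * O * (1 - O) / n
    d1 <- (d2 %*% t(W2)) * H * (1 - H)
    dW2 <- -rate * crossprod(H, d2) + mom * dW2
    db2 <- -rate * tc * colSums(d2) + mom * db2
    dW1 <- -rate * crossprod(X, d1) + mom * dW1
    db1 <- -rate * tc * colSums(d1) + mom * db1
    W2 <- W2 + dW2; b2 <- b2 + db2
    W1 <- W1 + dW1; b1 <- b1 + db1
  }
  if (!converged) {
    warnf("neural net did not reach RMS %.3g within %d iterations (final RMS %.4f)",
          config$rms_exit, config$max_iterations, history[length(history)])
  }
  structure(list(W1 = unname(W1), b1 = unname(b1), W2 = unname(W2),
                 b2 = unname(b2), history = history,
                 converged = converged, config = config, scheme = sch),
            class = "nn_model")
}

#' @export
print.nn_model <- function(x, ...) {
  cat(sprintf("<nn_model> 3 -> %d -> %d logistic; %d iterations, final RMS %.4f%s\n",
              ncol(x$W1), ncol(x$W2), length(x$history),
              x$history[length(x$history)],
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Classify an image with a trained neural network
#'
#' Per-pixel argmax over the K output activations; ties break to the lowest
#' class id. Every pixel receives a class (label 0 never occurs).
#'
#' @param model an `nn_model` from [train_neural_net()].
#' @param image an [rgb_image()].
#' @return A [class_map()].
#' @export
classify_neural_net <- function(model, image) {
  stopifnot(inherits(model, "nn_model"), inherits(image, "rgb_image"))
  X <- pixel_matrix(image)
  if (ncol(X) != nrow(model$W1)) stopf("model/image band mismatch")
  O <- nn_forward(model, X)$output
  lab <- max.col(O, ties.method = "first")
  class_map(matrix(lab, image$height, image$width), model$scheme)
}

#' Save and reload a trained network
#'
#' Plain-text JSON holding the weights at full printed double precision
#' together with the configuration (including the RNG seed). Reloaded weights
#' agree to within one unit in the last place, so a reloaded model classifies
#' identically except on exactly tied activations.
#'
#' @param model an `nn_model`.
#' @param path destination `.json` file.
#' @return `path` invisibly; [read_nn_model()] returns the model.
#' @export
write_nn_model <- function(model, path) {
  stopifnot(inherits(model, "nn_model"))
  doc <- list(
    hidden = ncol(model$W1), outputs = ncol(model$W2),
    W1 = as.numeric(model$W1), b1 = as.numeric(model$b1),
    W2 = as.numeric(model$W2), b2 = as.numeric(model$b2),
    history = model$history, converged = model$converged,
    config = unclass(model$config),
    scheme = list(name = model$scheme$name, colour = model$scheme$colour)
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_nn_model
#' @export
read_nn_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- doc$config
  hu <- cfg$hidden_units
  if (length(hu) != 1 || is.na(hu)) hu <- NULL   # JSON null round trip
  config <- nn_config(
    hidden_units = hu,
    training_rate = cfg$training_rate, momentum = cfg$momentum,
    threshold_contribution = cfg$threshold_contribution,
    rms_exit = cfg$rms_exit, max_iterations = cfg$max_iterations,
    rng_seed = cfg$rng_seed
  )
  nh <- as.integer(doc$hidden); K <- as.integer(doc$outputs)
  structure(list(W1 = matrix(as.numeric(doc$W1), 3, nh),
                 b1 = as.numeric(doc$b1),
                 W2 = matrix(as.numeric(doc$W2), nh, K),
                 b2 = as.numeric(doc$b2), history = as.numeric(doc$history),
                 converged = isTRUE(doc$converged), config = config,
                 scheme = class_scheme(doc$scheme$name, doc$scheme$colour)),
            class = "nn_model")
}
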