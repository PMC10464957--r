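#' Pipeline configuration
#'
#' One reproducible run of the full method: obtain an image with training and
#' ground-truth ROIs (either a synthetic scene or files on disk), estimate
#' class statistics, classify every pixel, assess accuracy, apply the
#' post-classification chain, and assess again. Accuracy is always reported
#' both before and after post-classification, because the method's claims are
#' before/after comparisons.
#'
#' @param scene a [scene_config()] to simulate inputs, or `NULL` to read files.
#' @param image_path,training_roi_path,ground_truth_roi_path input files, used
#'   when `scene` is `NULL`.
#' @param scheme the [class_scheme()] for file-based inputs.
#' @param classifier `"mlc"` or `"nn"`.
#' @param mlc an [mlc_config()].
#' @param nn an [nn_config()].
#' @param post a [postclass_config()].
#' @param seed run seed; also seeds the neural net unless `nn` overrides it.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(scene = NULL, image_path = NULL,
                            training_roi_path = NULL,
                            ground_truth_roi_path = NULL, scheme = NULL,
                            classifier = c("mlc", "nn"),
                            mlc = mlc_config(), nn = NULL,
                            post = postclass_config(), seed = 1) {
  classifier <- match.arg(classifier)
  if (is.null(scene)) {
    paths <- c(image_path, training_roi_path, ground_truth_roi_path)
    if (length(paths) != 3) {
      stopf("either a scene config or all three input paths are required")
    }
    missing <- paths[!file.exists(paths)]
    if (length(missing)) stopf("missing input file(s): %s",
                               paste(missing, collapse = ", "))
    if (is.null(scheme)) stopf("a class scheme is required for file inputs")
  } else {
    stopifnot(inherits(scene, "scene_config"))
  }
  if (is.null(nn)) nn <- nn_config(rng_seed = seed)
  structure(list(scene = scene, image_path = image_path,
                 training_roi_path = training_roi_path,
                 ground_truth_roi_path = ground_truth_roi_path,
                 scheme = scheme, classifier = classifier, mlc = mlc, nn = nn,
                 post = post, seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full redd-mapping pipeline
#'
#' Executes simulate/load -> train -> classify -> assess -> postprocess ->
#' assess in order and writes all artefacts to `out_dir`: class maps before
#' and after post-classification (TIFF + colour previews), both confusion
#' matrices and accuracy reports (CSV/text), a per-class before/after
#' comparison table, and a machine-readable run manifest (configuration,
#' package version, seed, per-stage timings, per-operator changed-pixel
#' counts). Outputs of completed stages are retained if a later stage fails.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if needed.
#' @param verbose message stage progress.
#' @return Invisibly, a list with the pre/post [class_map()]s, both
#'   `accuracy_report`s, the comparison data frame and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  say <- function(...) if (verbose) message(sprintf(...))

  t0 <- tic()
  inputs <- run_stage("inputs", {
    if (!is.null(config$scene)) {
      generate_scene(config$scene)
    } else {
      img <- read_rgb_image(config$image_path)
      d <- c(img$height, img$width)
      list(image = img,
           truth = NULL,
           training = read_roi_set(config$training_roi_path, config$scheme,
                                   "training", d),
           ground_truth = read_roi_set(config$ground_truth_roi_path,
                                       config$scheme, "ground_truth", d))
    }
  })
  timings["inputs"] <- tic() - t0
  say("inputs ready (%.2fs)", timings["inputs"])

  t0 <- tic()
  stats <- run_stage("training", {
    balance <- check_class_balance(inputs$training)
    s <- compute_class_statistics(inputs$image, inputs$training)
    write_class_statistics(s, file.path(out_dir, "class_statistics.yml"))
    attr(s, "balance") <- balance
    s
  })
  timings["training"] <- tic() - t0

  t0 <- tic()
  pre_map <- run_stage("classify", {
    if (config$classifier == "mlc") {
      classify_maximum_likelihood(inputs$image, stats, config$mlc)
    } else {
      model <- train_neural_net(inputs$image, inputs$training, config$nn)
      write_nn_model(model, file.path(out_dir, "nn_model.json"))
      classify_neural_net(model, inputs$image)
    }
  })
  timings["classify"] <- tic() - t0
  say("classified (%.2fs)", timings["classify"])
  write_class_map(pre_map, file.path(out_dir, "classified_pre.tif"),
                  preview_path = file.path(out_dir, "classified_pre.png"))

  t0 <- tic()
  pre_cm <- run_stage("assess_pre", {
    build_confusion_matrix(pre_map, inputs$ground_truth, inputs$training)
  })
  pre_report <- accuracy_report(pre_cm)
  timings["assess_pre"] <- tic() - t0
  write_confusion_matrix(pre_cm, file.path(out_dir, "confusion_pre.csv"))
  write_accuracy_report(pre_report, file.path(out_dir, "accuracy_pre.csv"),
                        file.path(out_dir, "accuracy_pre.txt"))

  t0 <- tic()
  post_map <- run_stage("postprocess", {
    apply_postclassification(pre_map, config$post, verbose = verbose)
  })
  timings["postprocess"] <- tic() - t0
  changes <- attr(post_map, "changes")
  write_class_map(post_map, file.path(out_dir, "classified_post.tif"),
                  preview_path = file.path(out_dir, "classified_post.png"))

  t0 <- tic()
  post_cm <- run_stage("assess_post", {
    build_confusion_matrix(post_map, inputs$ground_truth, inputs$training)
  })
  post_report <- accuracy_report(post_cm)
  timings["assess_post"] <- tic() - t0
  write_confusion_matrix(post_cm, file.path(out_dir, "confusion_post.csv"))
  write_accuracy_report(post_report, file.path(out_dir, "accuracy_post.csv"),
                        file.path(out_dir, "accuracy_post.txt"))

  comparison <- data.frame(
    class = pre_report$per_class$class,
    pa_pre = round_half_up(100 * pre_report$per_class$producer_accuracy),
    pa_post = round_half_up(100 * post_report$per_class$producer_accuracy),
    ua_pre = round_half_up(100 * pre_report$per_class$user_accuracy),
    ua_post = round_half_up(100 * post_report$per_class$user_accuracy)
  )
  comparison$pa_delta <- comparison$pa_post - comparison$pa_pre
  comparison$ua_delta <- comparison$ua_post - comparison$ua_pre
  utils::write.csv(comparison, file.path(out_dir, "accuracy_comparison.csv"),
                   row.names = FALSE, quote = FALSE)

  manifest <- list(
    package = "reddmap",
    version = as.character(utils::packageVersion("reddmap")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    classifier = config$classifier,
    config = serialize_config(config),
    overall_accuracy_pre = pre_report$overall_accuracy,
    overall_accuracy_post = post_report$overall_accuracy,
    kappa_pre = pre_report$kappa,
    kappa_post = post_report$kappa,
    changed_pixels = as.list(changes),
    timings_sec = as.list(round(timings, 3))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("OA %.2f%% -> %.2f%%", 100 * pre_report$overall_accuracy,
      100 * post_report$overall_accuracy)

  invisible(list(pre_map = pre_map, post_map = post_map,
                 pre_report = pre_report, post_report = post_report,
                 pre_cm = pre_cm, post_cm = post_cm,
                 comparison = comparison, out_dir = out_dir))
}

# JSON-serializable view of a pipeline config (drops matrices to vectors).
serialize_config <- function(config) {
  sc <- config$scene
  list(
    scene = if (is.null(sc)) NULL else {
      s <- unclass(sc)
      s$colour_means <- as.numeric(s$colour_means)
      s
    },
    image_path = config$image_path,
    training_roi_path = config$training_roi_path,
    ground_truth_roi_path = config$ground_truth_roi_path,
    classifier = config$classifier,
    mlc = unclass(config$mlc),
    nn = unclass(config$nn),
    post = unclass(config$post),
    seed = config$seed
  )
}
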