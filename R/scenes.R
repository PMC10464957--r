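#' Synthetic lake-scene configuration
#'
#' Parameters of the seeded scene generator that emulates the structure of a
#' subarctic lake spawning ground seen from a drone at survey altitude: from
#' the top of the frame, a vegetated land band, a pale shoreline band with
#' scattered yellow-brown surface rocks, a shallow-water band of light
#' grey-cyan underwater rocks carrying the dark irregular spawning-redd
#' blobs, and a dark-blue deep-water band. Redds are unions of jittered discs,
#' mimicking the small, irregular, loosely connected pixel groups the real
#' class forms; every pixel's colour is drawn from its class's Gaussian colour
#' model plus isotropic sensor noise.
#'
#' The default colour means are plausible stand-ins reproducing the contrast
#' structure of the real scenes (dark redds against lighter substrate), not
#' measured reflectances.
#'
#' @param height,width scene size in pixels.
#' @param seed RNG seed (mandatory; generation is pure given the config).
#' @param band_fractions named fractions of image height for the four zones,
#'   in top-to-bottom order `land`, `shoreline`, `shallow`, `deep`; must sum
#'   to 1.
#' @param colour_means `K x 3` matrix of class mean RGB on the unit scale,
#'   rows in scheme order.
#' @param colour_sd per-class standard deviation of the class colour model
#'   (isotropic; recycled to K).
#' @param noise_sd additional per-pixel sensor noise sd on the unit scale.
#' @param redd_blobs,redd_radius,redd_irregularity number of redd blobs, the
#'   range of their base radius in pixels, and the disc-jitter fraction
#'   controlling boundary irregularity.
#' @param rock_blobs,rock_radius surface-rock blobs scattered in the
#'   shoreline band.
#' @param roi_train_pixels,roi_truth_pixels pixels sampled per class for the
#'   training and ground-truth ROI sets (disjoint by construction, drawn from
#'   class interiors one pixel away from class borders).
#' @return A `scene_config` object.
#' @export
scene_config <- function(height = 512, width = 512, seed,
                         band_fractions = c(land = 0.18, shoreline = 0.14,
                                            shallow = 0.43, deep = 0.25),
                         colour_means = default_scene_colours(),
                         colour_sd = 0.02,
                         noise_sd = 0.02,
                         redd_blobs = 40, redd_radius = c(5, 10),
                         redd_irregularity = 0.4,
                         rock_blobs = 50, rock_radius = c(3, 7),
                         roi_train_pixels = 975, roi_truth_pixels = 1000) {
  if (missing(seed)) stopf("a seed is mandatory")
  if (height < 32 || width < 32) stopf("scene must be at least 32 x 32")
  if (abs(sum(band_fractions) - 1) > 1e-8) stopf("band_fractions must sum to 1")
  if (!identical(names(band_fractions), c("land", "shoreline", "shallow", "deep"))) {
    stopf("band_fractions must be named land, shoreline, shallow, deep")
  }
  if (any(band_fractions <= 0)) stopf("band fractions must be positive")
  colour_means <- as.matrix(colour_means)
  if (ncol(colour_means) != 3) stopf("colour_means must have 3 columns")
  if (any(colour_means < 0 | colour_means > 1)) stopf("colour means must be in [0, 1]")
  if (any(colour_sd < 0) || noise_sd < 0) stopf("noise parameters must be >= 0")
  if (any(redd_radius <= 0) || any(rock_radius <= 0)) stopf("radius ranges must be positive")
  if (redd_irregularity < 0 || redd_irregularity > 1) {
    stopf("redd_irregularity must be in [0, 1]")
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 seed = as.integer(seed), band_fractions = band_fractions,
                 colour_means = colour_means,
                 colour_sd = rep_len(colour_sd, nrow(colour_means)),
                 noise_sd = noise_sd,
                 redd_blobs = as.integer(redd_blobs),
                 redd_radius = sort(redd_radius),
                 redd_irregularity = redd_irregularity,
                 rock_blobs = as.integer(rock_blobs),
                 rock_radius = sort(rock_radius),
                 roi_train_pixels = as.integer(roi_train_pixels),
                 roi_truth_pixels = as.integer(roi_truth_pixels)),
            class = "scene_config")
}

#' @rdname scene_config
#' @export
default_scene_colours <- function() {
  m <- rbind(
    spawning_redds   = c(0.25, 0.24, 0.22),  # dark cleaned gravel
    vegetation       = c(0.30, 0.55, 0.25),
    underwater_rocks = c(0.62, 0.70, 0.72),  # light grey-cyan substrate
    deep_water       = c(0.08, 0.12, 0.35),
    shoreline        = c(0.85, 0.82, 0.75),  # lightest class
    surface_rocks    = c(0.65, 0.55, 0.35)
  )
  colnames(m) <- c("r", "g", "b")
  m
}

# Stamp a union of jittered discs (an irregular blob) of label `lab` onto
# `truth`, restricted to rows [rmin, rmax].
stamp_blob <- function(truth, r0, c0, radius, irregularity, lab, rmin, rmax) {
  n_sub <- 6L
  jit <- irregularity * radius
  rr <- r0 + stats::runif(n_sub, -jit, jit)
  cc <- c0 + stats::runif(n_sub, -jit, jit)
  rad <- radius * stats::runif(n_sub, 0.5, 0.85)
  rows <- max(rmin, floor(min(rr - rad))):min(rmax, ceiling(max(rr + rad)))
  cols <- max(1, floor(min(cc - rad))):min(ncol(truth), ceiling(max(cc + rad)))
  if (!length(rows) || !length(cols)) return(truth)
  rg <- matrix(rows, length(rows), length(cols))
  cg <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  inside <- matrix(FALSE, length(rows), length(cols))
  for (k in seq_len(n_sub)) {
    inside <- inside | ((rg - rr[k])^2 + (cg - cc[k])^2 <= rad[k]^2)
  }
  # the central disc keeps the blob connected
  inside <- inside | ((rg - r0)^2 + (cg - c0)^2 <= (0.6 * radius)^2)
  truth[rows, cols][inside] <- lab
  truth
}

# Interior pixels of each class: 4-neighbours all share the label (1-pixel
# stratification away from class borders, mimicking interior training areas).
interior_mask <- function(truth) {
  same <- function(dr, dc) shift_matrix(truth, dr, dc, fill = -1L) == truth
  same(1, 0) & same(-1, 0) & same(0, 1) & same(0, -1)
}

#' Generate a synthetic lake scene
#'
#' Lays out the four zone bands, scatters surface-rock blobs in the shoreline
#' band and dark irregular redd blobs in the shallow band, assigns every pixel
#' its true class, draws pixel colours from the class colour models plus
#' sensor noise (quantized to 8 bits), and samples pixel-disjoint training and
#' ground-truth ROI sets from class interiors. Fully reproducible for a given
#' config (which includes the seed).
#'
#' @param config a [scene_config()].
#' @return A list with elements `image` ([rgb_image()]), `truth`
#'   ([class_map()]), `training` and `ground_truth` ([roi_set()]s), and
#'   `config`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  sch <- thingvallavatn_scheme()
  h <- config$height; w <- config$width
  with_local_seed(config$seed, {
    bounds <- round(cumsum(config$band_fractions) * h)
    land_end <- bounds[1]; shore_end <- bounds[2]; shallow_end <- bounds[3]

    truth <- matrix(0L, h, w)
    truth[1:land_end, ] <- 2L                                  # vegetation
    truth[(land_end + 1):shore_end, ] <- 5L                    # shoreline
    truth[(shore_end + 1):shallow_end, ] <- 3L                 # underwater rocks
    truth[(shallow_end + 1):h, ] <- 4L                         # deep water

    for (i in seq_len(config$rock_blobs)) {                    # surface rocks
      rad <- stats::runif(1, config$rock_radius[1], config$rock_radius[2])
      r0 <- stats::runif(1, land_end + 1, shore_end)
      c0 <- stats::runif(1, 1, w)
      truth <- stamp_blob(truth, r0, c0, rad, config$redd_irregularity, 6L,
                          land_end + 1L, shore_end)
    }
    margin <- config$redd_radius[2] + 2
    if (shore_end + margin >= shallow_end - margin || 2 * margin >= w) {
      stopf("infeasible layout: shallow band too thin for redd radius %g",
            config$redd_radius[2])
    }
    for (i in seq_len(config$redd_blobs)) {                    # spawning redds
      rad <- stats::runif(1, config$redd_radius[1], config$redd_radius[2])
      r0 <- stats::runif(1, shore_end + margin, shallow_end - margin)
      c0 <- stats::runif(1, margin, w - margin)
      truth <- stamp_blob(truth, r0, c0, rad, config$redd_irregularity, 1L,
                          shore_end + 1L, shallow_end)
    }

    mu <- config$colour_means
    arr <- array(0, c(h, w, 3))
    idx <- as.vector(truth)
    for (b in 1:3) {
      v <- mu[idx, b] + stats::rnorm(h * w, 0, config$colour_sd[idx]) +
        stats::rnorm(h * w, 0, config$noise_sd)
      arr[, , b] <- matrix(pmin(pmax(v, 0), 1), h, w)
    }
    image <- rgb_image(round(arr * 255), bits = 8L)

    interior <- interior_mask(truth)
    need <- config$roi_train_pixels + config$roi_truth_pixels
    pick <- function(k) {
      avail <- which(truth == k & interior)
      if (length(avail) < need) {
        stopf("class '%s' supplies %d interior pixels; %d requested",
              sch$name[k], length(avail), need)
      }
      sel <- sample(avail, need)
      list(train = sel[seq_len(config$roi_train_pixels)],
           truth = sel[config$roi_train_pixels + seq_len(config$roi_truth_pixels)])
    }
    sel <- lapply(sch$id, pick)
    as_df <- function(which) {
      do.call(rbind, lapply(sch$id, function(k) {
        lin <- sel[[k]][[which]]
        data.frame(class_id = k, row = (lin - 1L) %% h + 1L,
                   col = (lin - 1L) %/% h + 1L)
      }))
    }
    list(image = image,
         truth = class_map(truth, sch),
         training = roi_set(as_df("train"), sch, "training", c(h, w)),
         ground_truth = roi_set(as_df("truth"), sch, "ground_truth", c(h, w)),
         config = config)
  })
}

#' Corrupt a label map with classification noise
#'
#' Flips each pixel independently with probability `rate` to a uniformly
#' random other class, creating the salt-and-pepper "spurious pixel" pattern
#' the post-classification operators are designed to remove.
#'
#' @param truth_map a [class_map()].
#' @param rate flip probability per pixel in `[0, 1)`.
#' @param seed RNG seed.
#' @return A [class_map()].
#' @export
corrupt_labels <- function(truth_map, rate, seed) {
  stopifnot(inherits(truth_map, "class_map"))
  if (rate < 0 || rate >= 1) stopf("rate must be in [0, 1)")
  if (rate == 0) return(truth_map)
  sch <- map_scheme(truth_map)
  K <- n_classes(sch)
  with_local_seed(seed, {
    lab <- unclass(truth_map)
    flip <- which(stats::runif(length(lab)) < rate)
    if (length(flip)) {
      old <- lab[flip]
      new <- integer(length(flip))
      nz <- old != 0L
      # uniform over the K - 1 other labels for classified pixels
      r <- old[nz] + sample.int(K - 1, sum(nz), replace = TRUE)
      new[nz] <- ifelse(r > K, r - K, r)
      new[!nz] <- sample.int(K, sum(!nz), replace = TRUE)
      lab[flip] <- new
    }
    class_map(lab, sch)
  })
}
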