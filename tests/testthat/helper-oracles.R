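# Independent oracles and fixture builders. Oracles are deliberately written
# as plain per-pixel loops, sharing no code with the package implementation.

# Brute-force Gaussian discriminant evaluation: for every pixel and class,
# g = log(prior) - 0.5 log|S| - 0.5 (x - m)' S^-1 (x - m), argmax, ties to
# the lowest class id.
oracle_mlc <- function(X, stats, priors = NULL) {
  K <- length(stats$classes)
  if (is.null(priors)) priors <- rep(1 / K, K)
  lab <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    best <- -Inf; bestk <- 0L
    for (cl in stats$classes) {
      S <- cl$cov
      if (cl$singular) {
        ridge <- 1e-6 * mean(diag(S))
        if (ridge <= 0) ridge <- 1e-6
        S <- S + diag(ridge, 3)
      }
      d <- X[i, ] - cl$mean
      g <- log(priors[cl$id]) - 0.5 * determinant(S)$modulus[1] -
        0.5 * as.numeric(t(d) %*% solve(S) %*% d)
      if (g > best + 1e-12) { best <- g; bestk <- cl$id }
    }
    lab[i] <- bestk
  }
  lab
}

# Exhaustive windowed vote with the package's tie rules: centre label counted
# center_weight times, window clipped at borders, centre keeps its label on a
# tie it participates in, otherwise lowest label wins.
oracle_majority <- function(lab, kernel, center_weight) {
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  h <- nrow(lab); w <- ncol(lab); hk <- kernel %/% 2
  out <- lab
  for (r in seq_len(h)) for (c in seq_len(w)) {
    rs <- max(1, r - hk):min(h, r + hk)
    cs <- max(1, c - hk):min(w, c + hk)
    win <- as.vector(lab[rs, cs])
    votes <- table(win)
    votes[as.character(lab[r, c])] <- votes[as.character(lab[r, c])] + center_weight - 1
    top <- max(votes)
    winners <- sort(as.integer(names(votes)[votes == top]))
    out[r, c] <- if (lab[r, c] %in% winners) lab[r, c] else winners[1]
  }
  out
}

# Stack-based flood fill per class; returns a list with component id matrix
# and component sizes.
oracle_flood_components <- function(lab, connectivity = 4) {
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  h <- nrow(lab); w <- ncol(lab)
  comp <- matrix(0L, h, w)
  sizes <- integer(0)
  nbr <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(rep(c(-1, 0, 1), 3), rep(c(-1, 0, 1), each = 3))[-5, ]
  }
  cid <- 0L
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (lab[r0, c0] == 0L || comp[r0, c0] != 0L) next
    cid <- cid + 1L
    stack <- list(c(r0, c0)); comp[r0, c0] <- cid; n <- 0L
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      n <- n + 1L
      for (k in seq_len(nrow(nbr))) {
        r <- p[1] + nbr[k, 1]; c <- p[2] + nbr[k, 2]
        if (r >= 1 && r <= h && c >= 1 && c <= w &&
            comp[r, c] == 0L && lab[r, c] == lab[p[1], p[2]]) {
          comp[r, c] <- cid
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
    sizes[cid] <- n
  }
  list(comp = comp, sizes = sizes)
}

# Per-pixel binary morphology with a size x size square structuring element,
# background padding, matching a centred (upper-left biased) origin.
oracle_dilate <- function(mask, size) {
  h <- nrow(mask); w <- ncol(mask)
  lo <- -(size %/% 2); off <- lo:(size - 1 + lo)
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    hit <- FALSE
    for (dr in off) for (dc in off) {
      rr <- r - dr; cc <- c - dc
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w && mask[rr, cc]) hit <- TRUE
    }
    out[r, c] <- hit
  }
  out
}

oracle_erode <- function(mask, size) {
  h <- nrow(mask); w <- ncol(mask)
  lo <- -(size %/% 2); off <- lo:(size - 1 + lo)
  out <- matrix(TRUE, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    all_in <- TRUE
    for (dr in off) for (dc in off) {
      rr <- r + dr; cc <- c + dc
      inside <- rr >= 1 && rr <= h && cc >= 1 && cc <= w && mask[rr, cc]
      if (!inside) all_in <- FALSE
    }
    out[r, c] <- all_in
  }
  out
}

oracle_close <- function(mask, size) oracle_erode(oracle_dilate(mask, size), size)

# --- fixture builders -------------------------------------------------------

test_scheme <- function(K = 3) {
  class_scheme(paste0("class", seq_len(K)))
}

random_class_map <- function(h, w, K = 3, seed = 1, p_unclassified = 0.1) {
  set.seed(seed)
  probs <- c(p_unclassified, rep((1 - p_unclassified) / K, K))
  class_map(matrix(sample(0:K, h * w, replace = TRUE, prob = probs), h, w),
            test_scheme(K))
}

# Two well-separated colour clusters (dark top half, light bottom half) with
# training ROIs; linearly separable in band space.
two_cluster_fixture <- function(seed = 1, h = 16, w = 16) {
  set.seed(seed)
  px <- array(0, c(h, w, 3))
  top <- seq_len(h %/% 2)
  px[top, , ] <- 40
  px[-top, , ] <- 210
  px <- px + array(round(runif(h * w * 3, -12, 12)), c(h, w, 3))
  img <- rgb_image(pmin(pmax(px, 0), 255))
  sch <- class_scheme(c("dark", "light"))
  coords <- expand.grid(row = seq_len(h), col = seq_len(w))
  coords$class_id <- ifelse(coords$row <= h %/% 2, 1L, 2L)
  pick <- do.call(rbind, lapply(1:2, function(k) {
    sub <- coords[coords$class_id == k, ]
    sub[sample(nrow(sub), 30), ]
  }))
  list(image = img, scheme = sch,
       training = roi_set(pick, sch, "training", c(h, w)))
}

# A random RGB image plus per-class training ROIs drawn from K colour models;
# used for the MLC-vs-oracle equivalence checks.
random_image_fixture <- function(h, w, K = 3, seed = 1) {
  set.seed(seed)
  means <- matrix(runif(K * 3, 0.15, 0.85), K, 3)
  img <- rgb_image(array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3)))
  # separate training image: ~20 noisy pixels per class arranged in rows
  th <- K * 4; tw <- 8
  tpx <- array(0, c(th, tw, 3))
  rows <- split(seq_len(th), rep(seq_len(K), each = 4))
  coords <- NULL
  for (k in seq_len(K)) {
    for (b in 1:3) {
      tpx[rows[[k]], , b] <- round(255 * pmin(pmax(
        means[k, b] + rnorm(4 * tw, 0, 0.05), 0), 1))
    }
    coords <- rbind(coords, expand.grid(row = rows[[k]], col = seq_len(tw),
                                        class_id = k))
  }
  timg <- rgb_image(tpx)
  sch <- test_scheme(K)
  stats <- compute_class_statistics(
    timg, roi_set(coords, sch, "training", c(th, tw)))
  list(image = img, stats = stats, scheme = sch)
}

# Small synthetic lake scene used across tests (fast to generate and classify).
small_scene <- function(seed, noise_sd = 0.02, ...) {
  generate_scene(scene_config(
    seed = seed, height = 128, width = 128,
    redd_blobs = 8, redd_radius = c(5, 8),
    rock_blobs = 12, rock_radius = c(4, 7),
    roi_train_pixels = 80, roi_truth_pixels = 80,
    noise_sd = noise_sd, ...))
}

map_equal <- function(a, b) identical(unclass(a)[, ], unclass(b)[, ])
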