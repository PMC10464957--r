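make_training_image <- function(values_by_class, h = 10, w = 10) {
  # values_by_class: list of n_k x 3 matrices of 8-bit band values; pixels are
  # laid out row-wise per class, ROIs point at them
  px <- array(0, c(h, w, 3))
  coords <- NULL
  r <- 1L
  for (k in seq_along(values_by_class)) {
    v <- values_by_class[[k]]
    for (i in seq_len(nrow(v))) {
      cc <- (i - 1L) %% w + 1L
      rr <- r + (i - 1L) %/% w
      px[rr, cc, ] <- v[i, ]
      coords <- rbind(coords, data.frame(class_id = k, row = rr, col = cc))
    }
    r <- r + ceiling(nrow(v) / w)
  }
  sch <- test_scheme(length(values_by_class))
  list(image = rgb_image(px), rois = roi_set(coords, sch, "training", c(h, w)),
       scheme = sch)
}

test_that("constant-colour class yields exact mean, zero covariance, singular flag", {
  vals <- matrix(rep(c(51, 102, 153), each = 5), 5, 3)  # 0.2, 0.4, 0.6 unit
  fx <- make_training_image(list(vals, matrix(sample(0:255, 15), 5, 3)))
  stats <- compute_class_statistics(fx$image, fx$rois)
  cl <- stats$classes[[1]]
  expect_equal(unname(cl$mean), c(0.2, 0.4, 0.6))
  expect_equal(unname(cl$cov), matrix(0, 3, 3))
  expect_true(cl$singular)
  expect_identical(cl$n, 5L)
})

test_that("covariance matches the closed-form two-point sample covariance", {
  # 4 pixels: two distinct values twice each; unbiased cov of {a,a,b,b} is
  # (2/3) * outer(a-m, a-m) + (2/3) * outer(b-m, b-m) with m = (a+b)/2
  a <- c(40, 80, 120); b <- c(200, 160, 240)
  vals <- rbind(a, a, b, b)
  fx <- make_training_image(list(vals, matrix(rep(c(10, 20, 30), 4), 4, 3,
                                              byrow = TRUE)))
  stats <- compute_class_statistics(fx$image, fx$rois)
  au <- a / 255; bu <- b / 255; m <- (au + bu) / 2
  expected <- (2 / 3) * (outer(au - m, au - m) + outer(bu - m, bu - m))
  expect_equal(unname(stats$classes[[1]]$cov), expected, tolerance = 1e-12)
  expect_equal(unname(stats$classes[[1]]$mean), m)
})

test_that("statistics are invariant to ROI pixel order", {
  set.seed(7)
  fx <- make_training_image(list(matrix(sample(0:255, 30), 10, 3),
                                 matrix(sample(0:255, 30), 10, 3)))
  stats1 <- compute_class_statistics(fx$image, fx$rois)
  shuffled <- fx$rois$pixels[sample(nrow(fx$rois$pixels)), ]
  rois2 <- roi_set(shuffled, fx$scheme, "training", fx$rois$dim)
  stats2 <- compute_class_statistics(fx$image, rois2)
  for (k in 1:2) {
    expect_equal(stats1$classes[[k]]$mean, stats2$classes[[k]]$mean)
    expect_equal(stats1$classes[[k]]$cov, stats2$classes[[k]]$cov)
  }
})

test_that("adding a pixel at the class mean never raises a covariance eigenvalue", {
  set.seed(13)
  v <- matrix(c(100, 140, 100, 180, 60, 220,
                120, 160, 200, 80, 40, 160), 4, 3)  # band means are integers
  stopifnot(all(colMeans(v) == round(colMeans(v))))
  fx <- make_training_image(list(v, matrix(rep(c(5, 10, 15), 4), 4, 3,
                                           byrow = TRUE)))
  stats <- compute_class_statistics(fx$image, fx$rois)
  ev_before <- eigen(stats$classes[[1]]$cov, symmetric = TRUE)$values

  fx2 <- make_training_image(list(rbind(v, colMeans(v)),
                                  matrix(rep(c(5, 10, 15), 4), 4, 3,
                                         byrow = TRUE)))
  stats2 <- compute_class_statistics(fx2$image, fx2$rois)
  ev_after <- eigen(stats2$classes[[1]]$cov, symmetric = TRUE)$values
  expect_true(all(ev_after <= ev_before + 1e-12))
})

test_that("classes with too few or no training pixels are rejected", {
  fx <- make_training_image(list(matrix(rep(c(1, 2, 3), 3), 3, 3, byrow = TRUE),
                                 matrix(rep(c(9, 9, 9), 4), 4, 3, byrow = TRUE)))
  expect_error(compute_class_statistics(fx$image, fx$rois), "at least 4")

  sch <- test_scheme(2)
  rois <- roi_set(data.frame(class_id = rep(1, 5), row = 1:5, col = 1),
                  sch, "training", c(10, 10))
  img <- rgb_image(array(0, c(10, 10, 3)))
  expect_error(compute_class_statistics(img, rois), "absent")
})

test_that("class balance report warns above the 2x ratio and not below", {
  sch <- test_scheme(2)
  eq <- roi_set(data.frame(class_id = rep(1:2, each = 100),
                           row = rep(1:100, 2), col = rep(1:2, each = 100)),
                sch, "training", c(100, 2))
  expect_silent(rep1 <- check_class_balance(eq))
  expect_equal(rep1$ratio, 1)
  expect_true(rep1$balanced)

  uneq <- roi_set(data.frame(class_id = rep(1:2, c(100, 300)),
                             row = c(1:100, rep(1:300, 1)),
                             col = rep(c(1, 2), c(100, 300))),
                  sch, "training", c(300, 2))
  expect_warning(rep2 <- check_class_balance(uneq), "unbalanced")
  expect_equal(rep2$ratio, 3)
  expect_false(rep2$balanced)
})

test_that("statistics survive a YAML round trip", {
  set.seed(3)
  fx <- make_training_image(list(matrix(sample(0:255, 30), 10, 3),
                                 matrix(sample(0:255, 30), 10, 3)))
  stats <- compute_class_statistics(fx$image, fx$rois)
  f <- withr::local_tempfile(fileext = ".yml")
  write_class_statistics(stats, f)
  back <- read_class_statistics(f, fx$scheme)
  for (k in 1:2) {
    expect_equal(unname(back$classes[[k]]$mean),
                 unname(stats$classes[[k]]$mean), tolerance = 1e-12)
    expect_equal(unname(back$classes[[k]]$cov),
                 unname(stats$classes[[k]]$cov), tolerance = 1e-12)
    expect_identical(back$classes[[k]]$n, stats$classes[[k]]$n)
  }
})
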