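test_that("a uniform map is a fixed point of every operator and the chain", {
  sch <- test_scheme(3)
  m <- class_map(matrix(2L, 12, 9), sch)
  expect_true(map_equal(majority_minority_filter(m), m))
  expect_true(map_equal(sieve_classes(m), m))
  expect_true(map_equal(clump_classes(m), m))
  expect_true(map_equal(apply_postclassification(m), m))
})

test_that("a single spurious pixel is flipped by the majority vote", {
  sch <- test_scheme(2)
  lab <- matrix(1L, 7, 7); lab[4, 4] <- 2L
  out <- majority_minority_filter(class_map(lab, sch), kernel = 3,
                                  center_weight = 1)
  expect_identical(unique(as.vector(unclass(out))), 1L)  # votes 8 vs 1
})

test_that("majority with dominant centre weight is the identity", {
  m <- random_class_map(15, 15, K = 3, seed = 2)
  out <- majority_minority_filter(m, kernel = 3, center_weight = 9)
  expect_true(map_equal(out, m))
})

test_that("majority filter matches the brute-force windowed vote", {
  for (seed in 1:4) {
    m <- random_class_map(16, 16, K = 3, seed = seed)
    out <- majority_minority_filter(m, kernel = 3, center_weight = 1)
    expect_identical(unclass(out)[, ], oracle_majority(unclass(m), 3, 1),
                     info = paste("seed", seed))
  }
  # larger kernel and weighted centre
  m <- random_class_map(16, 16, K = 4, seed = 9)
  out <- majority_minority_filter(m, kernel = 5, center_weight = 3)
  expect_identical(unclass(out)[, ], oracle_majority(unclass(m), 5, 3))
})

test_that("sieve removes exactly the components smaller than min_size", {
  sch <- test_scheme(2)
  # isolated single pixel at 4-connectivity, min size two -> unclassified
  lab <- matrix(1L, 6, 6); lab[3, 3] <- 2L
  out <- sieve_classes(class_map(lab, sch), connectivity = 4, min_size = 2)
  expect_identical(unclass(out)[3, 3], 0L)
  expect_identical(sum(unclass(out) == 0L), 1L)

  # a diagonal pair survives at 8- but not 4-connectivity
  lab2 <- matrix(1L, 6, 6); lab2[2, 2] <- 2L; lab2[3, 3] <- 2L
  out4 <- sieve_classes(class_map(lab2, sch), 4, 2)
  out8 <- sieve_classes(class_map(lab2, sch), 8, 2)
  expect_identical(sum(unclass(out4) == 2L), 0L)
  expect_identical(sum(unclass(out8) == 2L), 2L)

  # maps whose components all reach min_size are untouched
  big <- class_map(matrix(rep(c(1L, 2L), each = 18), 6, 6), sch)
  expect_true(map_equal(sieve_classes(big, 4, 2), big))
})

test_that("sieve agrees with an independent flood-fill labeling", {
  for (seed in c(3, 14)) for (conn in c(4, 8)) {
    m <- random_class_map(16, 16, K = 3, seed = seed)
    out <- sieve_classes(m, conn, min_size = 3)
    fl <- oracle_flood_components(unclass(m), conn)
    expected <- unclass(m)[, ]
    kill <- fl$comp != 0 & fl$sizes[pmax(fl$comp, 1)] < 3
    expected[kill] <- 0L
    expect_identical(unclass(out)[, ], expected,
                     info = paste("seed", seed, "conn", conn))
    # invariant: no surviving nonzero component is smaller than min_size
    fl2 <- oracle_flood_components(unclass(out), conn)
    expect_true(all(fl2$sizes >= 3 | fl2$sizes == 0))
  }
})

test_that("clump closes the gap between nearby same-class blobs", {
  sch <- test_scheme(2)
  # two class-1 blobs separated by a one-pixel unclassified gap on a 5 x 7
  # grid; closing with a 3 x 3 element bridges the gap
  lab <- matrix(0L, 5, 7)
  lab[2:4, 2:3] <- 1L
  lab[2:4, 5:6] <- 1L         # gap at column 4
  out <- clump_classes(class_map(lab, sch), size = 3)
  expect_identical(unclass(out)[2:4, 4], rep(1L, 3))
  fl <- oracle_flood_components(unclass(out), 4)
  expect_identical(length(fl$sizes), 1L)   # one merged component
})

test_that("clump matches the dilate-erode oracle when classes do not interact", {
  sch <- test_scheme(2)
  set.seed(31)
  lab <- matrix(0L, 16, 16)
  lab[2:5, 2:5] <- 1L; lab[3:4, 7:8] <- 1L       # class 1 in the top half
  lab[11:14, 3:6] <- 2L; lab[12:13, 9:10] <- 2L  # class 2 far away
  out <- clump_classes(class_map(lab, sch), size = 3)
  for (k in 1:2) {
    closed <- oracle_close(lab == k, 3)
    gained <- closed & lab == 0L
    expect_identical(unclass(out)[, ] == k, (lab == k) | gained,
                     info = paste("class", k))
  }
})

test_that("operators preserve dimensions and never invent labels", {
  for (seed in 1:3) {
    m <- random_class_map(16, 16, K = 3, seed = seed)
    for (f in list(function(x) majority_minority_filter(x, 3, 1),
                   function(x) sieve_classes(x, 4, 2),
                   function(x) clump_classes(x, 3))) {
      out <- f(m)
      expect_identical(dim(unclass(out)), dim(unclass(m)))
      expect_true(all(unique(as.vector(unclass(out))) %in%
                        c(0L, unique(as.vector(unclass(m))))))
    }
  }
})

test_that("the default chain cleans a salt-and-pepper corrupted truth map", {
  sc <- small_scene(seed = 101)
  bad <- corrupt_labels(sc$truth, 0.05, seed = 7)
  pre <- sum(unclass(bad) != unclass(sc$truth))
  fixed <- apply_postclassification(bad)
  post <- sum(unclass(fixed) != unclass(sc$truth))
  expect_lt(post, pre)
  changes <- attr(fixed, "changes")
  expect_named(changes, c("majority", "sieve", "clump"))
  expect_gt(changes["majority"], 0)
})

test_that("operator order matters on a crafted fixture", {
  sch <- test_scheme(2)
  # a 2x2 corner block of class 2: the majority filter erodes it to 3 pixels
  # (which the sieve at min size 4 then deletes), while sieving first lets the
  # still-complete block survive
  lab <- matrix(1L, 5, 5); lab[1:2, 1:2] <- 2L
  m <- class_map(lab, sch)
  maj_first <- sieve_classes(majority_minority_filter(m, 3, 1), 4, 4)
  sieve_first <- majority_minority_filter(sieve_classes(m, 4, 4), 3, 1)
  expect_true(any(unclass(maj_first) == 0L))
  expect_true(any(unclass(sieve_first) == 2L))
  expect_false(map_equal(maj_first, sieve_first))
  # the configurable order is honoured
  cfg <- postclass_config(sieve_min_size = 4,
                          operator_order = c("sieve", "majority"))
  out <- apply_postclassification(m, cfg)
  expect_true(map_equal(out, sieve_first))
})

test_that("operator parameters are validated", {
  m <- random_class_map(8, 8, K = 2, seed = 1)
  expect_error(majority_minority_filter(m, kernel = 4), "odd")
  expect_error(majority_minority_filter(m, 3, center_weight = 0), "positive")
  expect_error(sieve_classes(m, connectivity = 6), "connectivity")
  expect_error(clump_classes(m, size = 0), ">= 1")
  expect_error(postclass_config(majority_kernel = 2), "odd")
})
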