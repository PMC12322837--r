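# Keypoint detection, descriptor matching, and the rotation search.

blob_image <- function(n_blobs = 10, size = 96, seed = 4) {
  img <- matrix(0.1, size, size)
  g <- serialreg:::coord_grids(size, size)
  ctrs <- withr::with_seed(seed, cbind(sample(seq(25, size - 26, by = 5), n_blobs),
                                       sample(seq(25, size - 26, by = 5), n_blobs)))
  for (i in seq_len(n_blobs))
    img <- img + 0.8 * exp(-((g$x - ctrs[i, 1])^2 + (g$y - ctrs[i, 2])^2) / 8)
  list(img = image_section(img), centers = ctrs)
}

test_that("isolated bright blobs are each detected near their centre", {
  b <- blob_image()
  kp <- detect_and_describe(b$img)
  expect_gte(nrow(kp$xy), 10L)
  nearest <- apply(b$centers, 1, function(cc)
    min(sqrt((kp$xy[, 1] - cc[1])^2 + (kp$xy[, 2] - cc[2])^2)))
  expect_true(all(nearest <= 2))
})

test_that("detection is deterministic and flags textureless images", {
  img <- make_texture_image(7, c(128, 128))
  k1 <- detect_and_describe(img)
  k2 <- detect_and_describe(img)
  expect_identical(k1$xy, k2$xy)
  expect_identical(k1$desc, k2$desc)
  flat <- image_section(matrix(0.5, 64, 64))
  kf <- detect_and_describe(flat)
  expect_equal(nrow(kf$xy), 0L)
  expect_false(is.null(kf$warning))
})

test_that("matching is mutual-NN with ratio test and coordinate-agnostic", {
  img <- make_texture_image(8, c(128, 128))
  kp <- detect_and_describe(img)
  self <- match_descriptors(kp, kp)
  expect_equal(nrow(self$p), nrow(kp$xy))
  expect_equal(max(self$dist), 0, tolerance = 1e-6)
  expect_identical(self$p, self$q)

  # descriptors decide the pairing, not coordinates: shift moving coords
  kp_shift <- kp
  kp_shift$xy <- kp$xy + matrix(rep(c(5, 0), each = nrow(kp$xy)), ncol = 2)
  ms <- match_descriptors(kp, kp_shift)
  expect_equal(ms$q[, 1], ms$p[, 1] + 5)
  expect_equal(ms$q[, 2], ms$p[, 2])

  # near-duplicate descriptors fail the ratio test -> empty match set
  mk <- function(d) structure(list(xy = cbind(c(20, 40), c(20, 40)),
                                   desc = d, backend = "harris", index = 0L),
                              class = "keypoint_set")
  base <- matrix(rnorm(20), 2, 10)
  a <- mk(base)
  b <- mk(base[c(1, 1), ] + matrix(rnorm(20, 0, 1e-4), 2, 10))
  expect_equal(nrow(match_descriptors(a, b, ratio = 0.9)$p), 0L)

  # empty input -> empty output
  empty <- detect_and_describe(image_section(matrix(0.5, 64, 64)))
  expect_equal(nrow(match_descriptors(kp, empty)$p), 0L)
})

test_that("match symmetry: swapping the images swaps the roles", {
  a <- detect_and_describe(make_texture_image(9, c(128, 128)))
  b <- detect_and_describe(image_section(
    rotate_image(make_texture_image(9, c(128, 128))$pixels, 5,
                 fill = 0.15, expand = FALSE)))
  ab <- match_descriptors(a, b)
  ba <- match_descriptors(b, a)
  key_ab <- paste(ab$p[, 1], ab$p[, 2], ab$q[, 1], ab$q[, 2])
  key_ba <- paste(ba$q[, 1], ba$q[, 2], ba$p[, 1], ba$p[, 2])
  expect_setequal(key_ab, key_ba)
})

test_that("rotation search recovers the rotation and un-rotates the matches", {
  fx <- make_texture_image(15, c(160, 160))
  mv <- image_section(rotate_image(fx$pixels, -90, fill = 0.15))
  cfg <- fast_config()
  rp <- rotation_preprocess(fx, mv, c(0, 90, 180, 270), config = cfg)
  expect_equal(rp$angle, 90)
  expect_gt(rp$inlier_counts["90"], max(rp$inlier_counts[c("0", "180", "270")]))
  # un-rotated matches are fit by a near-pure-rotation affine at <1 px residual
  aff <- estimate_affine_ransac(rp$matches, 3, 1000, seed = 2)
  expect_true(aff$success)
  expect_lt(aff$mean_residual, 1)
  ang <- atan2(aff$transform$a[2, 1], aff$transform$a[1, 1]) * 180 / pi
  expect_equal(ang, 90, tolerance = 2)

  # identity pair: ties broken toward angle 0
  rp0 <- rotation_preprocess(fx, fx, c(0, 180), config = cfg)
  expect_equal(rp0$angle, 0)

  # textureless moving image: failure flag, angle 0
  flat <- image_section(matrix(0.5, 160, 160))
  rpf <- rotation_preprocess(fx, flat, c(0, 90), config = cfg)
  expect_true(rpf$matches$failed)
  expect_equal(rpf$angle, 0)
})

test_that("rotation search never loses inliers relative to no search", {
  cfg <- fast_config()
  for (seed in c(31, 32)) {
    fx <- make_texture_image(seed, c(128, 128))
    mv <- image_section(rotate_image(fx$pixels, -60, fill = 0.15))
    rp <- rotation_preprocess(fx, mv, seq(0, 330, by = 30), config = cfg)
    expect_gte(max(rp$inlier_counts), rp$inlier_counts["0"])
  }
})
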