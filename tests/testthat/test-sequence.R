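# Sequential pairwise registration, transform composition, stack resampling.

identity_pair <- function(t, nx = 64L, ny = 64L) {
  structure(list(
    fixed_index = t, moving_index = t + 1L, angle = 0,
    affine = structure(list(transform = affine2d(), inliers = integer(0),
                            n_inliers = 10L, mean_residual = 0,
                            success = TRUE), class = "affine_result"),
    field = bspline_field(nx, ny, c(4L, 4L)), final_loss = -1,
    flags = character(0)), class = "pair_registration")
}

translation_pair <- function(t, d, nx = 64L, ny = 64L) {
  p <- identity_pair(t, nx, ny)
  p$affine$transform <- affine2d(diag(2), d)
  p
}

random_pair <- function(t, nx = 96L, ny = 96L) {
  th <- runif(1, -10, 10) * pi / 180
  s <- runif(1, 0.97, 1.03)
  p <- identity_pair(t, nx, ny)
  p$affine$transform <- affine2d(
    s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2), runif(2, -5, 5))
  p$field <- bspline_field(nx, ny, c(4L, 4L), 3,
                           cx = matrix(rnorm(49, 0, 0.8), 7, 7),
                           cy = matrix(rnorm(49, 0, 0.8), 7, 7))
  p
}

test_that("registering two identical sections yields near-identity transforms", {
  img <- make_texture_image(70, c(96, 96))
  cfg <- fast_config()
  cfg$rotation_angles <- c(0, 90, 180, 270)
  pairs <- register_consecutive(list(img, img), cfg)
  expect_length(pairs, 1L)
  aff <- pairs[[1]]$affine$transform
  expect_lt(max(abs(aff$a - diag(2))), 0.01)
  expect_lt(sqrt(sum(aff$t^2)), 1)
  expect_lt(max(abs(c(pairs[[1]]$field$cx, pairs[[1]]$field$cy))), 0.5)
  expect_error(register_consecutive(list(img), cfg), "at least 2")
})

test_that("a blank slice is flagged but the pipeline completes", {
  img <- make_texture_image(71, c(96, 96))
  blank <- image_section(matrix(0.5, 96, 96))
  cfg <- fast_config()
  cfg$rotation_angles <- 0
  pairs <- register_consecutive(list(img, blank, img), cfg)
  expect_length(pairs, 2L)
  for (p in pairs) {
    expect_true("ransac_failed" %in% p$flags ||
                  "rotation_search_failed" %in% p$flags)
    expect_identical(p$affine$transform$a, diag(2))
    expect_true(all(p$field$cx == 0))
  }
})

test_that("composite transforms compose hops exactly", {
  # all-identity hops: every composite is the identity map
  pairs <- lapply(0:3, identity_pair)
  comps <- compose_to_anchor(pairs, anchor = 0L)
  pts <- cbind(runif(10, 5, 59), runif(10, 5, 59))
  for (cp in comps) expect_equal(apply_composite(cp, pts), pts,
                                 ignore_attr = TRUE, tolerance = 1e-9)
  # pure translations accumulate additively
  d <- list(c(3, -2), c(5, 1), c(-4, 6))
  tp <- lapply(0:2, function(t) translation_pair(t, d[[t + 1]]))
  comps_t <- compose_to_anchor(tp, anchor = 0L)
  for (s in 1:3) {
    total <- Reduce(`+`, d[seq_len(s)])
    expect_equal(apply_composite(comps_t[[s + 1]], pts),
                 pts + matrix(rep(total, each = nrow(pts)), ncol = 2),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # random 5-hop chain: composite equals hop-by-hop application
  withr::with_seed(72, rp <- lapply(0:4, random_pair))
  comps_r <- compose_to_anchor(rp, anchor = 0L)
  p20 <- withr::with_seed(73, cbind(runif(20, 10, 85), runif(20, 10, 85)))
  hopwise <- p20
  for (t in 5:1) hopwise <- map_points_pair(rp[[t]], hopwise, tol = 1e-4)
  via_comp <- apply_composite(comps_r[[6]], p20, tol = 1e-4)
  expect_lt(max(sqrt(rowSums((via_comp - hopwise)^2))), 0.1)
  # non-invertible hop affine is reported with the hop named
  bad <- rp
  bad[[3]]$affine$transform$a <- matrix(0, 2, 2)
  expect_error(compose_to_anchor(bad, 0L), "hop 3")
})

test_that("pre-anchor slices use exact inverse hops", {
  withr::with_seed(74, rp <- lapply(0:3, random_pair))
  comps <- compose_to_anchor(rp, anchor = 2L)
  expect_length(comps[[3]]$steps, 0L)   # anchor composite is identity
  pts <- withr::with_seed(75, cbind(runif(15, 20, 76), runif(15, 20, 76)))
  # slice 0 -> anchor 2 equals inverting hops 0 and 1 in turn
  manual <- pts
  for (t in 1:2) {
    manual <- ffd_transform_points(rp[[t]]$field, manual)
    manual <- affine_apply(affine_invert(rp[[t]]$affine$transform), manual)
  }
  expect_equal(apply_composite(comps[[1]], pts), manual, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("stack resampling respects composites and interpolates once", {
  secs <- lapply(1:3, function(i) make_texture_image(75 + i, c(64, 64)))
  idc <- compose_to_anchor(lapply(0:1, identity_pair), anchor = 0L)
  out <- resample_stack(secs, idc)
  for (i in 1:3) expect_equal(out[[i]]$pixels, secs[[i]]$pixels)
  # translation-only composites shift each slice exactly
  tp <- lapply(0:1, function(t) translation_pair(t, c(5, 0)))
  outs <- resample_stack(secs, compose_to_anchor(tp, anchor = 0L), fill = 0)
  expect_equal(outs[[2]]$pixels[, 6:64], secs[[2]]$pixels[, 1:59],
               tolerance = 1e-9)
  expect_equal(outs[[3]]$pixels[, 11:64], secs[[3]]$pixels[, 1:54],
               tolerance = 1e-9)
})

test_that("per-hop errors bound end-to-end error on a registered stack", {
  st <- make_synthetic_stack(
    synthetic_stack_spec(n_slices = 4, size = c(128L, 128L), rot_range = 10,
                         trans_range = 8, elastic_amp = 3), seed = 77)
  cfg <- fast_config()
  cfg$rotation_angles <- seq(0, 330, by = 30)
  res <- register_stack(st$sections, cfg)
  ev <- evaluate_sequence(st$landmarks, res$pairs, dims = c(128, 128))
  per_hop <- vapply(ev$pairs, function(e) e$mean_dist, numeric(1))
  # end-to-end: map slice 3 landmarks through the whole chain to slice 0
  pts <- st$landmarks[[4]]
  for (t in 3:1) pts <- map_points_pair(res$pairs[[t]], pts)
  e2e <- mean(sqrt(rowSums((pts - st$landmarks[[1]])^2)))
  expect_lt(e2e, length(per_hop) * max(per_hop) + 0.5)
})
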