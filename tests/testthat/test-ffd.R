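# B-spline deformation model, losses, and the non-rigid optimizer.

test_that("B-spline segment weights match closed forms and sum to one", {
  expect_equal(bspline_basis(0, 3), c(1, 4, 1, 0) / 6, tolerance = 1e-12)
  expect_equal(bspline_basis(0.25, 1), c(0.75, 0.25), tolerance = 1e-12)
  expect_error(bspline_basis(0.5, 0), "degree")
  set.seed(40)
  for (k in 1:4) {
    w <- bspline_basis(runif(25), k)
    expect_equal(rowSums(w), rep(1, 25), tolerance = 1e-12)
    expect_true(all(w >= -1e-15))
  }
})

test_that("point transform matches the explicit tensor-product oracle", {
  set.seed(41)
  # zero field is the identity
  f0 <- bspline_field(64, 48, c(4, 3))
  pts <- cbind(runif(20, 0, 64), runif(20, 0, 48))
  expect_equal(ffd_transform_points(f0, pts), pts, ignore_attr = TRUE)
  # uniform displacement: partition of unity forces pure translation
  fu <- bspline_field(64, 48, c(4, 3), 3,
                      cx = matrix(5, 6, 7), cy = matrix(-2, 6, 7))
  tp <- ffd_transform_points(fu, pts)
  expect_equal(tp[, 1], pts[, 1] + 5, tolerance = 1e-12)
  expect_equal(tp[, 2], pts[, 2] - 2, tolerance = 1e-12)
  # random fields against the explicit double-sum oracle (incl. a field
  # with one single nonzero control point)
  f1 <- bspline_field(10, 10, c(2, 2), 3)
  f1$cx[3, 4] <- 4.5
  f1$cy[3, 4] <- -1.25
  f2 <- bspline_field(10, 8, c(3, 2), 3,
                      cx = matrix(rnorm(30), 5, 6), cy = matrix(rnorm(30), 5, 6))
  for (fld in list(f1, f2)) {
    ps <- cbind(runif(40, 0, fld$nx - 1e-9), runif(40, 0, fld$ny - 1e-9))
    got <- ffd_transform_points(fld, ps)
    want <- t(apply(ps, 1, function(p) oracle_ffd_point(fld, p)))
    expect_equal(got, want, tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_error(ffd_transform_points(f1, cbind(-1, 5)), "support")
})

test_that("densified field agrees with pointwise evaluation", {
  set.seed(42)
  fld <- bspline_field(32, 24, c(4, 4), 3,
                       cx = matrix(rnorm(49), 7, 7), cy = matrix(rnorm(49), 7, 7))
  dn <- densify_field(fld)
  idx <- cbind(sample(24, 50, TRUE), sample(32, 50, TRUE))   # (row, col)
  pts <- cbind(idx[, 2] - 1, idx[, 1] - 1)
  tp <- ffd_transform_points(fld, pts)
  expect_equal(dn$ux[idx], tp[, 1] - pts[, 1], tolerance = 1e-10)
  expect_equal(dn$uy[idx], tp[, 2] - pts[, 2], tolerance = 1e-10)
  # zero and uniform fields densify as expected
  expect_true(all(densify_field(bspline_field(16, 16, c(2, 2)))$ux == 0))
  du <- densify_field(bspline_field(16, 16, c(2, 2), 3,
                                    cx = matrix(3, 5, 5), cy = matrix(0, 5, 5)))
  expect_equal(du$ux, matrix(3, 16, 16), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("FFD warping equals a per-pixel sampling oracle", {
  img <- as_gray(make_texture_image(43, c(64, 64)))
  sec <- image_section(img)
  # zero field: unchanged; integer-translation field: exact shift
  f0 <- bspline_field(64, 64, c(4, 4))
  expect_equal(warp_ffd(sec, f0)$pixels, img)
  ft <- bspline_field(64, 64, c(4, 4), 3,
                      cx = matrix(3, 7, 7), cy = matrix(0, 7, 7))
  wt <- warp_ffd(sec, ft, fill = 0)$pixels
  expect_equal(wt[, 1:61], img[, 4:64], tolerance = 1e-9)
  # random smooth field versus explicit per-pixel oracle
  set.seed(43)
  fr <- bspline_field(64, 64, c(4, 4), 3,
                      cx = matrix(rnorm(49, 0, 2), 7, 7),
                      cy = matrix(rnorm(49, 0, 2), 7, 7))
  got <- warp_ffd(sec, fr, fill = 0.5)$pixels
  want <- matrix(0, 64, 64)
  for (y in 0:63) for (x in 0:63) {
    tp <- oracle_ffd_point(fr, c(x, y))
    want[y + 1, x + 1] <- serialreg:::interp_bilinear(img, tp[1], tp[2], 0.5)
  }
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("local NCC matches its definition and brute-force oracle", {
  img <- as_gray(make_texture_image(44, c(64, 64)))
  # perfect correlation of an image with itself
  expect_equal(ncc_loss(img, img, 4), -1, tolerance = 1e-6)
  # invariance to affine intensity rescaling
  expect_equal(ncc_loss(img, 37 * img + 11, 4), -1, tolerance = 1e-4)
  # brute-force equivalence on small random pairs
  set.seed(44)
  for (i in 1:3) {
    f <- matrix(runif(49), 7, 7)
    w <- matrix(runif(49), 7, 7)
    expect_equal(ncc_loss(f, w, 1), oracle_ncc(f, w, 1), tolerance = 1e-9)
  }
  f10 <- matrix(runif(100), 10, 10)
  w10 <- matrix(runif(100), 10, 10)
  expect_equal(ncc_loss(f10, w10, 2), oracle_ncc(f10, w10, 2), tolerance = 1e-9)
  expect_equal(ncc_loss(f10, w10, 2, normalize = FALSE),
               oracle_ncc(f10, w10, 2, normalize = FALSE), tolerance = 1e-9)
  expect_error(ncc_loss(f10, w10, 6), "window")
})

test_that("diffusion regularizer: closed forms and brute-force oracle", {
  g <- serialreg:::coord_grids(10, 10)
  zero <- structure(list(ux = 0 * g$x, uy = 0 * g$x), class = "dense_field")
  expect_equal(diffusion_reg(zero), 0)
  const <- structure(list(ux = 0 * g$x + 3.2, uy = 0 * g$x - 1.1),
                     class = "dense_field")
  expect_equal(diffusion_reg(const), 0)
  # linear field u_x = x / Nx: the x-term contributes exactly 1/2
  lin <- structure(list(ux = g$x / 10, uy = 0 * g$x), class = "dense_field")
  expect_equal(diffusion_reg(lin), 0.5, tolerance = 1e-12)
  set.seed(45)
  ux <- matrix(rnorm(48), 6, 8)
  uy <- matrix(rnorm(48), 6, 8)
  expect_equal(diffusion_reg(structure(list(ux = ux, uy = uy),
                                       class = "dense_field")),
               oracle_diffusion(ux, uy), tolerance = 1e-9)
})

test_that("analytic control-point gradient matches finite differences", {
  set.seed(46)
  f <- as_gray(make_texture_image(46, c(64, 64)))
  m <- as_gray(make_texture_image(47, c(64, 64)))
  Bx <- serialreg:::bspline_basis_matrix(0:63, 64, 3, 3)
  g <- serialreg:::coord_grids(64, 64)
  eps <- serialreg:::ncc_eps(f, m, 25)
  cx <- matrix(rnorm(36, 0, 0.7), 6, 6)
  cy <- matrix(rnorm(36, 0, 0.7), 6, 6)
  ob <- serialreg:::ffd_objective(f, m, cx, cy, Bx, Bx, g$x, g$y,
                                  1.0, 2L, eps, 0, TRUE)
  h <- 1e-5
  fval <- function(cx, cy)
    serialreg:::ffd_objective(f, m, cx, cy, Bx, Bx, g$x, g$y, 1.0, 2L, eps,
                              0, TRUE, want_grad = FALSE)$total
  for (i in sample(36, 6)) {
    cp <- cx; cp[i] <- cp[i] + h
    cm <- cx; cm[i] <- cm[i] - h
    num <- (fval(cp, cy) - fval(cm, cy)) / (2 * h)
    expect_equal(ob$dcx[i], num, tolerance = 5e-3)
    cp <- cy; cp[i] <- cp[i] + h
    cm <- cy; cm[i] <- cm[i] - h
    num <- (fval(cx, cp) - fval(cx, cm)) / (2 * h)
    expect_equal(ob$dcy[i], num, tolerance = 5e-3)
  }
})

test_that("optimizer: identity fixed point, zero step, loss bookkeeping", {
  img <- make_texture_image(48, c(96, 96))
  cfg <- fast_config()
  cfg$grid_cells <- c(4L, 4L)
  opt <- optimize_ffd(img, img, cfg)
  expect_lt(max(abs(c(opt$field$cx, opt$field$cy))), 0.5)
  expect_lte(opt$trace$ncc[nrow(opt$trace)], -0.99)
  # landmark error for self-registration stays below half a pixel
  pts <- cbind(runif(20, 20, 75), runif(20, 20, 75))
  moved <- ffd_transform_points(opt$field, pts)
  expect_lt(max(sqrt(rowSums((moved - pts)^2))), 0.5)
  # exact loss decomposition in every report
  expect_equal(opt$trace$total, opt$trace$ncc + opt$trace$lambda * opt$trace$reg)
  # the accepted-loss trace never increases
  expect_true(all(diff(opt$trace$total) <= 0))
  # alpha = 0: nothing moves, trace is flat, stops at the first check
  cfg0 <- cfg
  cfg0$alpha <- 0
  opt0 <- optimize_ffd(img, img, cfg0)
  expect_true(all(opt0$field$cx == 0) && all(opt0$field$cy == 0))
  expect_lte(nrow(opt0$trace), 2L)
  expect_equal(length(unique(opt0$trace$total)), 1L)
})

test_that("non-rigid refinement recovers a known smooth deformation", {
  fx <- make_texture_image(49, c(128, 128))
  fld <- withr::with_seed(50, serialreg:::make_bump_field(128, 128, 2, 5, 25))
  g <- serialreg:::coord_grids(128, 128)
  pts <- cbind(as.vector(g$x), as.vector(g$y))
  src <- pts + serialreg:::eval_bump_field(fld, pts)
  mov <- matrix(serialreg:::interp_bilinear(as_gray(fx), src[, 1], src[, 2],
                                            0.15), 128, 128)
  cfg <- fast_config()
  opt <- optimize_ffd(fx, mov, cfg)
  q <- withr::with_seed(51, cbind(runif(30, 15, 112), runif(30, 15, 112)))
  truth <- q + serialreg:::eval_bump_field(fld, q)
  before <- mean(sqrt(rowSums((q - truth)^2)))
  est <- ffd_invert_points(opt$field, q, max_iter = 25, tol = 0.01)
  after <- mean(sqrt(rowSums((est - truth)^2)))
  expect_lt(after, 0.5 * before)
})

test_that("regularization pressure is monotone in lambda", {
  fx <- make_texture_image(52, c(64, 64))
  fld <- withr::with_seed(53, serialreg:::make_bump_field(64, 64, 2, 4, 15))
  g <- serialreg:::coord_grids(64, 64)
  pts <- cbind(as.vector(g$x), as.vector(g$y))
  src <- pts + serialreg:::eval_bump_field(fld, pts)
  mov <- matrix(serialreg:::interp_bilinear(as_gray(fx), src[, 1], src[, 2],
                                            0.15), 64, 64)
  cfg <- fast_config()
  cfg$grid_cells <- c(4L, 4L)
  cfg$max_iters <- 80L
  runs <- lapply(c(cfg$lambda, 10 * cfg$lambda), function(lam) {
    c2 <- cfg
    c2$lambda <- lam
    optimize_ffd(fx, mov, c2)
  })
  reg_final <- sapply(runs, function(r) r$trace$reg[nrow(r$trace)])
  expect_lte(reg_final[2], reg_final[1])
})
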