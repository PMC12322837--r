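# B-spline free-form deformation: transform model, local-NCC similarity,
# diffusion regularization, and the gradient-descent refinement loop.
#
# The deformation T(x) = x + sum_ij c_ij B_i(u) B_j(v) is parameterized by
# control-point displacements on a uniform grid of `cells` spline cells
# covering the image domain [0, Nx] x [0, Ny]; a degree-k spline needs
# cells + k control points per axis (the extra k rows/columns are the
# padding that keeps the full domain, borders included, inside the spline
# support).  Like warping, the field is a backward map: it gives, for every
# fixed-frame position, the coordinate at which the moving image is sampled.

#' Uniform B-spline segment weights (Cox-de Boor)
#'
#' Evaluates the `k + 1` non-zero uniform B-spline basis functions on one
#' knot span at local coordinate `t` in `[0, 1)`.  The weights are
#' non-negative and sum to one (partition of unity).  For the cubic case
#' `t = 0` gives `(1/6, 4/6, 1/6, 0)`.
#'
#' @param t numeric vector of local coordinates in `[0, 1]`.
#' @param degree spline degree `k >= 1`.
#' @return a `length(t) x (k + 1)` matrix of weights (a plain vector for a
#'   single `t`).
#' @export
bspline_basis <- function(t, degree = 3L) {
  if (degree < 1L) stop("spline degree must be >= 1")
  if (any(t < 0 | t > 1)) stop("local coordinate must lie in [0, 1]")
  n <- length(t)
  w <- matrix(1, n, 1)
  for (k in seq_len(degree)) {
    wn <- matrix(0, n, k + 1)
    for (a in 0:k) {
      if (a > 0) wn[, a + 1] <- wn[, a + 1] + (t + k - a) / k * w[, a]
      if (a < k) wn[, a + 1] <- wn[, a + 1] + (a + 1 - t) / k * w[, a + 1]
    }
    w <- wn
  }
  if (n == 1L) as.vector(w) else w
}

# Basis matrix mapping control columns to sample positions.  `coords` are
# 0-based positions in [0, N]; returns length(coords) x (cells + degree).
bspline_basis_matrix <- function(coords, n_pixels, cells, degree) {
  if (any(coords < 0 | coords > n_pixels))
    stop("point outside the spline support [0, N]")
  spacing <- n_pixels / cells
  u <- coords / spacing
  cell <- pmin(floor(u), cells - 1)
  tt <- u - cell
  w <- bspline_basis(tt, degree)
  if (is.null(dim(w))) w <- matrix(w, 1)
  B <- matrix(0, length(coords), cells + degree)
  for (a in 0:degree) {
    B[cbind(seq_along(coords), cell + a + 1)] <- w[, a + 1]
  }
  B
}

#' Construct a B-spline displacement field
#'
#' @param nx,ny image domain size in pixels.
#' @param cells `c(cx, cy)` number of spline cells along x and y.
#' @param degree spline degree (default cubic).
#' @param cx,cy optional control-point displacement matrices, each of
#'   dimension `(cells[2] + degree) x (cells[1] + degree)` (rows = y
#'   control index, columns = x control index), giving the x- and
#'   y-components of the displacement in pixels.  Default all zero
#'   (identity transform).
#' @return object of class `bspline_field`.
#' @export
bspline_field <- function(nx, ny, cells = c(8L, 8L), degree = 3L,
                          cx = NULL, cy = NULL) {
  if (degree < 1L) stop("spline degree must be >= 1")
  stopifnot(length(cells) == 2L, all(cells >= 1L), nx >= 2, ny >= 2)
  ncx <- cells[1] + degree
  ncy <- cells[2] + degree
  if (is.null(cx)) cx <- matrix(0, ncy, ncx)
  if (is.null(cy)) cy <- matrix(0, ncy, ncx)
  stopifnot(all(dim(cx) == c(ncy, ncx)), all(dim(cy) == c(ncy, ncx)),
            all(is.finite(cx)), all(is.finite(cy)))
  structure(
    list(cx = cx, cy = cy, cells = as.integer(cells), degree = as.integer(degree),
         nx = as.integer(nx), ny = as.integer(ny),
         spacing = c(nx / cells[1], ny / cells[2])),
    class = "bspline_field"
  )
}

#' @export
print.bspline_field <- function(x, ...) {
  cat(sprintf(
    "<bspline_field: %d x %d cells (degree %d) on %d x %d px, max |c| = %.3f px>\n",
    x$cells[1], x$cells[2], x$degree, x$nx, x$ny,
    max(abs(c(x$cx, x$cy)))))
  invisible(x)
}

# Displacement lookup; with clamp = TRUE coordinates outside the domain
# use the displacement of the nearest domain point (constant extension),
# which keeps chained transform composition defined everywhere.
ffd_displacement <- function(field, pts, clamp = FALSE) {
  px <- pts[, 1]
  py <- pts[, 2]
  if (clamp) {
    px <- pmin(pmax(px, 0), field$nx)
    py <- pmin(pmax(py, 0), field$ny)
  }
  Bx <- bspline_basis_matrix(px, field$nx, field$cells[1], field$degree)
  By <- bspline_basis_matrix(py, field$ny, field$cells[2], field$degree)
  cbind(rowSums((By %*% field$cx) * Bx), rowSums((By %*% field$cy) * Bx))
}

#' Apply a B-spline deformation to points
#'
#' `T(x) = x + sum_ij c_ij B_i(u) B_j(v)` with `(u, v)` the normalized local
#' coordinates of `x` in the control grid.  Points must lie inside the
#' spline support `[0, Nx] x [0, Ny]`.
#'
#' @param field a `bspline_field`.
#' @param pts n x 2 matrix of `(x, y)` coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
ffd_transform_points <- function(field, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  pts + ffd_displacement(field, pts)
}

#' Dense displacement field of a B-spline deformation
#'
#' Evaluates `u(x) = T(x) - x` at every pixel centre of the image domain.
#'
#' @param field a `bspline_field`.
#' @return object of class `dense_field`: list with `ux`, `uy`
#'   (`Ny x Nx` matrices, pixels).
#' @export
densify_field <- function(field) {
  Bx <- bspline_basis_matrix(0:(field$nx - 1), field$nx, field$cells[1],
                             field$degree)
  By <- bspline_basis_matrix(0:(field$ny - 1), field$ny, field$cells[2],
                             field$degree)
  structure(
    list(ux = By %*% field$cx %*% t(Bx), uy = By %*% field$cy %*% t(Bx)),
    class = "dense_field"
  )
}

#' Warp an image with a B-spline deformation (backward resampling)
#'
#' Output pixel `x` is sampled from the moving image at `T(x)` by bilinear
#' interpolation; samples outside the image take `fill`.
#'
#' @param image `image_section` or numeric matrix/array (moving image).
#' @param field a `bspline_field` over the output domain.
#' @param fill background fill value.
#' @return warped `image_section`.
#' @export
warp_ffd <- function(image, field, fill = 0) {
  sec <- as_section(image)
  dn <- densify_field(field)
  g <- coord_grids(field$ny, field$nx)
  tx <- as.vector(g$x + dn$ux)
  ty <- as.vector(g$y + dn$uy)
  warp_plane <- function(m) matrix(interp_bilinear(m, tx, ty, fill),
                                   field$ny, field$nx)
  px <- sec$pixels
  out <- if (length(dim(px)) == 3L) {
    array(c(warp_plane(px[, , 1]), warp_plane(px[, , 2]), warp_plane(px[, , 3])),
          dim = c(field$ny, field$nx, 3L))
  } else {
    warp_plane(px)
  }
  image_section(out, sec$index)
}

#' Numerically invert a B-spline deformation at points
#'
#' Solves `T(x) = y` for `x` by fixed-point iteration `x <- y - u(x)`,
#' which converges for the smooth, moderate deformations this pipeline
#' estimates.
#'
#' @param field a `bspline_field`.
#' @param pts n x 2 matrix of target coordinates `y`.
#' @param max_iter iteration cap.
#' @param tol stop when every point moves the residual `||T(x) - y||` below
#'   this many pixels.
#' @return n x 2 matrix of pre-images `x`.
#' @export
ffd_invert_points <- function(field, pts, max_iter = 10L, tol = 0.1) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  x <- pts
  for (i in seq_len(max_iter)) {
    res <- ffd_displacement(field, x, clamp = TRUE) + x - pts
    if (max(sqrt(rowSums(res^2))) < tol) break
    x <- x - res
  }
  x
}

# Relative-epsilon stabilizer for the squared-NCC denominator: scaled to the
# window pixel count and both dynamic ranges so that identical textured
# patches score 1 to ~1e-9 regardless of whether intensities live in [0, 1]
# or [0, 255].
ncc_eps <- function(f, w, n_window, rel = 1e-6) {
  (rel * n_window * max(diff(range(f)), 1e-12) * max(diff(range(w)), 1e-12))^2
}

ncc_terms <- function(f, w, r, eps) {
  n <- (2 * r + 1)^2
  sF <- box_sum_valid(f, r)
  sW <- box_sum_valid(w, r)
  sFF <- box_sum_valid(f * f, r)
  sWW <- box_sum_valid(w * w, r)
  sFW <- box_sum_valid(f * w, r)
  num <- sFW - sF * sW / n
  d1 <- pmax(sFF - sF^2 / n, 0)
  d2 <- pmax(sWW - sW^2 / n, 0)
  den <- d1 * d2 + eps
  list(num = num, d1 = d1, d2 = d2, den = den, cc = num^2 / den,
       muF = sF / n, muW = sW / n, n_omega = length(num))
}

#' Local normalized cross-correlation loss
#'
#' `L_NCC = -sum_x CC(x)` over all pixels whose `(2r+1) x (2r+1)` window
#' lies fully inside the image, where `CC` is the squared local NCC
#' `S_num^2 / (S_den1 S_den2 + eps)` between the fixed and warped images
#' (local means subtracted within each window).  `CC` is 1 for locally
#' identical (up to affine intensity rescaling) patches and 0 for
#' uncorrelated ones, so the loss attains -1 per valid pixel at a perfect
#' match.  By default the sum is divided by the number of valid windows so
#' that one regularization weight works across image sizes; set
#' `normalize = FALSE` for the bare sum.
#'
#' @param fixed,warped `image_section`s or matrices of identical shape
#'   (RGB is reduced to luminance).
#' @param radius window radius `r` (window side `2r + 1`).
#' @param normalize divide by the number of valid windows.
#' @param eps_rel relative denominator stabilizer (see Details in the
#'   methods vignette).
#' @return scalar loss (negative; `-1` means perfect local correlation
#'   everywhere when normalized).
#' @export
ncc_loss <- function(fixed, warped, radius = 4L, normalize = TRUE,
                     eps_rel = 1e-6) {
  f <- as_gray(fixed)
  w <- as_gray(warped)
  if (!all(dim(f) == dim(w))) stop("fixed and warped images differ in shape")
  if (2 * radius + 1 > min(dim(f))) stop("NCC window larger than the image")
  eps <- ncc_eps(f, w, (2 * radius + 1)^2, eps_rel)
  tm <- ncc_terms(f, w, radius, eps)
  s <- sum(tm$cc)
  if (normalize) -s / tm$n_omega else -s
}

#' Diffusion regularization of a displacement field
#'
#' Smoothness penalty
#' `0.5 * (E_x[s_x^2 ||d_x u||^2] + E_x[s_y^2 ||d_y u||^2])` with forward
#' finite differences of the displacement vectors, scaling factors
#' `s_x = Nx`, `s_y = Ny` (the field dimensions in pixels), and the
#' expectation taken over all valid positions.  Zero for any constant
#' (rigid-translation) field.
#'
#' @param dense a `dense_field` (list with `ux`, `uy` matrices) as returned
#'   by [densify_field()].
#' @return scalar penalty.
#' @export
diffusion_reg <- function(dense) {
  ux <- dense$ux
  uy <- dense$uy
  stopifnot(all(dim(ux) == dim(uy)), nrow(ux) >= 2L, ncol(ux) >= 2L)
  ny <- nrow(ux)
  nx <- ncol(ux)
  dxux <- ux[, 2:nx, drop = FALSE] - ux[, 1:(nx - 1), drop = FALSE]
  dxuy <- uy[, 2:nx, drop = FALSE] - uy[, 1:(nx - 1), drop = FALSE]
  dyux <- ux[2:ny, , drop = FALSE] - ux[1:(ny - 1), , drop = FALSE]
  dyuy <- uy[2:ny, , drop = FALSE] - uy[1:(ny - 1), , drop = FALSE]
  ex <- nx^2 * mean(dxux^2 + dxuy^2)
  ey <- ny^2 * mean(dyux^2 + dyuy^2)
  0.5 * (ex + ey)
}

# Adjoint of the forward x-difference operator (and its y analogue).
adj_dx <- function(d) {
  nx <- ncol(d) + 1L
  cbind(-d[, 1, drop = FALSE],
        if (nx > 2L) d[, 1:(nx - 2), drop = FALSE] - d[, 2:(nx - 1), drop = FALSE],
        d[, nx - 1, drop = FALSE])
}
adj_dy <- function(d) {
  ny <- nrow(d) + 1L
  rbind(-d[1, , drop = FALSE],
        if (ny > 2L) d[1:(ny - 2), , drop = FALSE] - d[2:(ny - 1), , drop = FALSE],
        d[ny - 1, , drop = FALSE])
}

# Full loss + analytic gradient with respect to the control points.
# The regularizer inside the optimizer is the diffusion penalty evaluated
# on the NORMALIZED displacement field (components divided by Nx and Ny),
# which makes its value and hence the default lambda independent of image
# size; for square images it reduces to the plain squared-finite-difference
# penalty in pixel units.
ffd_objective <- function(f, mov, cx, cy, Bx, By, gx, gy, lambda, r, eps,
                          fill, normalize, want_grad = TRUE) {
  ny <- nrow(f)
  nx <- ncol(f)
  ux <- By %*% cx %*% t(Bx)
  uy <- By %*% cy %*% t(Bx)
  tx <- gx + ux
  ty <- gy + uy
  w <- matrix(interp_bilinear(mov, as.vector(tx), as.vector(ty), fill), ny, nx)
  tm <- ncc_terms(f, w, r, eps)
  l_ncc <- if (normalize) -sum(tm$cc) / tm$n_omega else -sum(tm$cc)

  nvx <- ny * (nx - 1)
  nvy <- (ny - 1) * nx
  axy2 <- (nx / ny)^2
  ayx2 <- (ny / nx)^2
  dxux <- ux[, 2:nx] - ux[, 1:(nx - 1)]
  dxuy <- uy[, 2:nx] - uy[, 1:(nx - 1)]
  dyux <- ux[2:ny, ] - ux[1:(ny - 1), ]
  dyuy <- uy[2:ny, ] - uy[1:(ny - 1), ]
  l_reg <- 0.5 * ((sum(dxux^2) + axy2 * sum(dxuy^2)) / nvx +
                    (ayx2 * sum(dyux^2) + sum(dyuy^2)) / nvy)
  total <- l_ncc + lambda * l_reg
  out <- list(total = total, ncc = l_ncc, reg = l_reg, warped = w)
  if (!want_grad) return(out)

  scal <- if (normalize) 1 / tm$n_omega else 1
  a <- 2 * tm$num / tm$den
  b <- 2 * tm$num^2 * tm$d1 / tm$den^2
  g_w <- -scal * (f * box_scatter_full(a, r, ny, nx) -
                    box_scatter_full(a * tm$muF, r, ny, nx) -
                    w * box_scatter_full(b, r, ny, nx) +
                    box_scatter_full(b * tm$muW, r, ny, nx))
  gr <- interp_bilinear_grad(mov, as.vector(tx), as.vector(ty))
  g_tx <- g_w * matrix(gr$gx, ny, nx)
  g_ty <- g_w * matrix(gr$gy, ny, nx)

  g_ux <- g_tx + lambda * (adj_dx(dxux) / nvx + ayx2 * adj_dy(dyux) / nvy)
  g_uy <- g_ty + lambda * (axy2 * adj_dx(dxuy) / nvx + adj_dy(dyuy) / nvy)
  out$dcx <- t(By) %*% g_ux %*% Bx
  out$dcy <- t(By) %*% g_uy %*% Bx
  out
}

#' B-spline non-rigid registration by gradient descent
#'
#' Minimizes `L = L_NCC + lambda * L_reg` over the control-point
#' displacements, starting from the zero (identity) field, using analytic
#' gradients obtained by the chain rule through the bilinear warp and the
#' tensor-product spline basis.  The update is a normalized gradient step:
#' each accepted iteration moves the largest control-point component by at
#' most the current step size (initially `config$alpha`, in pixels), and
#' the step is halved whenever it would increase the loss (backtracking),
#' so the recorded loss trace is non-increasing.  Optimization stops when
#' the loss improvement falls below `config$tol`, when backtracking cannot
#' find a descent step, or after `config$max_iters` iterations.
#'
#' @param fixed,moving `image_section`s (or matrices) of identical shape;
#'   RGB is reduced to luminance for the loss.
#' @param config pipeline configuration (see [default_config()]); the
#'   relevant entries are `grid_cells`, `spline_degree`, `ncc_radius`,
#'   `lambda`, `alpha`, `max_iters`, `tol`, `background`, `normalize_ncc`.
#' @return list: `field` (the optimized `bspline_field`) and `trace`
#'   (data frame with one row per recorded iteration: `iter`, `total`,
#'   `ncc`, `reg`, `lambda`; row `iter = 0` is the initial loss).
#' @export
optimize_ffd <- function(fixed, moving, config = default_config()) {
  f <- as_gray(fixed)
  mov <- as_gray(moving)
  if (!all(dim(f) == dim(mov))) stop("fixed and moving images differ in shape")
  ny <- nrow(f)
  nx <- ncol(f)
  k <- config$spline_degree
  cells <- config$grid_cells
  r <- config$ncc_radius
  if (2 * r + 1 > min(ny, nx)) stop("NCC window larger than the image")
  Bx <- bspline_basis_matrix(0:(nx - 1), nx, cells[1], k)
  By <- bspline_basis_matrix(0:(ny - 1), ny, cells[2], k)
  g <- coord_grids(ny, nx)
  eps <- ncc_eps(f, mov, (2 * r + 1)^2)
  cx <- matrix(0, cells[2] + k, cells[1] + k)
  cy <- cx

  obj <- function(cx, cy, want_grad = TRUE)
    ffd_objective(f, mov, cx, cy, Bx, By, g$x, g$y, config$lambda, r, eps,
                  config$background, config$normalize_ncc, want_grad)

  cur <- obj(cx, cy)
  if (!is.finite(cur$total))
    stop(sprintf("non-finite loss at initialization (ncc=%g, reg=%g)",
                 cur$ncc, cur$reg))
  trace <- data.frame(iter = 0L, total = cur$total, ncc = cur$ncc,
                      reg = cur$reg, lambda = config$lambda)
  step <- config$alpha
  for (it in seq_len(config$max_iters)) {
    gmax <- max(abs(c(cur$dcx, cur$dcy)))
    if (gmax == 0) break
    accepted <- FALSE
    for (h in 1:12) {
      ncx <- cx - step * cur$dcx / gmax
      ncy <- cy - step * cur$dcy / gmax
      cand <- obj(ncx, ncy)
      if (!is.finite(cand$total))
        stop(sprintf("non-finite loss at iteration %d (ncc=%g, reg=%g)",
                     it, cand$ncc, cand$reg))
      if (cand$total <= cur$total) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    delta <- cur$total - cand$total
    cx <- ncx
    cy <- ncy
    cur <- cand
    trace <- rbind(trace, data.frame(iter = it, total = cur$total,
                                     ncc = cur$ncc, reg = cur$reg,
                                     lambda = config$lambda))
    if (delta < config$tol) break
    step <- min(step * 1.25, config$alpha)
  }
  field <- bspline_field(nx, ny, cells, k, cx = cx, cy = cy)
  list(field = field, trace = trace)
}
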