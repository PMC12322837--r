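# Low-level raster helpers shared by all modules.
#
# Coordinate convention (package-wide): 0-based, x = column index,
# y = row index, origin at the centre of the top-left pixel.  Matrices are
# stored in R's native row-major-visual form: img[y + 1, x + 1].

#' Bilinear interpolation of an image at fractional coordinates
#'
#' Samples `img` at the 0-based positions `(x, y)`.  Positions outside the
#' pixel grid (`x` outside `[0, Nx - 1]` or `y` outside `[0, Ny - 1]`) take
#' the fill value.
#'
#' @param img numeric matrix (`Ny x Nx`).
#' @param x,y numeric vectors of equal length, 0-based coordinates.
#' @param fill background value for out-of-bounds samples.
#' @return numeric vector of sampled intensities.
#' @keywords internal
interp_bilinear <- function(img, x, y, fill = 0) {
  ny <- nrow(img)
  nx <- ncol(img)
  ok <- x >= 0 & x <= nx - 1 & y >= 0 & y <= ny - 1 & is.finite(x) & is.finite(y)
  x0 <- pmin(pmax(floor(x), 0), nx - 2)
  y0 <- pmin(pmax(floor(y), 0), ny - 2)
  fx <- x - x0
  fy <- y - y0
  fx[!ok] <- 0
  fy[!ok] <- 0
  x0[!ok] <- 0
  y0[!ok] <- 0
  v00 <- img[cbind(y0 + 1, x0 + 1)]
  v01 <- img[cbind(y0 + 1, x0 + 2)]
  v10 <- img[cbind(y0 + 2, x0 + 1)]
  v11 <- img[cbind(y0 + 2, x0 + 2)]
  out <- (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
  out[!ok] <- fill
  out
}

# Exact spatial derivative of the bilinear interpolant at (x, y);
# zero outside the image (matches background-fill semantics, so the
# optimizer never pulls on the constant fill region).
interp_bilinear_grad <- function(img, x, y) {
  ny <- nrow(img)
  nx <- ncol(img)
  ok <- x >= 0 & x <= nx - 1 & y >= 0 & y <= ny - 1 & is.finite(x) & is.finite(y)
  x0 <- pmin(pmax(floor(x), 0), nx - 2)
  y0 <- pmin(pmax(floor(y), 0), ny - 2)
  fx <- x - x0
  fy <- y - y0
  fx[!ok] <- 0
  fy[!ok] <- 0
  x0[!ok] <- 0
  y0[!ok] <- 0
  v00 <- img[cbind(y0 + 1, x0 + 1)]
  v01 <- img[cbind(y0 + 1, x0 + 2)]
  v10 <- img[cbind(y0 + 2, x0 + 1)]
  v11 <- img[cbind(y0 + 2, x0 + 2)]
  gx <- (1 - fy) * (v01 - v00) + fy * (v11 - v10)
  gy <- (1 - fx) * (v10 - v00) + fx * (v11 - v01)
  gx[!ok] <- 0
  gy[!ok] <- 0
  list(gx = gx, gy = gy)
}

# Summed-area table with a leading zero row/column.
sat2d <- function(m) {
  s <- apply(m, 2, cumsum)
  if (is.null(dim(s))) s <- matrix(s, nrow = nrow(m))
  s <- t(apply(s, 1, cumsum))
  out <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  out[-1L, -1L] <- s
  out
}

# Sliding-window sums over (2r+1)^2 windows fully inside the image.
# Returns a (ny - 2r) x (nx - 2r) matrix of sums at valid window centres.
box_sum_valid <- function(m, r) {
  w <- 2L * r + 1L
  ny <- nrow(m)
  nx <- ncol(m)
  stopifnot(ny >= w, nx >= w)
  s <- sat2d(m)
  s[(w + 1):(ny + 1), (w + 1):(nx + 1), drop = FALSE] -
    s[1:(ny - w + 1), (w + 1):(nx + 1), drop = FALSE] -
    s[(w + 1):(ny + 1), 1:(nx - w + 1), drop = FALSE] +
    s[1:(ny - w + 1), 1:(nx - w + 1), drop = FALSE]
}

# Adjoint of box_sum_valid: scatter per-centre values back onto the full
# pixel grid (each pixel receives the sum over all valid windows containing
# it).  `a` has the dimensions returned by box_sum_valid.
box_scatter_full <- function(a, r, ny, nx) {
  pad <- matrix(0, ny + 2L * r, nx + 2L * r)
  pad[(2L * r + 1):(ny), (2L * r + 1):(nx)] <- a
  box_sum_valid(pad, r)
}

# Separable convolution with replicate padding, kernel applied along rows
# (y) then columns (x).
sep_conv <- function(m, kernel) {
  r <- (length(kernel) - 1L) / 2L
  ny <- nrow(m)
  nx <- ncol(m)
  out <- matrix(0, ny, nx)
  for (k in seq_along(kernel)) {
    idx <- pmin(pmax(seq_len(ny) + (k - 1L - r), 1L), ny)
    out <- out + kernel[k] * m[idx, , drop = FALSE]
  }
  out2 <- matrix(0, ny, nx)
  for (k in seq_along(kernel)) {
    idx <- pmin(pmax(seq_len(nx) + (k - 1L - r), 1L), nx)
    out2 <- out2 + kernel[k] * out[, idx, drop = FALSE]
  }
  out2
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

gauss_blur <- function(m, sigma) sep_conv(m, gauss_kernel(sigma))

# Pixel-centre coordinate grids (0-based), matching matrix layout.
coord_grids <- function(ny, nx) {
  list(
    x = matrix(rep(0:(nx - 1L), each = ny), ny, nx),
    y = matrix(rep(0:(ny - 1L), times = nx), ny, nx)
  )
}
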