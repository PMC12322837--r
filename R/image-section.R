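#' Construct an image section
#'
#' One 2D section of a serial stack.  `pixels` is a numeric `Ny x Nx` matrix
#' (grayscale) or `Ny x Nx x 3` array (RGB); `index` is the slice position in
#' the ordered sequence (0-based).  Intensities keep whatever scale the
#' source provided (e.g. 0..255 for an 8-bit file, 0..1 for synthetic data);
#' all similarity measures downstream are invariant to affine intensity
#' rescaling.
#'
#' @param pixels numeric matrix or 3-channel array of intensities.
#' @param index integer slice position.
#' @return an object of class `image_section` with fields `pixels`, `index`,
#'   `ny`, `nx`.
#' @export
image_section <- function(pixels, index = 0L) {
  if (is.null(dim(pixels)) || !(length(dim(pixels)) %in% c(2L, 3L)))
    stop("pixels must be a matrix or Ny x Nx x 3 array")
  if (length(dim(pixels)) == 3L && dim(pixels)[3] != 3L)
    stop("multi-channel sections must have exactly 3 channels")
  if (!all(is.finite(pixels))) stop("pixel intensities must be finite")
  ny <- dim(pixels)[1]
  nx <- dim(pixels)[2]
  if (nx < 8L || ny < 8L) stop("sections must be at least 8 x 8 pixels")
  structure(
    list(pixels = pixels, index = as.integer(index), ny = ny, nx = nx),
    class = "image_section"
  )
}

#' @export
print.image_section <- function(x, ...) {
  ch <- if (length(dim(x$pixels)) == 3L) "RGB" else "gray"
  cat(sprintf("<image_section #%d: %d x %d px, %s, range [%.3g, %.3g]>\n",
              x$index, x$nx, x$ny, ch, min(x$pixels), max(x$pixels)))
  invisible(x)
}

as_section <- function(x, index = 0L) {
  if (inherits(x, "image_section")) x else image_section(x, index)
}

#' Grayscale view of a section
#'
#' RGB sections are reduced to luminance (0.299 R + 0.587 G + 0.114 B);
#' grayscale sections are returned as-is.
#'
#' @param section an `image_section` or numeric matrix/array.
#' @return numeric matrix.
#' @export
as_gray <- function(section) {
  px <- if (inherits(section, "image_section")) section$pixels else section
  if (length(dim(px)) == 3L) {
    0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  } else {
    px
  }
}

#' Rotate an image about its centre
#'
#' Rotation by `degrees` (counter-clockwise in the x-right / y-down raster
#' frame this package uses everywhere) about the image centre.  With
#' `expand = TRUE` the output canvas is enlarged to the bounding box of the
#' rotated image so no content is clipped; out-of-bounds samples take
#' `fill`.  The returned object carries the forward map from input to output
#' coordinates as attribute `"map"` (`list(R, c_in, c_out)` with
#' `p_out = R %*% (p_in - c_in) + c_out`), which the rotation search uses to
#' express matches in the unrotated frame without resampling twice.
#'
#' @param img numeric matrix or 3-channel array.
#' @param degrees rotation angle in degrees.
#' @param fill background fill value.
#' @param expand enlarge the canvas to avoid clipping.
#' @return rotated image with attribute `"map"`.
#' @export
rotate_image <- function(img, degrees, fill = 0, expand = TRUE) {
  th <- degrees * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  d <- dim(img)
  ny <- d[1]
  nx <- d[2]
  c_in <- c((nx - 1) / 2, (ny - 1) / 2)
  if (expand) {
    nxo <- ceiling(nx * abs(cos(th)) + ny * abs(sin(th)))
    nyo <- ceiling(nx * abs(sin(th)) + ny * abs(cos(th)))
  } else {
    nxo <- nx
    nyo <- ny
  }
  c_out <- c((nxo - 1) / 2, (nyo - 1) / 2)
  g <- coord_grids(nyo, nxo)
  # backward map: output -> input
  dx <- as.vector(g$x) - c_out[1]
  dy <- as.vector(g$y) - c_out[2]
  xs <- R[1, 1] * dx + R[2, 1] * dy + c_in[1]   # R^-1 = t(R)
  ys <- R[1, 2] * dx + R[2, 2] * dy + c_in[2]
  rot_plane <- function(m) matrix(interp_bilinear(m, xs, ys, fill), nyo, nxo)
  out <- if (length(d) == 3L) {
    array(c(rot_plane(img[, , 1]), rot_plane(img[, , 2]), rot_plane(img[, , 3])),
          dim = c(nyo, nxo, 3L))
  } else {
    rot_plane(img)
  }
  attr(out, "map") <- list(R = R, c_in = c_in, c_out = c_out)
  out
}
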