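# Affine stage: least-squares fitting, RANSAC, and backward warping.
#
# The transform direction is fixed throughout the package: an affine maps
# MOVING coordinates q into the FIXED frame, x' = A q + t.  Images are
# resampled with the inverse map (backward warping).

#' Construct a 2D affine transform
#'
#' @param a 2x2 numeric matrix (linear part).
#' @param t length-2 numeric translation `(tx, ty)` in pixels.
#' @return object of class `affine2d`.
#' @export
affine2d <- function(a = diag(2), t = c(0, 0)) {
  a <- matrix(as.numeric(a), 2, 2)
  t <- as.numeric(t)
  stopifnot(length(t) == 2L, all(is.finite(a)), all(is.finite(t)))
  dt <- abs(det(a))
  if (dt < 1e-6 || dt > 1e6)
    warning(sprintf("affine determinant %.3g is outside [1e-6, 1e6]", det(a)))
  structure(list(a = a, t = t), class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat(sprintf("<affine2d  A = [%.4f %.4f; %.4f %.4f]  t = (%.2f, %.2f)>\n",
              x$a[1, 1], x$a[1, 2], x$a[2, 1], x$a[2, 2], x$t[1], x$t[2]))
  invisible(x)
}

#' Apply an affine transform to points
#'
#' @param tf an `affine2d`.
#' @param pts n x 2 matrix of `(x, y)` coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
affine_apply <- function(tf, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  cbind(tf$a[1, 1] * pts[, 1] + tf$a[1, 2] * pts[, 2] + tf$t[1],
        tf$a[2, 1] * pts[, 1] + tf$a[2, 2] * pts[, 2] + tf$t[2])
}

#' Invert an affine transform
#' @param tf an `affine2d`.
#' @return the inverse `affine2d`.
#' @export
affine_invert <- function(tf) {
  if (abs(det(tf$a)) < .Machine$double.eps * 100)
    stop("affine transform is not invertible")
  ai <- solve(tf$a)
  affine2d(ai, -as.vector(ai %*% tf$t))
}

#' Compose two affine transforms
#'
#' Returns the transform equivalent to applying `second` after `first`,
#' i.e. `x -> second(first(x))`.
#' @param first,second `affine2d` objects.
#' @return composed `affine2d`.
#' @export
affine_compose <- function(first, second) {
  affine2d(second$a %*% first$a, as.vector(second$a %*% first$t) + second$t)
}

#' Least-squares affine fit from point correspondences
#'
#' Finds the `(A, t)` minimizing `sum ||A q_i + t - p_i||^2`, mapping moving
#' coordinates `q` into the fixed frame where `p` lives.
#'
#' @param p n x 2 matrix of fixed-frame points.
#' @param q n x 2 matrix of corresponding moving-frame points.
#' @return fitted `affine2d`.
#' @export
fit_affine_lsq <- function(p, q) {
  p <- matrix(as.numeric(p), ncol = 2)
  q <- matrix(as.numeric(q), ncol = 2)
  n <- nrow(p)
  if (n < 3L || nrow(q) != n) stop("need at least 3 point pairs")
  M <- cbind(q[, 1], q[, 2], 1)
  qr_M <- qr(M)
  if (qr_M$rank < 3L)
    stop("degenerate configuration: moving points are collinear")
  cx <- qr.coef(qr_M, p[, 1])
  cy <- qr.coef(qr_M, p[, 2])
  affine2d(matrix(c(cx[1], cy[1], cx[2], cy[2]), 2, 2), c(cx[3], cy[3]))
}

#' Robust affine estimation with RANSAC
#'
#' Repeatedly samples minimal 3-pair subsets from the match set, fits an
#' exact affine, and counts matches whose fixed-frame residual
#' `||A q + t - p||` is below `threshold_px`.  The hypothesis with the most
#' inliers wins (ties: smaller mean inlier residual) and is re-fit by least
#' squares on its full inlier set.  Deterministic for a given `seed`.
#'
#' @param matches a `match_set` (see [match_descriptors()]) or a list with
#'   n x 2 matrices `p` and `q`.
#' @param threshold_px inlier residual threshold in pixels.
#' @param n_iter number of random hypotheses.
#' @param seed RNG seed (the global RNG state is left untouched).
#' @return list of class `affine_result`: `transform` (`affine2d`),
#'   `inliers` (integer index vector into the matches), `n_inliers`,
#'   `mean_residual` (px, over inliers, after the refit), `success`.
#' @export
estimate_affine_ransac <- function(matches, threshold_px = 3, n_iter = 2000,
                                   seed = 1L) {
  p <- matches$p
  q <- matches$q
  n <- if (is.null(p)) 0L else nrow(p)
  fail <- structure(
    list(transform = affine2d(), inliers = integer(0), n_inliers = 0L,
         mean_residual = NA_real_, success = FALSE),
    class = "affine_result"
  )
  if (n < 3L) return(fail)
  px <- p[, 1]; py <- p[, 2]; qx <- q[, 1]; qy <- q[, 2]
  th2 <- threshold_px^2
  best_n <- 0L
  best_resid <- Inf
  best_in <- integer(0)
  withr::with_seed(seed, {
    for (it in seq_len(n_iter)) {
      s <- sample.int(n, 3L)
      M <- cbind(qx[s], qy[s], rep(1, 3))
      dM <- M[1, 1] * (M[2, 2] - M[3, 2]) - M[1, 2] * (M[2, 1] - M[3, 1]) +
        (M[2, 1] * M[3, 2] - M[3, 1] * M[2, 2])
      if (abs(dM) < 1e-9) next
      cx <- solve(M, px[s])
      cy <- solve(M, py[s])
      rx <- cx[1] * qx + cx[2] * qy + cx[3] - px
      ry <- cy[1] * qx + cy[2] * qy + cy[3] - py
      r2 <- rx * rx + ry * ry
      inl <- r2 < th2
      cnt <- sum(inl)
      if (cnt >= 3L) {
        mres <- mean(sqrt(r2[inl]))
        if (cnt > best_n || (cnt == best_n && mres < best_resid)) {
          best_n <- cnt
          best_resid <- mres
          best_in <- which(inl)
        }
      }
    }
  })
  if (best_n < 3L) return(fail)
  tf <- fit_affine_lsq(p[best_in, , drop = FALSE], q[best_in, , drop = FALSE])
  pr <- affine_apply(tf, q[best_in, , drop = FALSE])
  res <- sqrt(rowSums((pr - p[best_in, , drop = FALSE])^2))
  structure(
    list(transform = tf, inliers = best_in, n_inliers = best_n,
         mean_residual = mean(res), success = TRUE),
    class = "affine_result"
  )
}

#' @export
print.affine_result <- function(x, ...) {
  cat(sprintf("<affine_result: %s, %d inliers, mean residual %.3f px>\n",
              if (x$success) "ok" else "FAILED", x$n_inliers,
              if (is.na(x$mean_residual)) NA else x$mean_residual))
  invisible(x)
}

#' Warp an image with an affine transform (backward resampling)
#'
#' Produces the moving image resampled into the fixed frame: the output
#' pixel at `x'` is sampled from the moving image at `A^-1 (x' - t)` by
#' bilinear interpolation.  RGB channels are warped identically.
#'
#' @param image `image_section` or numeric matrix/array (the moving image).
#' @param transform `affine2d` mapping moving to fixed coordinates.
#' @param output_shape `c(ny, nx)` of the output; defaults to the input
#'   shape.
#' @param fill background value for samples outside the moving image.
#' @return warped `image_section` (index preserved when given one).
#' @export
warp_affine <- function(image, transform, output_shape = NULL, fill = 0) {
  sec <- as_section(image)
  inv <- affine_invert(transform)
  if (is.null(output_shape)) output_shape <- c(sec$ny, sec$nx)
  nyo <- output_shape[1]
  nxo <- output_shape[2]
  g <- coord_grids(nyo, nxo)
  src <- affine_apply(inv, cbind(as.vector(g$x), as.vector(g$y)))
  warp_plane <- function(m) matrix(interp_bilinear(m, src[, 1], src[, 2], fill),
                                   nyo, nxo)
  px <- sec$pixels
  out <- if (length(dim(px)) == 3L) {
    array(c(warp_plane(px[, , 1]), warp_plane(px[, , 2]), warp_plane(px[, , 3])),
          dim = c(nyo, nxo, 3L))
  } else {
    warp_plane(px)
  }
  image_section(out, sec$index)
}
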