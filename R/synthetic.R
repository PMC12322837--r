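# Synthetic serial-section stacks with exactly tracked landmarks and
# ground-truth transforms.  These emulate the degradations of real serial
# histology — per-slice global rigid/affine perturbation, smooth elastic
# deformation, illumination jitter, and fresh fine-grain content noise —
# while keeping an analytic ground truth at every landmark.

#' Specification of a synthetic serial-section stack
#'
#' Per-hop perturbation magnitudes describe how slice `t+1` is generated
#' from slice `t`.  Defaults describe a moderately misaligned stack:
#' rotations up to +/-20 degrees, translations up to +/-15 px, isotropic
#' scale in `[0.97, 1.03]`, elastic deformation up to 5 px built from
#' smooth Gaussian bumps, and +/-10% illumination jitter.
#'
#' @param n_slices number of sections (>= 2).
#' @param size `c(nx, ny)` image size in pixels.
#' @param rot_range maximum absolute per-hop rotation (degrees).
#' @param scale_range `c(lo, hi)` isotropic per-hop scale factor range.
#' @param trans_range maximum absolute per-hop translation (px, each axis).
#' @param elastic_bumps number of Gaussian bumps per hop.
#' @param elastic_amp maximum elastic displacement magnitude (px).
#' @param elastic_sigma bump smoothness scale (px).
#' @param n_landmarks number of tracked landmarks (>= 4).
#' @param jitter illumination jitter amplitude (relative gain; offset is
#'   half of it).
#' @param noise_amp amplitude of fresh per-slice fine-grain noise.
#' @param background background intensity (also the warp fill value).
#' @param blob_count number of textured tissue blobs in the base image.
#' @return list of class `synthetic_stack_spec`.
#' @export
synthetic_stack_spec <- function(n_slices = 8L, size = c(256L, 256L),
                                 rot_range = 20, scale_range = c(0.97, 1.03),
                                 trans_range = 15, elastic_bumps = 3L,
                                 elastic_amp = 5, elastic_sigma = 40,
                                 n_landmarks = 25L, jitter = 0.1,
                                 noise_amp = 0.02, background = 0.15,
                                 blob_count = 40L) {
  stopifnot(n_slices >= 2L, n_landmarks >= 4L, elastic_amp >= 0,
            all(is.finite(c(rot_range, scale_range, trans_range,
                            elastic_amp, elastic_sigma, jitter))))
  structure(
    list(n_slices = as.integer(n_slices), size = as.integer(size),
         rot_range = rot_range, scale_range = scale_range,
         trans_range = trans_range, elastic_bumps = as.integer(elastic_bumps),
         elastic_amp = elastic_amp, elastic_sigma = elastic_sigma,
         n_landmarks = as.integer(n_landmarks), jitter = jitter,
         noise_amp = noise_amp, background = background,
         blob_count = as.integer(blob_count)),
    class = "synthetic_stack_spec"
  )
}

#' Generate a textured synthetic tissue image
#'
#' Multi-scale smoothed noise plus elliptical "tissue" blobs with internal
#' speckle, producing dense corner-detectable structure on a uniform
#' background.  Deterministic for a given seed; intensities in `[0, 1]`
#' with dynamic range of at least half the scale.
#'
#' @param seed RNG seed.
#' @param size `c(nx, ny)` in pixels (at least 64 x 64).
#' @param blob_count number of elliptical blobs.
#' @param background background intensity level.
#' @return an `image_section` (grayscale, `[0, 1]`).
#' @export
make_texture_image <- function(seed = 1L, size = c(256L, 256L),
                               blob_count = 40L, background = 0.15) {
  stopifnot(size[1] >= 64L, size[2] >= 64L)
  nx <- size[1]
  ny <- size[2]
  withr::with_seed(seed, {
    img <- matrix(0, ny, nx)
    # multi-scale smoothed noise: coarse structure down to corner-scale grain
    for (scale in c(24, 12, 6)) {
      cny <- ceiling(ny / scale) + 2L
      cnx <- ceiling(nx / scale) + 2L
      coarse <- matrix(stats::rnorm(cny * cnx), cny, cnx)
      g <- coord_grids(ny, nx)
      up <- matrix(interp_bilinear(coarse, as.vector(g$x) / scale,
                                   as.vector(g$y) / scale, 0), ny, nx)
      img <- img + up * scale / 24
    }
    # elliptical tissue blobs with internal speckle
    g <- coord_grids(ny, nx)
    for (b in seq_len(blob_count)) {
      cx <- stats::runif(1, 0.1 * nx, 0.9 * nx)
      cy <- stats::runif(1, 0.1 * ny, 0.9 * ny)
      ax <- stats::runif(1, 6, nx / 8)
      ay <- stats::runif(1, 6, ny / 8)
      th <- stats::runif(1, 0, pi)
      amp <- stats::runif(1, 0.4, 1.2) * sample(c(-1, 1), 1)
      dx <- (g$x - cx) * cos(th) + (g$y - cy) * sin(th)
      dy <- -(g$x - cx) * sin(th) + (g$y - cy) * cos(th)
      q <- (dx / ax)^2 + (dy / ay)^2
      img <- img + amp * exp(-q * 2)
    }
    img <- img + 0.15 * gauss_blur(matrix(stats::rnorm(ny * nx), ny, nx), 1)
    lo <- stats::quantile(img, 0.01)
    hi <- stats::quantile(img, 0.99)
    img <- (img - lo) / (hi - lo)
    img <- pmin(pmax(img * (0.95 - background) + background, 0), 1)
  })
  image_section(matrix(img, ny, nx), 0L)
}

# Smooth elastic field: sum of Gaussian bumps, rescaled so the maximum
# displacement magnitude over the pixel grid equals `amp`.
make_bump_field <- function(nx, ny, n_bumps, amp, sigma) {
  centers <- cbind(stats::runif(n_bumps, 0.15 * nx, 0.85 * nx),
                   stats::runif(n_bumps, 0.15 * ny, 0.85 * ny))
  vecs <- matrix(stats::rnorm(2 * n_bumps), n_bumps, 2)
  vecs <- vecs / sqrt(rowSums(vecs^2)) * stats::runif(n_bumps, 0.4, 1)
  fld <- list(centers = centers, vecs = vecs, sigma = sigma, scale = 1)
  if (amp > 0 && n_bumps > 0) {
    g <- coord_grids(ny, nx)
    d <- eval_bump_field(fld, cbind(as.vector(g$x), as.vector(g$y)))
    mx <- max(sqrt(rowSums(d^2)))
    fld$scale <- if (mx > 0) amp / mx else 0
  } else {
    fld$scale <- 0
  }
  fld
}

eval_bump_field <- function(fld, pts) {
  out <- matrix(0, nrow(pts), 2)
  for (b in seq_len(nrow(fld$centers))) {
    w <- exp(-((pts[, 1] - fld$centers[b, 1])^2 +
                 (pts[, 2] - fld$centers[b, 2])^2) / (2 * fld$sigma^2))
    out[, 1] <- out[, 1] + fld$vecs[b, 1] * w
    out[, 2] <- out[, 2] + fld$vecs[b, 2] * w
  }
  out * fld$scale
}

# Ground-truth hop map B_t: slice t+1 coordinates -> slice t coordinates,
# B(x) = A (x - c) + c + d + bump(x).  Generation warps slice t backward
# through B_t; landmarks are propagated with the numerically exact inverse.
gt_hop <- function(affine, bump) list(affine = affine, bump = bump)

#' Apply a ground-truth hop transform to points
#'
#' Maps slice `t+1` coordinates into the slice `t` frame.
#'
#' @param hop one element of a synthetic stack's `hops` list.
#' @param pts n x 2 coordinate matrix.
#' @return n x 2 transformed coordinates.
#' @export
gt_hop_apply <- function(hop, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  affine_apply(hop$affine, pts) + eval_bump_field(hop$bump, pts)
}

#' Invert a ground-truth hop transform at points
#'
#' Solves `B(x) = p` by fixed-point iteration to ~1e-12 px, mapping slice
#' `t` coordinates into the slice `t+1` frame.
#'
#' @param hop one element of a synthetic stack's `hops` list.
#' @param pts n x 2 coordinate matrix.
#' @return n x 2 pre-images.
#' @export
gt_hop_invert <- function(hop, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  inv <- affine_invert(hop$affine)
  x <- affine_apply(inv, pts)
  for (i in 1:60) {
    res <- gt_hop_apply(hop, x) - pts
    if (max(abs(res)) < 1e-13) break
    x <- affine_apply(inv, pts - eval_bump_field(hop$bump, x))
  }
  x
}

#' Generate a synthetic serial-section stack
#'
#' Slice 0 is a textured tissue image; each following slice is the previous
#' one warped by a random hop transform (rotation/scale/translation about
#' the centre plus a smooth Gaussian-bump elastic field), with global
#' illumination jitter (gain/offset) and fresh fine-grain noise emulating
#' section-to-section content change.  Landmarks are sampled on slice 0 at
#' least 10% of the image size away from the borders and propagated exactly
#' through the ground-truth transforms.
#'
#' @param spec a `synthetic_stack_spec`.
#' @param seed master seed; all randomness derives from it.
#' @return list of class `synthetic_stack`: `sections` (list of
#'   `image_section`), `landmarks` (list of n x 2 matrices, one per slice,
#'   rownames `l1..ln`), `hops` (list of ground-truth hop transforms, hop
#'   `t` maps slice `t+1` coords to slice `t` coords), `spec`, `seed`.
#' @export
make_synthetic_stack <- function(spec = synthetic_stack_spec(), seed = 1L) {
  nx <- spec$size[1]
  ny <- spec$size[2]
  base <- make_texture_image(seed, spec$size, spec$blob_count, spec$background)
  withr::with_seed(seed + 1L, {
    sections <- vector("list", spec$n_slices)
    sections[[1]] <- base
    lm <- cbind(stats::runif(spec$n_landmarks, 0.1 * nx, 0.9 * nx),
                stats::runif(spec$n_landmarks, 0.1 * ny, 0.9 * ny))
    rownames(lm) <- paste0("l", seq_len(spec$n_landmarks))
    landmarks <- vector("list", spec$n_slices)
    landmarks[[1]] <- lm
    hops <- vector("list", spec$n_slices - 1L)
    ctr <- c((nx - 1) / 2, (ny - 1) / 2)
    g <- coord_grids(ny, nx)
    grid_pts <- cbind(as.vector(g$x), as.vector(g$y))
    for (t in seq_len(spec$n_slices - 1L)) {
      th <- stats::runif(1, -spec$rot_range, spec$rot_range) * pi / 180
      sc <- stats::runif(1, spec$scale_range[1], spec$scale_range[2])
      d <- stats::runif(2, -spec$trans_range, spec$trans_range)
      A <- sc * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      aff <- affine2d(A, ctr + d - as.vector(A %*% ctr))
      bump <- make_bump_field(nx, ny, spec$elastic_bumps, spec$elastic_amp,
                              spec$elastic_sigma)
      hop <- gt_hop(aff, bump)
      hops[[t]] <- hop
      # image: slice_{t+1}(x) = jitter(slice_t(B(x))) + fresh noise
      src <- gt_hop_apply(hop, grid_pts)
      prev <- as_gray(sections[[t]])
      warped <- matrix(interp_bilinear(prev, src[, 1], src[, 2],
                                       spec$background), ny, nx)
      gain <- 1 + stats::runif(1, -spec$jitter, spec$jitter)
      offset <- stats::runif(1, -spec$jitter / 2, spec$jitter / 2)
      noise <- spec$noise_amp * gauss_blur(matrix(stats::rnorm(ny * nx), ny, nx), 1)
      img <- pmin(pmax(gain * warped + offset + noise, 0), 1)
      sections[[t + 1L]] <- image_section(img, t)
      lm_next <- gt_hop_invert(hop, landmarks[[t]])
      rownames(lm_next) <- rownames(lm)
      landmarks[[t + 1L]] <- lm_next
    }
  })
  structure(
    list(sections = sections, landmarks = landmarks, hops = hops,
         spec = spec, seed = as.integer(seed)),
    class = "synthetic_stack"
  )
}

#' @export
print.synthetic_stack <- function(x, ...) {
  cat(sprintf("<synthetic_stack: %d slices of %d x %d px, %d landmarks, seed %d>\n",
              x$spec$n_slices, x$spec$size[1], x$spec$size[2],
              x$spec$n_landmarks, x$seed))
  invisible(x)
}
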