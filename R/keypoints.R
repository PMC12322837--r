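# Keypoint detection, description, matching, and the rotation search that
# maximizes valid match pairs before the affine stage.
#
# Backends are pluggable: a backend is a function (gray image matrix,
# config) -> list(xy = n x 2 matrix, desc = n x d matrix).  The built-in
# "harris" backend (corner detector + normalized patch descriptors) needs no
# pretrained weights; learned extractors can be registered under the same
# contract.

.backends <- new.env(parent = emptyenv())

#' Register a keypoint backend
#'
#' @param name backend identifier.
#' @param fn function `(img, config)` returning `list(xy, desc)` with `xy`
#'   an n x 2 matrix of 0-based `(x, y)` coordinates inside the image and
#'   `desc` an n x d descriptor matrix.
#' @export
register_keypoint_backend <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .backends)
  invisible(name)
}

#' List registered keypoint backends
#' @return character vector of backend names.
#' @export
list_keypoint_backends <- function() ls(.backends)

# ---- built-in backend: Harris corners + normalized patch descriptors ----

harris_response <- function(img, sigma_d = 1, sigma_i = 1.5, k = 0.05) {
  ny <- nrow(img)
  nx <- ncol(img)
  sm <- gauss_blur(img, sigma_d)
  ix <- matrix(0, ny, nx)
  iy <- matrix(0, ny, nx)
  ix[, 2:(nx - 1)] <- (sm[, 3:nx] - sm[, 1:(nx - 2)]) / 2
  iy[2:(ny - 1), ] <- (sm[3:ny, ] - sm[1:(ny - 2), ]) / 2
  ixx <- gauss_blur(ix * ix, sigma_i)
  iyy <- gauss_blur(iy * iy, sigma_i)
  ixy <- gauss_blur(ix * iy, sigma_i)
  (ixx * iyy - ixy^2) - k * (ixx + iyy)^2
}

# 3x3 non-maximum suppression; returns a logical matrix.
nonmax_3x3 <- function(r) {
  ny <- nrow(r)
  nx <- ncol(r)
  pad <- matrix(-Inf, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- r
  keep <- matrix(TRUE, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[(2 + dy):(ny + 1 + dy), (2 + dx):(nx + 1 + dx)]
    keep <- keep & (r >= nb)
  }
  keep & is.finite(r)
}

backend_harris <- function(img, config = default_config()) {
  side <- config$patch_side
  margin <- side + 2L
  ny <- nrow(img)
  nx <- ncol(img)
  empty <- list(xy = matrix(numeric(0), 0, 2), desc = matrix(numeric(0), 0, side^2))
  rng <- diff(range(img))
  if (rng < 1e-12) {
    attr(empty, "warning") <- "constant image: no keypoints"
    return(empty)
  }
  if (ny < 2L * margin + 8L || nx < 2L * margin + 8L) {
    attr(empty, "warning") <- "image too small for the patch descriptor"
    return(empty)
  }
  work <- (img - min(img)) / rng
  resp <- harris_response(work, config$harris_sigma / 1.5, config$harris_sigma)
  keep <- nonmax_3x3(resp)
  thresh <- max(resp) * config$harris_rel_thresh
  keep <- keep & resp > thresh & resp > 0
  # enforce the border margin needed by the descriptor patch
  keep[c(seq_len(margin), (ny - margin + 1):ny), ] <- FALSE
  keep[, c(seq_len(margin), (nx - margin + 1):nx)] <- FALSE
  idx <- which(keep)
  if (length(idx) == 0L) {
    attr(empty, "warning") <- "no corners above threshold"
    return(empty)
  }
  yy <- (idx - 1L) %% ny
  xx <- (idx - 1L) %/% ny
  ord <- order(-resp[idx], yy, xx)
  if (length(ord) > config$max_keypoints) ord <- ord[seq_len(config$max_keypoints)]
  xy <- cbind(xx[ord], yy[ord])
  desc <- patch_descriptors(work, xy, side = side, orient = config$orient_patches)
  list(xy = xy, desc = desc)
}

# Square patch descriptors: Gaussian-windowed, zero-mean, unit-norm patches
# of `side` x `side` pixels.  With orient = TRUE each patch is rotated to
# its dominant gradient orientation before sampling (partial rotation
# invariance); the default leaves patches upright so that large rotations
# are handled explicitly by the rotation search.
patch_descriptors <- function(img, xy, side = 16L, orient = FALSE) {
  k <- nrow(xy)
  d <- seq_len(side) - (side / 2)            # offsets, e.g. -7..8 for side 16
  grid <- expand.grid(dy = d, dx = d)
  npx <- side^2
  w <- exp(-(grid$dx^2 + grid$dy^2) / (2 * (side / 3)^2))
  if (k == 0L) return(matrix(numeric(0), 0, npx))
  if (!orient) {
    rows <- rep(xy[, 2] + 1L, times = npx) + rep(grid$dy, each = k)
    cols <- rep(xy[, 1] + 1L, times = npx) + rep(grid$dx, each = k)
    P <- matrix(img[cbind(rows, cols)], k, npx)
  } else {
    P <- matrix(0, k, npx)
    gx <- img[, c(2:ncol(img), ncol(img))] - img[, c(1, 1:(ncol(img) - 1))]
    gy <- img[c(2:nrow(img), nrow(img)), ] - img[c(1, 1:(nrow(img) - 1)), ]
    for (i in seq_len(k)) {
      rs <- xy[i, 2] + 1L + d
      cs <- xy[i, 1] + 1L + d
      th <- atan2(sum(gy[rs, cs] * matrix(w, side, side)),
                  sum(gx[rs, cs] * matrix(w, side, side)))
      ct <- cos(th); st <- sin(th)
      sx <- xy[i, 1] + ct * grid$dx - st * grid$dy
      sy <- xy[i, 2] + st * grid$dx + ct * grid$dy
      P[i, ] <- interp_bilinear(img, sx, sy, 0)
    }
  }
  P <- P * rep(w, each = k)
  P <- P - rowMeans(P)
  nrm <- sqrt(rowSums(P^2))
  nrm[nrm < 1e-12] <- 1
  P / nrm
}

#' Detect keypoints and compute descriptors
#'
#' Runs the requested backend on the grayscale view of a section.  The
#' result is deterministic for a fixed backend and image.  A constant
#' (textureless) image yields an empty set with a warning flag rather than
#' an error.
#'
#' @param section `image_section` or numeric matrix.
#' @param backend backend name (default the built-in `"harris"`).
#' @param config pipeline configuration, see [default_config()].
#' @return object of class `keypoint_set`: `xy` (n x 2, 0-based), `desc`
#'   (n x d), `backend`, `index`, `warning` (NULL or message).
#' @export
detect_and_describe <- function(section, backend = "harris",
                                config = default_config()) {
  sec <- as_section(section)
  fn <- get0(backend, envir = .backends)
  if (is.null(fn)) stop(sprintf("unknown keypoint backend '%s'", backend))
  out <- fn(as_gray(sec), config)
  structure(
    list(xy = out$xy, desc = out$desc, backend = backend, index = sec$index,
         warning = attr(out, "warning")),
    class = "keypoint_set"
  )
}

#' @export
print.keypoint_set <- function(x, ...) {
  cat(sprintf("<keypoint_set: %d keypoints (%s)%s>\n", nrow(x$xy), x$backend,
              if (is.null(x$warning)) "" else paste0(", warning: ", x$warning)))
  invisible(x)
}

new_match_set <- function(p, q, dist, angle = 0, failed = FALSE) {
  structure(
    list(p = p, q = q, dist = dist, angle = angle, failed = failed),
    class = "match_set"
  )
}

#' @export
print.match_set <- function(x, ...) {
  n <- if (is.null(x$p)) 0L else nrow(x$p)
  cat(sprintf("<match_set: %d pairs, rotation %g deg%s>\n", n, x$angle,
              if (isTRUE(x$failed)) ", FAILED" else ""))
  invisible(x)
}

#' Match descriptors between two keypoint sets
#'
#' Mutual-nearest-neighbour matching under Euclidean descriptor distance,
#' filtered by Lowe's ratio test (nearest / second-nearest < `ratio`).
#' Each keypoint appears in at most one pair.  Either set empty yields an
#' empty match set.
#'
#' @param fixed_kp,moving_kp `keypoint_set` objects from the same backend.
#' @param ratio ratio-test threshold.
#' @return `match_set` with `p` (fixed coords), `q` (moving coords),
#'   `dist` (descriptor distances), `angle` (0 here).
#' @export
match_descriptors <- function(fixed_kp, moving_kp, ratio = 0.9) {
  nf <- nrow(fixed_kp$xy)
  nm <- nrow(moving_kp$xy)
  if (nf == 0L || nm == 0L)
    return(new_match_set(matrix(numeric(0), 0, 2), matrix(numeric(0), 0, 2),
                         numeric(0)))
  if (!identical(fixed_kp$backend, moving_kp$backend))
    stop("keypoint sets come from different backends")
  df <- fixed_kp$desc
  dm <- moving_kp$desc
  d2 <- outer(rowSums(df^2), rep(1, nm)) + outer(rep(1, nf), rowSums(dm^2)) -
    2 * tcrossprod(df, dm)
  d2 <- pmax(d2, 0)
  nn1 <- max.col(-d2, ties.method = "first")
  d1 <- d2[cbind(seq_len(nf), nn1)]
  d2m <- d2
  d2m[cbind(seq_len(nf), nn1)] <- Inf
  second <- d2m[cbind(seq_len(nf), max.col(-d2m, ties.method = "first"))]
  rev_nn <- max.col(-t(d2), ties.method = "first")   # best fixed for each moving
  pass <- rev_nn[nn1] == seq_len(nf) &
    (d1 < 1e-24 | sqrt(d1) < ratio * sqrt(pmax(second, 0)))
  idx <- which(pass)
  new_match_set(fixed_kp$xy[idx, , drop = FALSE],
                moving_kp$xy[nn1[idx], , drop = FALSE],
                sqrt(d1[idx]))
}

#' Rotation search: orient the moving section before matching
#'
#' For every candidate angle the moving image is rotated about its centre
#' (expanded canvas, background fill), keypoints are detected and matched
#' against the fixed section, and RANSAC inliers are counted.  The angle
#' with the most inliers wins; ties go to the smallest absolute angle
#' (angles are compared on (-180, 180]).  The winning matches are returned
#' with the moving coordinates mapped back into the ORIGINAL unrotated
#' frame, so the downstream affine stage estimates a single transform in
#' original frames and the image is never resampled twice.
#'
#' If no angle reaches 3 RANSAC inliers the search fails: angle 0 and the
#' (possibly empty) angle-0 match set are returned with `failed = TRUE`.
#'
#' @param fixed,moving `image_section`s.
#' @param angles candidate angles in degrees (within `[0, 360)`).
#' @param backend keypoint backend name.
#' @param config pipeline configuration.
#' @return list: `angle` (best angle, degrees), `matches` (`match_set` in
#'   original frames, `failed` flag set on failure), `inlier_counts`
#'   (named per angle).
#' @export
rotation_preprocess <- function(fixed, moving, angles = NULL,
                                backend = "harris", config = default_config()) {
  if (is.null(angles)) angles <- config$rotation_angles
  stopifnot(length(angles) >= 1L)
  fixed <- as_section(fixed)
  moving <- as_section(moving)
  fkp <- detect_and_describe(fixed, backend, config)
  counts <- setNames(integer(length(angles)), as.character(angles))
  sets <- vector("list", length(angles))
  for (i in seq_along(angles)) {
    ang <- angles[i]
    rot <- rotate_image(moving$pixels, ang, fill = config$background)
    mp <- attr(rot, "map")
    mkp <- detect_and_describe(image_section(rot, moving$index), backend, config)
    ms <- match_descriptors(fkp, mkp, ratio = config$ratio_thresh)
    rr <- estimate_affine_ransac(ms, config$ransac_threshold,
                                 config$search_iters,
                                 seed = config$seed + 101L * i)
    counts[i] <- rr$n_inliers
    # fold the trial rotation into the match coordinates: back to the
    # original moving frame via the inverse of the recorded forward map
    if (nrow(ms$q) > 0L) {
      dq <- cbind(ms$q[, 1] - mp$c_out[1], ms$q[, 2] - mp$c_out[2])
      q0 <- cbind(mp$R[1, 1] * dq[, 1] + mp$R[2, 1] * dq[, 2] + mp$c_in[1],
                  mp$R[1, 2] * dq[, 1] + mp$R[2, 2] * dq[, 2] + mp$c_in[2])
      ms <- new_match_set(ms$p, q0, ms$dist, angle = ang)
    } else {
      ms$angle <- ang
    }
    sets[[i]] <- ms
  }
  signed <- ((angles + 180) %% 360) - 180
  ord <- order(-counts, abs(signed), seq_along(angles))
  best <- ord[1]
  if (counts[best] < 3L) {
    i0 <- which.min(abs(signed))
    ms <- sets[[i0]]
    ms$angle <- 0
    ms$failed <- TRUE
    return(list(angle = 0, matches = ms, inlier_counts = counts))
  }
  list(angle = angles[best], matches = sets[[best]], inlier_counts = counts)
}
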