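# Sequential orchestration: pairwise registration over consecutive
# sections, composition of per-pair transforms into a common anchor frame,
# and single-resampling reconstruction of the registered stack.
#
# A pair registration stores the hop point-map H_t from slice t+1
# coordinates into slice t coordinates as the pair (affine forward, FFD
# inverse): the affine maps moving to fixed coordinates (x' = A q + t) and
# the stored B-spline field is the backward image map of the non-rigid
# stage, so mapping a point forward requires the field's (numeric)
# inverse, while resampling an image uses the exact field evaluation.

#' Register every consecutive pair of a section sequence
#'
#' For each hop `t -> t+1`: rotation search, RANSAC affine estimation,
#' affine warp of the moving section into the fixed frame, then B-spline
#' non-rigid refinement between the fixed section and the affinely warped
#' moving section.  A failed rotation search or RANSAC leaves the pair with
#' identity transforms and a flag; the pipeline always completes.
#'
#' @param sections ordered list of `image_section`s (>= 2).
#' @param config pipeline configuration, see [default_config()].
#' @param backend keypoint backend name.
#' @param verbose print one progress line per pair.
#' @return list of `pair_registration` objects with fields `fixed_index`,
#'   `moving_index`, `angle`, `affine` (`affine_result`), `field`
#'   (`bspline_field`), `final_loss`, `flags` (character vector).
#' @export
register_consecutive <- function(sections, config = default_config(),
                                 backend = "harris", verbose = FALSE) {
  n <- length(sections)
  if (n < 2L) stop("need at least 2 sections to register")
  sections <- lapply(seq_along(sections), function(i)
    as_section(sections[[i]], i - 1L))
  pairs <- vector("list", n - 1L)
  for (t in seq_len(n - 1L)) {
    fixed <- sections[[t]]
    moving <- sections[[t + 1L]]
    flags <- character(0)
    rot <- rotation_preprocess(fixed, moving, config$rotation_angles,
                               backend, config)
    if (isTRUE(rot$matches$failed)) flags <- c(flags, "rotation_search_failed")
    aff <- estimate_affine_ransac(rot$matches, config$ransac_threshold,
                                  config$ransac_iters,
                                  seed = config$seed + 7L * t)
    field <- bspline_field(fixed$nx, fixed$ny, config$grid_cells,
                           config$spline_degree)
    final_loss <- NA_real_
    if (!aff$success) {
      flags <- c(flags, "ransac_failed")
    } else {
      warped <- warp_affine(moving, aff$transform,
                            output_shape = c(fixed$ny, fixed$nx),
                            fill = config$background)
      opt <- optimize_ffd(fixed, warped, config)
      field <- opt$field
      final_loss <- opt$trace$total[nrow(opt$trace)]
    }
    if (verbose)
      message(sprintf(
        "pair %d->%d: angle %g deg, %d inliers%s", t - 1L, t, rot$angle,
        aff$n_inliers, if (length(flags)) paste0(" [", paste(flags, collapse = ","), "]") else ""))
    pairs[[t]] <- structure(
      list(fixed_index = t - 1L, moving_index = t, angle = rot$angle,
           affine = aff, field = field, final_loss = final_loss,
           flags = flags),
      class = "pair_registration"
    )
  }
  pairs
}

#' @export
print.pair_registration <- function(x, ...) {
  cat(sprintf("<pair_registration %d->%d: angle %g, %d inliers%s>\n",
              x$moving_index, x$fixed_index, x$angle, x$affine$n_inliers,
              if (length(x$flags)) paste0(", flags: ", paste(x$flags, collapse = ","))
              else ""))
  invisible(x)
}

# A composite transform is an ordered list of primitive steps applied
# first-to-last to points; each step is an affine or FFD applied forward or
# inverted.
composite_transform <- function(slice, steps) {
  structure(list(slice = slice, steps = steps), class = "composite_transform")
}

apply_step <- function(step, pts, tol = 0.1) {
  if (step$type == "affine") {
    if (step$fwd) affine_apply(step$tf, pts)
    else affine_apply(affine_invert(step$tf), pts)
  } else {
    if (step$fwd) pts + ffd_displacement(step$field, pts, clamp = TRUE)
    else ffd_invert_points(step$field, pts, max_iter = 10L, tol = tol)
  }
}

#' Map points through a composite transform
#'
#' Applies the chain step by step; FFD inversions use fixed-point iteration
#' (tolerance `tol` pixels).
#'
#' @param composite a `composite_transform` from [compose_to_anchor()].
#' @param pts n x 2 matrix of coordinates in the composite's slice frame.
#' @param tol FFD inversion tolerance in pixels.
#' @return n x 2 matrix of coordinates in the anchor frame.
#' @export
apply_composite <- function(composite, pts, tol = 0.1) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  for (s in composite$steps) pts <- apply_step(s, pts, tol)
  pts
}

#' Invert a composite transform
#'
#' Reverses the chain and flips every step, turning an `s -> anchor` point
#' map into the `anchor -> s` map used for backward image resampling.
#'
#' @param composite a `composite_transform`.
#' @return the inverted `composite_transform`.
#' @export
invert_composite <- function(composite) {
  steps <- rev(lapply(composite$steps, function(s) {
    s$fwd <- !s$fwd
    s
  }))
  composite_transform(composite$slice, steps)
}

#' Compose per-pair transforms into a common anchor frame
#'
#' For a slice `s` after the anchor the composite chains the hop maps
#' `s -> s-1 -> ... -> anchor` (affine forward, then FFD inverted); for a
#' slice before the anchor the inverse hops are chained (FFD forward, then
#' affine inverted).  The anchor slice's composite is the identity (empty
#' chain).  Mapping points through a composite equals sequential
#' application of the hops.
#'
#' @param pairs list of `pair_registration`s covering hops `0..N-2`.
#' @param anchor anchor slice index (0-based); default the middle slice
#'   `floor(N / 2)`.
#' @return list of `composite_transform`s, one per slice `0..N-1`.
#' @export
compose_to_anchor <- function(pairs, anchor = NULL) {
  n <- length(pairs) + 1L
  if (is.null(anchor)) anchor <- n %/% 2L
  if (anchor < 0L || anchor > n - 1L) stop("anchor index out of range")
  for (pr in pairs) {
    if (abs(det(pr$affine$transform$a)) < 1e-12)
      stop(sprintf("hop %d->%d has a non-invertible affine",
                   pr$moving_index, pr$fixed_index))
  }
  hop_fwd <- function(pr) list(
    list(type = "affine", fwd = TRUE, tf = pr$affine$transform),
    list(type = "ffd", fwd = FALSE, field = pr$field)
  )
  hop_inv <- function(pr) list(
    list(type = "ffd", fwd = TRUE, field = pr$field),
    list(type = "affine", fwd = FALSE, tf = pr$affine$transform)
  )
  lapply(0:(n - 1L), function(s) {
    steps <- list()
    if (s > anchor) {
      for (t in seq(s - 1L, anchor, by = -1L))   # hops s-1, ..., anchor
        steps <- c(steps, hop_fwd(pairs[[t + 1L]]))
    } else if (s < anchor) {
      for (t in seq(s, anchor - 1L, by = 1L))    # inverse hops s, ..., anchor-1
        steps <- c(steps, hop_inv(pairs[[t + 1L]]))
    }
    composite_transform(s, steps)
  })
}

#' Resample the registered stack into the anchor frame
#'
#' Each slice is resampled exactly once: the anchor-frame pixel grid is
#' mapped through the full inverted composite chain (exact affine algebra
#' and exact FFD evaluations or numeric inversions on coordinates, never
#' intermediate images) and the slice is sampled a single time by bilinear
#' interpolation.
#'
#' @param sections ordered list of `image_section`s.
#' @param composites list of `composite_transform`s from
#'   [compose_to_anchor()].
#' @param output_shape `c(ny, nx)` of the common frame; defaults to the
#'   anchor slice's shape.
#' @param fill background fill value.
#' @param tol FFD inversion tolerance (px).
#' @return list of registered `image_section`s (the 3D stack, in order).
#' @export
resample_stack <- function(sections, composites, output_shape = NULL,
                           fill = 0, tol = 0.1) {
  if (length(sections) != length(composites))
    stop("need exactly one composite per slice")
  anchor <- which(vapply(composites, function(cp) length(cp$steps) == 0L,
                         logical(1)))[1]
  if (is.null(output_shape)) {
    a <- as_section(sections[[if (is.na(anchor)) 1L else anchor]])
    output_shape <- c(a$ny, a$nx)
  }
  nyo <- output_shape[1]
  nxo <- output_shape[2]
  g <- coord_grids(nyo, nxo)
  grid_pts <- cbind(as.vector(g$x), as.vector(g$y))
  lapply(seq_along(sections), function(i) {
    sec <- as_section(sections[[i]], i - 1L)
    src <- apply_composite(invert_composite(composites[[i]]), grid_pts, tol)
    plane <- function(m) matrix(interp_bilinear(m, src[, 1], src[, 2], fill),
                                nyo, nxo)
    px <- sec$pixels
    out <- if (length(dim(px)) == 3L) {
      array(c(plane(px[, , 1]), plane(px[, , 2]), plane(px[, , 3])),
            dim = c(nyo, nxo, 3L))
    } else {
      plane(px)
    }
    image_section(out, sec$index)
  })
}

#' Map moving-slice landmarks through one pair registration
#'
#' Applies the hop point-map: affine forward, then the numeric inverse of
#' the stored backward B-spline field.
#'
#' @param pair a `pair_registration`.
#' @param pts n x 2 landmark coordinates in the moving (t+1) slice frame.
#' @param tol FFD inversion tolerance (px).
#' @return n x 2 coordinates in the fixed (t) slice frame.
#' @export
map_points_pair <- function(pair, pts, tol = 0.1) {
  pts <- affine_apply(pair$affine$transform, pts)
  ffd_invert_points(pair$field, pts, max_iter = 10L, tol = tol)
}

#' Evaluate a registered sequence against per-slice ground-truth landmarks
#'
#' For every consecutive pair, maps the moving slice's landmarks into the
#' fixed slice's frame through the estimated transforms and evaluates them
#' against the fixed slice's ground-truth landmarks, with the raw moving
#' positions as the initial-error reference.
#'
#' @param landmarks list of n x 2 landmark matrices, one per slice,
#'   row-aligned across slices.
#' @param pairs list of `pair_registration`s.
#' @param dims `c(Nx, Ny)` of the sections.
#' @param pixel_size optional physical pixel size for `AMean_D`.
#' @return list: `pairs` (list of `pair_evaluation`), `summary` (one-row
#'   data frame from [summarize_suite()]), `initial_summary` (same metrics
#'   for the unregistered positions).
#' @export
evaluate_sequence <- function(landmarks, pairs, dims, pixel_size = 1) {
  evals <- vector("list", length(pairs))
  evals0 <- vector("list", length(pairs))
  for (t in seq_along(pairs)) {
    truth <- landmarks[[t]]
    init <- landmarks[[t + 1L]]
    est <- map_points_pair(pairs[[t]], init)
    rownames(est) <- rownames(init)
    evals[[t]] <- evaluate_pair(est, truth, init, dims)
    evals0[[t]] <- evaluate_pair(init, truth, init, dims)
  }
  list(pairs = evals,
       summary = summarize_suite(evals, pixel_size),
       initial_summary = summarize_suite(evals0, pixel_size))
}
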