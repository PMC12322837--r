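# Landmark tables (CSV) and transform files (JSON).
#
# Landmark CSV schema: columns `section`, `landmark_id`, `x`, `y` (header
# required), coordinates 0-based pixels with x = column and y = row,
# origin at the top-left pixel centre — the same convention every module
# of this package uses.

#' Read per-section landmark tables from CSV
#'
#' @param path CSV file with columns `section`, `landmark_id`, `x`, `y`.
#' @return named list (by section index) of n x 2 coordinate matrices with
#'   landmark identifiers as rownames; attribute `"out_of_bounds"` flags
#'   rows with negative coordinates (landmarks outside the image are
#'   allowed, e.g. near torn edges).
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop(sprintf("landmark file does not exist: '%s'", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("section", "landmark_id", "x", "y")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L)
    stop(sprintf("landmark CSV '%s' lacks column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  key <- paste(df$section, df$landmark_id)
  if (anyDuplicated(key))
    stop(sprintf("duplicate (section, landmark_id) in '%s': %s", path,
                 paste(utils::head(unique(key[duplicated(key)]), 5),
                       collapse = "; ")))
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
    stop(sprintf("non-finite landmark coordinates in '%s'", path))
  out <- lapply(split(df, df$section), function(d) {
    m <- cbind(x = as.numeric(d$x), y = as.numeric(d$y))
    rownames(m) <- as.character(d$landmark_id)
    m
  })
  attr(out, "out_of_bounds") <- any(df$x < 0 | df$y < 0)
  out
}

#' Write per-section landmark tables to CSV
#'
#' @param landmarks list of n x 2 coordinate matrices (one per section, in
#'   order), rownames used as landmark identifiers.
#' @param path output CSV path.
#' @export
write_landmarks <- function(landmarks, path) {
  rows <- lapply(seq_along(landmarks), function(i) {
    m <- landmarks[[i]]
    ids <- rownames(m)
    if (is.null(ids)) ids <- paste0("l", seq_len(nrow(m)))
    data.frame(section = i - 1L, landmark_id = ids, x = m[, 1], y = m[, 2])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

TRANSFORM_SCHEMA_VERSION <- "1.0"

affine_to_json <- function(tf) {
  # row-major [a11, a12, tx, a21, a22, ty]
  c(tf$a[1, 1], tf$a[1, 2], tf$t[1], tf$a[2, 1], tf$a[2, 2], tf$t[2])
}

affine_from_json <- function(v) {
  affine2d(matrix(c(v[1], v[4], v[2], v[5]), 2, 2), c(v[3], v[6]))
}

field_to_json <- function(field) {
  list(
    grid_shape = dim(field$cx),                       # rows (y), cols (x)
    cells = field$cells, degree = field$degree,
    nx = field$nx, ny = field$ny,
    # flat displacement list, column-major, x-components then y-components
    displacements = c(as.vector(field$cx), as.vector(field$cy))
  )
}

field_from_json <- function(f) {
  shp <- as.integer(f$grid_shape)
  n <- prod(shp)
  d <- as.numeric(f$displacements)
  if (length(d) != 2L * n)
    stop("transform file is corrupt: displacement count does not match grid shape")
  bspline_field(f$nx, f$ny, as.integer(f$cells), as.integer(f$degree),
                cx = matrix(d[seq_len(n)], shp[1], shp[2]),
                cy = matrix(d[n + seq_len(n)], shp[1], shp[2]))
}

#' Write pair registrations to a JSON transform file
#'
#' The schema stores, per registered pair, the affine as six row-major
#' numbers `[a11, a12, tx, a21, a22, ty]` and the B-spline field as its
#' grid geometry plus a flat displacement list.  Numbers are serialized at
#' 17 significant digits, so a read-back reproduces every value exactly.
#'
#' @param pairs list of `pair_registration`s (see
#'   [register_consecutive()]).
#' @param path output JSON path.
#' @export
write_transform_file <- function(pairs, path) {
  payload <- list(
    schema = "serialreg-transforms",
    version = TRANSFORM_SCHEMA_VERSION,
    pairs = lapply(pairs, function(pr) list(
      fixed_index = pr$fixed_index,
      moving_index = pr$moving_index,
      rotation_deg = pr$angle,
      affine = affine_to_json(pr$affine$transform),
      n_inliers = pr$affine$n_inliers,
      mean_residual = pr$affine$mean_residual,
      success = pr$affine$success,
      bspline = field_to_json(pr$field),
      final_loss = pr$final_loss,
      flags = as.list(pr$flags)
    ))
  )
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a JSON transform file
#'
#' @param path file written by [write_transform_file()].
#' @return list of `pair_registration`s.
#' @export
read_transform_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("transform file does not exist: '%s'", path))
  payload <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
                      error = function(e)
                        stop(sprintf("cannot parse transform file '%s': %s",
                                     path, conditionMessage(e))))
  if (!identical(payload$schema, "serialreg-transforms"))
    stop(sprintf("'%s' is not a serialreg transform file", path))
  if (!identical(payload$version, TRANSFORM_SCHEMA_VERSION))
    stop(sprintf("transform schema version mismatch: file has %s, this package reads %s",
                 payload$version, TRANSFORM_SCHEMA_VERSION))
  lapply(payload$pairs, function(p) {
    res <- structure(
      list(transform = affine_from_json(as.numeric(p$affine)),
           inliers = integer(0),
           n_inliers = as.integer(p$n_inliers),
           mean_residual = if (is.null(p$mean_residual)) NA_real_
           else as.numeric(p$mean_residual),
           success = isTRUE(p$success)),
      class = "affine_result")
    structure(
      list(fixed_index = as.integer(p$fixed_index),
           moving_index = as.integer(p$moving_index),
           angle = as.numeric(p$rotation_deg),
           affine = res,
           field = field_from_json(p$bspline),
           final_loss = if (is.null(p$final_loss)) NA_real_
           else as.numeric(p$final_loss),
           flags = as.character(unlist(p$flags))),
      class = "pair_registration")
  })
}

#' Write the per-pair quality report
#'
#' One CSV row per registered pair: indices, selected rotation angle,
#' inlier count, mean inlier residual, final loss, and flags.
#'
#' @param pairs list of `pair_registration`s.
#' @param path output CSV path.
#' @export
write_quality_report <- function(pairs, path) {
  df <- do.call(rbind, lapply(pairs, function(p) data.frame(
    fixed_index = p$fixed_index, moving_index = p$moving_index,
    rotation_deg = p$angle, n_inliers = p$affine$n_inliers,
    mean_residual = p$affine$mean_residual, final_loss = p$final_loss,
    flags = paste(p$flags, collapse = ";"))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
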