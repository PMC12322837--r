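# Pipeline configuration: one flat list mirrored field-for-field by the
# YAML/JSON config file.  Every default is discoverable via
# `print_config()` (and the CLI's --print-config flag).

#' Default pipeline configuration
#'
#' Returns the full configuration with documented defaults:
#' \describe{
#'   \item{rotation_angles}{candidate rotation angles for the search,
#'     degrees in `[0, 360)`; default 0, 30, ..., 330.}
#'   \item{ransac_threshold}{RANSAC inlier residual threshold (px).}
#'   \item{ransac_iters}{RANSAC hypotheses for the final affine fit.}
#'   \item{search_iters}{cheaper RANSAC hypothesis count used per
#'     candidate angle during the rotation search.}
#'   \item{seed}{base RNG seed for all stochastic steps.}
#'   \item{grid_cells}{B-spline control grid, `c(x_cells, y_cells)` spline
#'     cells over the image.}
#'   \item{spline_degree}{B-spline degree (cubic by default).}
#'   \item{ncc_radius}{local NCC window radius (window side `2r + 1`).}
#'   \item{lambda}{regularization weight.}
#'   \item{alpha}{initial optimizer step: maximum control-point motion per
#'     iteration, px.}
#'   \item{max_iters}{non-rigid iteration cap.}
#'   \item{tol}{stopping tolerance on the loss decrease.}
#'   \item{anchor}{anchor slice index; `NULL` selects the middle slice.}
#'   \item{background}{fill value for out-of-bounds samples.}
#'   \item{ratio_thresh}{descriptor ratio-test threshold.}
#'   \item{max_keypoints}{keypoint cap per image.}
#'   \item{patch_side}{descriptor patch side (px).}
#'   \item{orient_patches}{rotate patches to their dominant gradient
#'     orientation (partial rotation invariance); off by default so that
#'     large rotations are resolved by the explicit rotation search.}
#'   \item{harris_sigma}{integration scale of the corner detector.}
#'   \item{harris_rel_thresh}{corner response threshold, relative to the
#'     image maximum.}
#'   \item{normalize_ncc}{divide the NCC loss by the number of valid
#'     windows (recommended; `FALSE` gives the bare sum).}
#' }
#'
#' @return named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    rotation_angles = seq(0, 330, by = 30),
    ransac_threshold = 3,
    ransac_iters = 2000L,
    search_iters = 500L,
    seed = 42L,
    grid_cells = c(8L, 8L),
    spline_degree = 3L,
    ncc_radius = 4L,
    lambda = 1.0,
    alpha = 1.0,
    max_iters = 500L,
    tol = 1e-6,
    anchor = NULL,
    background = 0,
    ratio_thresh = 0.9,
    max_keypoints = 800L,
    patch_side = 16L,
    orient_patches = FALSE,
    harris_sigma = 1.5,
    harris_rel_thresh = 0.001,
    normalize_ncc = TRUE
  ), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param config a configuration list.
#' @return the validated config (invisibly errors otherwise).
#' @export
validate_config <- function(config) {
  stopifnot(
    length(config$rotation_angles) >= 1L,
    all(config$rotation_angles >= 0 & config$rotation_angles < 360),
    config$ransac_threshold > 0,
    config$ransac_iters >= 1L, config$search_iters >= 1L,
    all(config$grid_cells >= 1L), config$spline_degree >= 1L,
    config$ncc_radius >= 1L, config$lambda >= 0, config$alpha >= 0,
    config$max_iters >= 1L, config$tol > 0,
    config$ratio_thresh > 0, config$max_keypoints >= 1L,
    config$patch_side >= 8L, config$harris_sigma > 0
  )
  invisible(config)
}

#' Read a configuration file (YAML or JSON)
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return `pipeline_config` list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::fromJSON(path)
  else stop(sprintf("config file '%s' must be YAML or JSON", path))
  cfg <- default_config()
  unknown <- setdiff(names(vals), names(cfg))
  if (length(unknown) > 0L)
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  for (k in names(vals)) cfg[[k]] <- vals[[k]]
  cfg$grid_cells <- as.integer(cfg$grid_cells)
  if (length(cfg$grid_cells) == 1L) cfg$grid_cells <- rep(cfg$grid_cells, 2L)
  validate_config(cfg)
  cfg
}

#' Print a configuration as YAML
#'
#' @param config configuration list (default the package defaults).
#' @export
print_config <- function(config = default_config()) {
  cat(yaml::as.yaml(config[!vapply(config, is.null, logical(1))]))
  invisible(config)
}
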