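#' Full registration pipeline on an ordered stack
#'
#' Convenience wrapper chaining the whole pipeline: consecutive pairwise
#' registration, composition to the anchor frame, and single-pass
#' resampling of the registered 3D stack.
#'
#' @param sections ordered list of `image_section`s.
#' @param config pipeline configuration, see [default_config()].
#' @param backend keypoint backend name.
#' @param verbose print per-pair progress.
#' @return list: `pairs` (per-hop `pair_registration`s), `composites`
#'   (per-slice `composite_transform`s), `registered` (list of resampled
#'   `image_section`s), `anchor` (anchor slice index).
#' @export
register_stack <- function(sections, config = default_config(),
                           backend = "harris", verbose = FALSE) {
  validate_config(config)
  pairs <- register_consecutive(sections, config, backend, verbose)
  anchor <- if (is.null(config$anchor)) length(sections) %/% 2L else config$anchor
  composites <- compose_to_anchor(pairs, anchor)
  registered <- resample_stack(sections, composites, fill = config$background)
  list(pairs = pairs, composites = composites, registered = registered,
       anchor = anchor)
}
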