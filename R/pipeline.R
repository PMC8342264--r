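#' Localize microspheres from an aligned block-face stack
#'
#' Runs the full detection-to-atlas chain on one brain: threshold the green
#' channel of every section, resolve each sphere's true section by serial
#' mask subtraction, extract centroids, map them into atlas coordinates
#' through the per-section mappings, assign hemispheres from midline
#' delineations, and look up the anatomic structure of every detection.
#'
#' The stack is expected to be rotated/aligned already (see
#' [rotate_stack_by_midline()] and [rigid_align_stack()]); set
#' `align = TRUE` to run rigid alignment here.
#'
#' @param stack A [blockface_stack].
#' @param mappings Per-section atlas mappings (tibble from
#'   [propagate_anchors()] or equivalent, one row per section).
#' @param annotation An [annotation_volume].
#' @param ontology An [atlas_ontology].
#' @param midlines Optional midline polylines (see [assign_hemisphere()]).
#' @param align Run [rigid_align_stack()] before detection (default FALSE).
#' @param threshold_low Segmentation threshold (default 140).
#' @param diameter_um Nominal sphere diameter, 20 um; sets the default
#'   component match radius (one diameter) and area band.
#' @param visibility_depth_um Depth through which a sphere stays visible
#'   (default 400 um); with the section thickness this bounds how many
#'   consecutive sections one sphere may span.
#' @param match_radius_px Override the component match radius in pixels.
#' @param subtract_mode `"component"` or `"pixel"`, see
#'   [resolve_z_by_serial_subtraction()].
#' @param ... Passed to [extract_centroids()].
#' @return Tibble of detections: `id`, `section_index`, `x_px`, `y_px`,
#'   `area_px2`, `equiv_diameter_um`, `merged`, `hemisphere`, `ax`, `ay`,
#'   `az`, `region_id`, `region_name`, `region_level`. Unaccounted
#'   detections have `NA` region columns.
#' @export
localize_microspheres <- function(stack, mappings, annotation, ontology,
                                  midlines = NULL, align = FALSE,
                                  threshold_low = 140, diameter_um = 20,
                                  visibility_depth_um = 400,
                                  match_radius_px = NULL,
                                  subtract_mode = c("component", "pixel"),
                                  ...) {
  subtract_mode <- match.arg(subtract_mode)
  if (align) {
    stack <- rigid_align_stack(stack)$stack
  }
  n <- length(stack$sections)
  stopifnot(nrow(mappings) == n)
  d <- section_dim(stack$sections[[1]])
  match_radius_px <- match_radius_px %||% (diameter_um / stack$pixel_size_um)
  max_chain <- ceiling(visibility_depth_um / stack$section_thickness_um)

  masks <- threshold_stack(stack, low = threshold_low)
  final <- resolve_z_by_serial_subtraction(
    masks, match_radius_px = match_radius_px, mode = subtract_mode,
    max_chain_sections = max_chain)
  det <- extract_centroids(final, stack$pixel_size_um,
                           diameter_um = diameter_um, ...)
  if (nrow(det) == 0L) {
    det$hemisphere <- character(0)
    det$ax <- det$ay <- det$az <- numeric(0)
    det$region_id <- integer(0)
    det$region_name <- character(0)
    det$region_level <- integer(0)
    return(det)
  }
  det$hemisphere <- assign_hemisphere(midlines, det)
  m <- mappings[match(det$section_index, mappings$section_index), ,
                drop = FALSE]
  coords <- pixel_to_atlas(m, det$x_px, det$y_px,
                           width = d["width"], height = d["height"])
  det <- dplyr::bind_cols(det, coords)
  det$region_id <- assign_region(coords, annotation)
  nm <- attr(ontology, "node_name")
  lv <- ontology_level(ontology)
  det$region_name <- unname(nm[as.character(det$region_id)])
  det$region_level <- unname(lv[as.character(det$region_id)])
  det
}

#' Write detections to CSV
#'
#' @param detections Tibble from [localize_microspheres()] or
#'   [extract_centroids()].
#' @param path Output CSV path.
#' @param source `"auto"` or `"manual"`, recorded in a `source` column.
#' @export
write_detections_csv <- function(detections, path, source = "auto") {
  detections$source <- source
  utils::write.csv(detections, path, row.names = FALSE)
  invisible(path)
}
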