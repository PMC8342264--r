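#' Atlas annotation volume
#'
#' A 3D integer label volume with isotropic voxels. Voxel value 0 means
#' "outside the brain"; every other label must be an ontology structure id.
#' Atlas coordinates throughout the package are continuous, 0-based voxel
#' indices: voxel `(i, j, k)` (0-based) covers the half-open cube
#' `[i, i+1) x [j, j+1) x [k, k+1)`. The third axis is anterior-posterior
#' (the cutting axis of a coronal series).
#'
#' @param labels 3D integer array of structure labels.
#' @param voxel_size_um Isotropic voxel edge length in micrometres.
#' @return An `annotation_volume` object.
#' @export
annotation_volume <- function(labels, voxel_size_um) {
  if (length(dim(labels)) != 3L || any(dim(labels) < 1L)) {
    stop("`labels` must be a 3D array with positive dimensions", call. = FALSE)
  }
  check_positive_scalar(voxel_size_um, "voxel_size_um")
  structure(
    list(labels = labels, voxel_size_um = voxel_size_um),
    class = "annotation_volume"
  )
}

#' @export
print.annotation_volume <- function(x, ...) {
  cat(sprintf("<annotation_volume> %s voxels @ %g um, %d labels\n",
              paste(dim(x$labels), collapse = " x "), x$voxel_size_um,
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

#' Read / write an annotation volume as NIfTI
#'
#' The voxel size is carried in the NIfTI header (`pixdim`, mm).
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @return [read_annotation_nifti()]: an [annotation_volume].
#' @export
read_annotation_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  vox_mm <- RNifti::pixdim(img)[1]
  annotation_volume(array(as.integer(round(img)), dim = dim(img)),
                    voxel_size_um = vox_mm * 1000)
}

#' @rdname read_annotation_nifti
#' @param annotation An [annotation_volume].
#' @export
write_annotation_nifti <- function(annotation, path) {
  img <- RNifti::asNifti(annotation$labels)
  RNifti::pixdim(img) <- rep(annotation$voxel_size_um / 1000, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Look up the structure at atlas coordinates
#'
#' Nearest-voxel lookup: the continuous 0-based coordinate is floored to its
#' containing voxel. Coordinates outside the volume, or falling on label 0,
#' are unaccounted and return `NA` -- these are the "unaccounted
#' microspheres" of a region report.
#'
#' @param coords A matrix or data frame with columns `ax`, `ay`, `az`
#'   (continuous 0-based voxel coordinates), or a length-3 vector.
#' @param annotation An [annotation_volume].
#' @return Integer vector of structure ids, `NA` where unaccounted.
#' @export
assign_region <- function(coords, annotation) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3)
  if (is.data.frame(coords)) {
    coords <- as.matrix(coords[, c("ax", "ay", "az")])
  }
  stopifnot(ncol(coords) == 3)
  d <- dim(annotation$labels)
  idx <- floor(coords) + 1
  inside <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
    idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  inside[is.na(inside)] <- FALSE
  out <- rep(NA_integer_, nrow(coords))
  if (any(inside)) {
    out[inside] <- annotation$labels[idx[inside, , drop = FALSE]]
  }
  out[!is.na(out) & out == 0L] <- NA_integer_
  out
}

#' Structure volumes from the annotation
#'
#' A structure's volume includes all voxels labelled with the structure
#' itself or any of its descendants (both hemispheres).
#'
#' @param annotation An [annotation_volume].
#' @param ontology An [atlas_ontology].
#' @return Tibble `id`, `name`, `level`, `n_voxels`, `volume_mm3` in
#'   ontology order; `n_voxels` is cumulative over descendants.
#' @export
region_volumes <- function(annotation, ontology) {
  labs <- as.vector(annotation$labels)
  labs <- labs[labs != 0L]
  bad <- setdiff(unique(labs), ontology$id)
  if (length(bad)) {
    stop("annotation labels missing from ontology: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tab <- table(labs)
  agg <- aggregate_counts(
    ontology,
    tibble::tibble(id = as.integer(names(tab)), n = as.numeric(tab))
  )
  vox_mm3 <- (annotation$voxel_size_um / 1000)^3
  tibble::tibble(
    id = agg$id, name = agg$name, level = agg$level,
    n_voxels = agg$n_total,
    volume_mm3 = agg$n_total * vox_mm3
  )
}

#' Microsphere density of a region
#'
#' @param count Number of spheres in the region.
#' @param volume_mm3 Region volume in mm^3.
#' @return Density in spheres per mm^3. A zero-volume region with a nonzero
#'   count is an error; with zero count the density is 0.
#' @export
region_density <- function(count, volume_mm3) {
  bad <- volume_mm3 <= 0 & count > 0
  if (any(bad, na.rm = TRUE)) {
    stop("nonzero count in zero-volume region", call. = FALSE)
  }
  out <- ifelse(volume_mm3 > 0, count / volume_mm3, 0)
  out
}
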