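#' Automatic ROI placement in the phantom tracts
#'
#' Places one disk ROI at the in-plane centroid of the projection tract and
#' one at the centroid of the association tract, on a single axial slice
#' (the phantom analog of the lateral-ventricle-body level; defaults to the
#' mid slice of the tract slab). Placement is deterministic. Errors if a
#' tract is too thin to contain the disk.
#'
#' @param spec a [phantom_spec()].
#' @param diameter ROI diameter in mm (default 5, the clinical ALPS
#'   convention).
#' @param slice_index axial (z) slice index; default the mid slice of the
#'   projection tract slab.
#'
#' @return Named list of two `roi_spec` objects, `projection` and
#'   `association`.
#' @export
place_rois_auto <- function(spec, diameter = 5,
                            slice_index = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(slice_index)) {
    zr <- spec$regions$projection$z
    slice_index <- as.integer(round(mean(zr)))
  }
  out <- lapply(c(projection = "projection", association = "association"),
                function(nm) {
    r <- spec$regions[[nm]]
    if (slice_index < r$z[1] || slice_index > r$z[2]) {
      stop(sprintf("ROI placement: slice %d outside tract '%s' (z %d..%d)",
                   slice_index, nm, r$z[1], r$z[2]))
    }
    center <- c(round(mean(r$x)), round(mean(r$y)))
    ext_mm <- c(diff(r$x) + 1, diff(r$y) + 1) * spec$voxel_size[1:2]
    if (any(ext_mm < diameter)) {
      stop(sprintf(
        "ROI placement: tract '%s' (%.1f x %.1f mm in plane) cannot contain a %.1f mm disk",
        nm, ext_mm[1], ext_mm[2], diameter))
    }
    roi_spec(fiber_class = nm, center = center, diameter = diameter,
             slice_index = slice_index)
  })
  out
}

#' Specify a disk ROI on an axial slice
#'
#' @param fiber_class "projection" or "association".
#' @param center integer 2-vector, in-plane (x, y) voxel coordinates of the
#'   disk center.
#' @param diameter disk diameter in mm (> 0).
#' @param slice_index axial (z) slice index.
#' @param hemisphere hemisphere tag (single left-hemisphere measurement by
#'   default, matching the clinical procedure).
#'
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(fiber_class, center, diameter = 5, slice_index = 1L,
                     hemisphere = "left") {
  fiber_class <- match.arg(fiber_class, c("projection", "association"))
  stopifnot(diameter > 0, length(center) == 2L)
  structure(list(fiber_class = fiber_class,
                 center = as.integer(round(center)),
                 diameter = diameter,
                 slice_index = as.integer(slice_index),
                 hemisphere = hemisphere),
            class = "roi_spec")
}

#' Rasterize a disk ROI to a voxel mask
#'
#' A voxel on the ROI slice is included iff its in-plane center lies within
#' diameter/2 of the ROI center (half-in voxels excluded). The center voxel
#' is always included, so the mask is never empty; it is symmetric under
#' in-plane reflection about the center.
#'
#' @param roi a [roi_spec()].
#' @param grid_shape integer 3-vector, voxels per axis.
#' @param voxel_size numeric 3-vector, mm per voxel.
#'
#' @return Logical array (nx, ny, nz).
#' @export
roi_mask <- function(roi, grid_shape, voxel_size) {
  stopifnot(inherits(roi, "roi_spec"), length(grid_shape) == 3L,
            length(voxel_size) == 3L)
  mask <- array(FALSE, dim = grid_shape)
  if (roi$slice_index < 1 || roi$slice_index > grid_shape[3]) {
    stop("roi_mask: slice index outside grid")
  }
  ix <- seq_len(grid_shape[1])
  iy <- seq_len(grid_shape[2])
  dx <- (ix - roi$center[1]) * voxel_size[1]
  dy <- (iy - roi$center[2]) * voxel_size[2]
  inplane <- outer(dx^2, dy^2, "+") <= (roi$diameter / 2)^2
  inplane[roi$center[1], roi$center[2]] <- TRUE   # center voxel guaranteed
  mask[, , roi$slice_index] <- inplane
  mask
}

#' Mean per-axis diffusivities over a voxel mask
#'
#' Returns the arithmetic means of the diagonal tensor components Dxx, Dyy,
#' Dzz over the masked voxels — raw diffusivities along the image axes (as
#' the ALPS formula consumes), not eigenvalues.
#'
#' @param field a [tensor_field()].
#' @param mask logical array matching the field grid.
#'
#' @return Named numeric vector `c(dxx, dyy, dzz)` in mm^2/s, with attribute
#'   `n_voxels`.
#' @export
extract_axis_diffusivities <- function(field, mask) {
  stopifnot(inherits(field, "tensor_field"))
  dm <- dim(field$D)[1:3]
  if (!all(dim(mask) == dm)) stop("mask dimensions do not match field")
  idx <- which(as.logical(mask))
  if (length(idx) == 0L) stop("extract_axis_diffusivities: empty mask")
  M <- tensor_matrix(field)
  out <- c(dxx = mean(M[idx, 1]), dyy = mean(M[idx, 2]), dzz = mean(M[idx, 3]))
  attr(out, "n_voxels") <- length(idx)
  out
}
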