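#' Specify the three-tract digital phantom
#'
#' The phantom mirrors the ALPS measurement geometry at the level of the
#' lateral ventricle body: projection fibers run along the image z-axis,
#' association fibers along y, subcortical fibers along x, and the
#' perivascular space along x, perpendicular to the first two. Each tract is
#' an axis-aligned cuboid of axis-aligned (diagonal) tensors embedded in an
#' isotropic background.
#'
#' @param grid_shape integer 3-vector, voxels per axis (default 48 x 48 x 24 —
#'   a reduced-FOV analog of a 128 x 128 in-plane matrix).
#' @param voxel_size numeric 3-vector, mm per voxel (default 1.72 x 1.72 x 3,
#'   echoing a 220 mm FOV / 128 matrix in plane and 3 mm slices).
#' @param regions named list of tract cuboids `projection`, `association`,
#'   `subcortical`, each a list with integer vectors `x`, `y`, `z` of
#'   (first, last) voxel indices (1-based, inclusive). Tracts must be
#'   pairwise disjoint.
#' @param d_parallel diffusivity along each tract's fiber axis, mm^2/s.
#' @param d_perp diffusivity across the fibers (non-perivascular), mm^2/s.
#' @param d_background isotropic background diffusivity, mm^2/s.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 24L),
                         voxel_size = c(1.72, 1.72, 3),
                         regions = default_phantom_regions(),
                         d_parallel = 1.4e-3,
                         d_perp = 0.4e-3,
                         d_background = 0.8e-3) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            length(voxel_size) == 3L, all(voxel_size > 0),
            d_parallel > 0, d_perp > 0, d_background > 0)
  need <- c("projection", "association", "subcortical")
  if (!all(need %in% names(regions))) {
    stop("regions must name tracts: ", paste(need, collapse = ", "))
  }
  for (nm in need) {
    r <- regions[[nm]]
    for (ax in 1:3) {
      rng <- r[[c("x", "y", "z")[ax]]]
      if (length(rng) != 2L || rng[1] > rng[2] || rng[1] < 1 ||
          rng[2] > grid_shape[ax]) {
        stop(sprintf("region '%s' %s-range out of grid bounds", nm,
                     c("x", "y", "z")[ax]))
      }
    }
  }
  overlap <- function(a, b) {
    all(vapply(c("x", "y", "z"),
               function(ax) a[[ax]][1] <= b[[ax]][2] && b[[ax]][1] <= a[[ax]][2],
               logical(1)))
  }
  pairs <- utils::combn(need, 2)
  for (k in seq_len(ncol(pairs))) {
    if (overlap(regions[[pairs[1, k]]], regions[[pairs[2, k]]])) {
      stop(sprintf("regions '%s' and '%s' overlap", pairs[1, k], pairs[2, k]))
    }
  }
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 regions = regions, d_parallel = d_parallel, d_perp = d_perp,
                 d_background = d_background),
            class = "phantom_spec")
}

#' Default tract layout for the 48 x 48 x 24 grid
#'
#' Three disjoint cuboids side by side along x (a single left-hemisphere
#' tract pair plus the subcortical band), each spanning the central slab so
#' a 5 mm disk ROI fits comfortably inside any tract on the mid slice.
#'
#' @return Named list of tract cuboids suitable for [phantom_spec()].
#' @export
default_phantom_regions <- function() {
  list(projection  = list(x = c(6L, 15L),  y = c(14L, 33L), z = c(5L, 20L)),
       association = list(x = c(20L, 29L), y = c(14L, 33L), z = c(5L, 20L)),
       subcortical = list(x = c(34L, 43L), y = c(14L, 33L), z = c(5L, 20L)))
}

#' Invert the ALPS formula for the perivascular diffusivity
#'
#' The ALPS index is mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc).
#' With a common perivascular (x-axis) diffusivity d in both tracts the
#' numerator is d, so the d that yields a target index is
#' `target * mean(dyy_proj, dzz_assoc)`. Plugging the result back into
#' [compute_alps()] reproduces the target exactly.
#'
#' @param target_alps desired ALPS index (dimensionless, > 0).
#' @param dyy_proj y-axis diffusivity of the projection tract, mm^2/s.
#' @param dzz_assoc z-axis diffusivity of the association tract, mm^2/s.
#'
#' @return Perivascular x-axis diffusivity in mm^2/s.
#' @export
#' @examples
#' solve_perivascular_dxx(1.45, 0.4e-3, 0.4e-3)  # 0.58e-3
solve_perivascular_dxx <- function(target_alps, dyy_proj, dzz_assoc) {
  if (target_alps <= 0 || dyy_proj <= 0 || dzz_assoc <= 0) {
    stop("solve_perivascular_dxx: all inputs must be positive")
  }
  target_alps * mean(c(dyy_proj, dzz_assoc))
}

#' Build a ground-truth tensor field with a prescribed ALPS index
#'
#' Fills each tract with a diagonal tensor whose largest eigenvalue lies on
#' the fiber axis (projection: z, association: y, subcortical: x) and sets
#' the x-axis diffusivity of the projection and association tracts via
#' [solve_perivascular_dxx()] so the analytic region-mean ALPS index equals
#' `alps_true` exactly. Background voxels are isotropic.
#'
#' @param spec a [phantom_spec()].
#' @param alps_true target ground-truth ALPS index (> 0). Targets that would
#'   require a perivascular diffusivity at or above `d_parallel` are rejected
#'   (the fiber axis would no longer be the principal axis).
#'
#' @return A `tensor_field` (see [tensor_field()]) carrying the spec and the
#'   analytic truth in attributes.
#' @export
make_phantom <- function(spec, alps_true) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (alps_true <= 0) stop("alps_true must be positive")
  d_peri <- solve_perivascular_dxx(alps_true, spec$d_perp, spec$d_perp)
  if (d_peri >= spec$d_parallel) {
    warning(sprintf(paste0(
      "alps_true = %.3g needs perivascular Dxx = %.3g mm^2/s >= d_parallel ",
      "= %.3g mm^2/s: the fiber axis would no longer be the principal axis"),
      alps_true, d_peri, spec$d_parallel))
    stop("make_phantom: target ALPS incompatible with tract anisotropy")
  }
  dm <- spec$grid_shape
  D <- array(0, dim = c(dm, 6L))
  for (k in 1:3) D[, , , k] <- spec$d_background
  fill <- function(D, region, diag3) {
    xs <- region$x[1]:region$x[2]
    ys <- region$y[1]:region$y[2]
    zs <- region$z[1]:region$z[2]
    for (k in 1:3) D[xs, ys, zs, k] <- diag3[k]
    D
  }
  # (Dxx, Dyy, Dzz); off-diagonals stay 0 (axis-aligned fibers)
  D <- fill(D, spec$regions$projection,  c(d_peri, spec$d_perp, spec$d_parallel))
  D <- fill(D, spec$regions$association, c(d_peri, spec$d_parallel, spec$d_perp))
  D <- fill(D, spec$regions$subcortical, c(spec$d_parallel, spec$d_perp, spec$d_perp))
  tf <- tensor_field(D, spec$voxel_size)
  attr(tf, "phantom_spec") <- spec
  attr(tf, "alps_true") <- alps_true
  tf
}

#' Construct a tensor field
#'
#' @param D numeric array of dimension (nx, ny, nz, 6) holding the symmetric
#'   tensor components (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) in mm^2/s.
#' @param voxel_size numeric 3-vector, mm.
#'
#' @return An object of class `tensor_field`.
#' @export
tensor_field <- function(D, voxel_size) {
  D <- as.array(D)
  if (length(dim(D)) != 4L || dim(D)[4] != 6L) {
    stop("D must be an (nx, ny, nz, 6) array")
  }
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  structure(list(D = D, voxel_size = as.numeric(voxel_size)),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  dm <- dim(x$D)
  cat(sprintf("tensor_field: %d x %d x %d voxels, voxel %s mm\n",
              dm[1], dm[2], dm[3], paste(x$voxel_size, collapse = " x ")))
  invisible(x)
}

# flatten the (nx,ny,nz,6) component array into (nvox, 6)
tensor_matrix <- function(field) {
  dm <- dim(field$D)
  matrix(field$D, nrow = prod(dm[1:3]), ncol = 6L)
}
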