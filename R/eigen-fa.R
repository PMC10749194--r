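#' Voxelwise eigensystem of a tensor field
#'
#' Eigenvalues are returned in descending order with orthonormal
#' eigenvectors. Negative eigenvalues (noise-driven) are clamped to zero;
#' the number of clamped voxels is recorded in the `n_clamped` attribute and
#' reported via a message.
#'
#' @param field a [tensor_field()].
#'
#' @return An object of class `eigen_system`: list with `values`
#'   (nx, ny, nz, 3 array, descending lambda1..3 in mm^2/s) and `vectors`
#'   (nx, ny, nz, 3, 3 array; `vectors[..., , k]` is the unit eigenvector of
#'   lambda_k).
#' @export
tensor_eigensystem <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  dm <- dim(field$D)[1:3]
  M <- tensor_matrix(field)
  nvox <- nrow(M)
  vals <- matrix(0, nvox, 3L)
  vecs <- array(0, dim = c(nvox, 3L, 3L))
  for (v in seq_len(nvox)) {
    Dv <- matrix(c(M[v, 1], M[v, 4], M[v, 5],
                   M[v, 4], M[v, 2], M[v, 6],
                   M[v, 5], M[v, 6], M[v, 3]), 3L, 3L)
    e <- eigen(Dv, symmetric = TRUE)   # descending by default
    vals[v, ] <- e$values
    vecs[v, , ] <- e$vectors
  }
  n_clamped <- sum(apply(vals < -1e-15, 1, any))
  if (n_clamped > 0) {
    message(sprintf("tensor_eigensystem: clamped negative eigenvalues in %d voxels",
                    n_clamped))
  }
  vals[vals < 0] <- 0
  structure(list(values = array(vals, dim = c(dm, 3L)),
                 vectors = array(vecs, dim = c(dm, 3L, 3L))),
            class = "eigen_system", n_clamped = n_clamped)
}

#' Fractional anisotropy map
#'
#' FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||, in [0, 1];
#' defined as 0 for the zero tensor (0/0 convention) and for perfectly
#' isotropic voxels.
#'
#' @param eigs an `eigen_system` from [tensor_eigensystem()].
#'
#' @return Numeric array (nx, ny, nz) of FA values.
#' @export
fractional_anisotropy <- function(eigs) {
  stopifnot(inherits(eigs, "eigen_system"))
  dm <- dim(eigs$values)[1:3]
  L <- matrix(eigs$values, ncol = 3L)
  lbar <- rowMeans(L)
  ss <- rowSums(L^2)
  dev <- rowSums((L - lbar)^2)
  fa <- ifelse(ss > 0, sqrt(1.5 * dev / ss), 0)
  array(pmin(pmax(fa, 0), 1), dim = dm)
}

#' Directionally-encoded color FA map
#'
#' Standard DEC convention: channel c = FA * |e1 . axis_c| with red = x,
#' green = y, blue = z, clipped to [0, 1]. In the phantom the projection
#' tract (z fibers) renders blue, association (y) green, subcortical (x)
#' red.
#'
#' @param eigs an `eigen_system`.
#' @param fa FA array from [fractional_anisotropy()] (computed if missing).
#'
#' @return Numeric array (nx, ny, nz, 3) of RGB channels in [0, 1].
#' @export
color_fa <- function(eigs, fa = fractional_anisotropy(eigs)) {
  stopifnot(inherits(eigs, "eigen_system"))
  dm <- dim(eigs$values)[1:3]
  e1 <- array(eigs$vectors[, , , , 1L], dim = c(dm, 3L))
  rgb <- abs(e1) * as.vector(fa)
  array(pmin(pmax(rgb, 0), 1), dim = c(dm, 3L))
}
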