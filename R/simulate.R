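#' Simulate diffusion-weighted volumes from a tensor field
#'
#' Forward model: the mono-exponential Stejskal-Tanner signal
#' S_i = S0 * exp(-b_i * g_i' D g_i) per voxel and gradient entry. With
#' `snr = NULL` the analytic signals are returned exactly; otherwise Rician
#' noise is added (magnitude of a complex Gaussian disturbance with
#' per-channel sigma = s0 / snr, the usual magnitude-MRI model), seeded and
#' reproducible.
#'
#' @param field a [tensor_field()].
#' @param gtab a [gradient_table()].
#' @param s0 unweighted (b = 0) signal amplitude, arbitrary units (> 0).
#' @param snr signal-to-noise ratio on the b0 signal, or `NULL` for
#'   noiseless simulation. Default 30, typical of a clinical 3 T DTI scan.
#' @param seed integer seed for the noise draw (ignored when `snr = NULL`).
#'
#' @return An object of class `dwi_volume`: list with `data`
#'   (nx, ny, nz, nvol array), `voxel_size`, and the gradient table.
#' @export
simulate_dwi <- function(field, gtab, s0 = 1000, snr = 30, seed = 0L) {
  stopifnot(inherits(field, "tensor_field"), inherits(gtab, "gradient_table"))
  if (s0 <= 0) stop("s0 must be positive")
  if (!is.null(snr) && snr <= 0) stop("snr must be positive or NULL")
  dm <- dim(field$D)[1:3]
  X <- tensor_design(gtab)               # nvol x 6
  M <- tensor_matrix(field)              # nvox x 6
  S <- s0 * exp(-tcrossprod(M, X))       # nvox x nvol
  if (!is.null(snr)) {
    sigma <- s0 / snr
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    n <- length(S)
    S <- sqrt((S + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  }
  dwi_volume(array(S, dim = c(dm, length(gtab$bvals))), field$voxel_size, gtab)
}

#' Construct a 4-D diffusion-weighted volume
#'
#' @param data numeric array (nx, ny, nz, nvol), one 3-D volume per gradient
#'   entry.
#' @param voxel_size numeric 3-vector, mm.
#' @param gtab matching [gradient_table()] (nvol entries).
#'
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(data, voxel_size, gtab) {
  data <- as.array(data)
  if (length(dim(data)) != 4L) stop("data must be a 4-D array")
  stopifnot(inherits(gtab, "gradient_table"))
  if (dim(data)[4] != length(gtab$bvals)) {
    stop(sprintf("volume count (%d) does not match gradient entries (%d)",
                 dim(data)[4], length(gtab$bvals)))
  }
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 gtab = gtab), class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  dm <- dim(x$data)
  cat(sprintf("dwi_volume: %d x %d x %d voxels, %d volumes\n",
              dm[1], dm[2], dm[3], dm[4]))
  invisible(x)
}
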