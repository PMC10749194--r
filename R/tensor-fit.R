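#' Fit diffusion tensors by log-linear least squares
#'
#' Per voxel, solves -ln(S_i / S0) = b_i * g_i' D g_i in the six tensor
#' components by ordinary least squares on the design
#' b * (gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz). S0 is the mean of the
#' b = 0 volumes. Signals are floored at `eps_frac * S0` before the log so
#' noise-driven nonpositive magnitudes cannot produce -Inf. The estimator is
#' exact on noiseless positive signals.
#'
#' @param dwi a [dwi_volume()].
#' @param gtab gradient table; defaults to the one carried by `dwi`.
#' @param mask optional logical array (nx, ny, nz); voxels outside get zero
#'   tensors.
#' @param eps_frac signal floor as a fraction of S0 (default 1e-6).
#'
#' @return A [tensor_field()] of fitted tensors.
#' @export
fit_tensor <- function(dwi, gtab = dwi$gtab, mask = NULL, eps_frac = 1e-6) {
  stopifnot(inherits(dwi, "dwi_volume"), inherits(gtab, "gradient_table"))
  dm <- dim(dwi$data)
  if (dm[4] != length(gtab$bvals)) {
    stop(sprintf("volume count (%d) does not match gradient entries (%d)",
                 dm[4], length(gtab$bvals)))
  }
  is_b0 <- gtab$bvals == 0
  if (!any(is_b0)) stop("fit requires at least one b = 0 volume")
  if (sum(!is_b0) < 6) stop("fit requires at least 6 weighted directions")
  X <- tensor_design(gtab)[!is_b0, , drop = FALSE]   # n_dwi x 6
  qrX <- qr(X)
  if (qrX$rank < 6L) {
    stop("rank-deficient gradient design (rank ", qrX$rank,
         " < 6): directions are coplanar or degenerate")
  }
  nvox <- prod(dm[1:3])
  S <- matrix(dwi$data, nrow = nvox)                 # nvox x nvol
  keep <- if (is.null(mask)) rep(TRUE, nvox) else {
    stopifnot(all(dim(mask) == dm[1:3]))
    as.logical(mask)
  }
  s0 <- rowMeans(S[keep, is_b0, drop = FALSE])
  Sw <- S[keep, !is_b0, drop = FALSE]
  Sw <- pmax(Sw, eps_frac * pmax(s0, .Machine$double.eps))
  Y <- -log(Sw / s0)                                 # nvox_in x n_dwi
  # normal-equations-free solve via the QR of X: coef' = qr.solve per column
  coefs <- t(qr.coef(qrX, t(Y)))                     # nvox_in x 6
  M <- matrix(0, nvox, 6L)
  M[keep, ] <- coefs
  tensor_field(array(M, dim = c(dm[1:3], 6L)), dwi$voxel_size)
}
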