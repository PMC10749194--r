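#' Diffusion gradient tables
#'
#' A gradient table pairs each acquired volume with a diffusion weighting
#' (b-value, s/mm^2) and a unit gradient direction. Entries with b = 0 carry
#' the zero vector.
#'
#' @param bvals numeric vector of b-values in s/mm^2.
#' @param bvecs 3 x n numeric matrix of gradient directions (columns).
#'
#' @return An object of class `gradient_table`: a list with elements
#'   `bvals` (length n) and `bvecs` (3 x n matrix).
#' @export
gradient_table <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  dimnames(bvecs) <- NULL
  if (nrow(bvecs) != 3L) stop("bvecs must be a 3 x n matrix")
  if (length(bvals) != ncol(bvecs)) {
    stop(sprintf("gradient table length mismatch: %d b-values vs %d b-vectors",
                 length(bvals), ncol(bvecs)))
  }
  if (any(bvals < 0)) stop("b-values must be nonnegative")
  nrm <- sqrt(colSums(bvecs^2))
  dwi <- bvals > 0
  if (any(abs(nrm[dwi] - 1) > 1e-6)) {
    warning("non-unit b-vectors for b > 0 entries; renormalizing")
    bvecs[, dwi] <- sweep(bvecs[, dwi, drop = FALSE], 2, nrm[dwi], "/")
  }
  if (any(nrm[!dwi] > 1e-12)) bvecs[, !dwi] <- 0
  structure(list(bvals = bvals, bvecs = bvecs), class = "gradient_table")
}

#' Build an acquisition scheme with near-uniform directions
#'
#' Generates `n_b0` unweighted volumes followed by `n_directions` diffusion
#' directions at b-value `b`, spread over the half-sphere by a deterministic
#' Fibonacci spiral. The scheme mimics a 30-direction, b = 1000 s/mm^2
#' single-shell clinical protocol. The result depends only on the arguments:
#' `seed` is accepted for interface stability but the spiral itself is
#' deterministic, so repeated calls are identical.
#'
#' @param n_directions number of diffusion-weighted directions (>= 6; the
#'   diffusion tensor has six free parameters).
#' @param b b-value in s/mm^2 for the weighted volumes (default 1000).
#' @param n_b0 number of b = 0 volumes (default 1).
#' @param seed unused; retained so acquisition configs can carry a seed field.
#'
#' @return A [gradient_table()] with `n_b0 + n_directions` entries, b0 first.
#' @export
#' @examples
#' gt <- build_gradient_table(30, 1000, 1)
#' length(gt$bvals)  # 31
build_gradient_table <- function(n_directions, b = 1000, n_b0 = 1, seed = 0L) {
  if (n_directions < 6) {
    stop("invalid scheme: at least 6 directions are needed to determine the ",
         "6 free tensor parameters (got ", n_directions, ")")
  }
  if (b <= 0) stop("b must be positive for the weighted shell")
  i <- seq_len(n_directions)
  # Fibonacci half-shell: z uniform in (0, 1), golden-angle azimuth
  z <- (i - 0.5) / n_directions
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- rbind(r * cos(phi), r * sin(phi), z)
  bvecs <- cbind(matrix(0, 3, n_b0), dirs)
  gradient_table(c(rep(0, n_b0), rep(b, n_directions)), bvecs)
}

#' @export
print.gradient_table <- function(x, ...) {
  cat(sprintf("gradient_table: %d volumes (%d b0, %d weighted), b = %s s/mm^2\n",
              length(x$bvals), sum(x$bvals == 0), sum(x$bvals > 0),
              paste(unique(x$bvals[x$bvals > 0]), collapse = ", ")))
  invisible(x)
}

# 6-column tensor design row for one (b, g): b * (gx^2, gy^2, gz^2,
# 2 gx gy, 2 gx gz, 2 gy gz), matching the (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
# component order used throughout.
tensor_design <- function(gtab) {
  g <- gtab$bvecs
  b <- gtab$bvals
  cbind(g[1, ]^2, g[2, ]^2, g[3, ]^2,
        2 * g[1, ] * g[2, ], 2 * g[1, ] * g[3, ], 2 * g[2, ] * g[3, ]) * b
}
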