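# Small phantom used by most unit tests: same tract layout logic as the
# default, scaled to a 24 x 24 x 12 grid so full-grid operations stay fast.
small_phantom_spec <- function(...) {
  phantom_spec(
    grid_shape = c(24L, 24L, 12L),
    voxel_size = c(1.72, 1.72, 3),
    regions = list(
      projection  = list(x = c(3L, 8L),   y = c(7L, 17L), z = c(3L, 10L)),
      association = list(x = c(10L, 15L), y = c(7L, 17L), z = c(3L, 10L)),
      subcortical = list(x = c(17L, 22L), y = c(7L, 17L), z = c(3L, 10L))),
    ...)
}

# uniform single-tensor field on a tiny grid
uniform_field <- function(diag3, off3 = c(0, 0, 0), shape = c(3L, 3L, 3L),
                          voxel_size = c(1.72, 1.72, 3)) {
  D <- array(0, dim = c(shape, 6L))
  for (k in 1:3) D[, , , k] <- diag3[k]
  for (k in 1:3) D[, , , k + 3L] <- off3[k]
  tensor_field(D, voxel_size)
}

# analytic truncated-normal mean and sd (oracle for marginal checks)
truncnorm_moments <- function(mean, sd, lo = -Inf, hi = Inf) {
  a <- (lo - mean) / sd; b <- (hi - mean) / sd
  Z <- pnorm(b) - pnorm(a)
  da <- dnorm(a); db <- dnorm(b)
  m <- mean + sd * (da - db) / Z
  v <- sd^2 * (1 + (ifelse(is.finite(a), a * da, 0) -
                    ifelse(is.finite(b), b * db, 0)) / Z -
               ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(v))
}
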