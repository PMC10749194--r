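test_that("eigensystem sorts descending and finds the fiber axis", {
  f <- uniform_field(c(1.4, 0.4, 0.4) * 1e-3, shape = c(1L, 1L, 1L))
  e <- tensor_eigensystem(f)
  expect_equal(e$values[1, 1, 1, ], c(1.4, 0.4, 0.4) * 1e-3)
  expect_equal(abs(e$vectors[1, 1, 1, , 1]), c(1, 0, 0))
  fz <- uniform_field(c(0.4, 0.4, 1.4) * 1e-3, shape = c(1L, 1L, 1L))
  ez <- tensor_eigensystem(fz)
  expect_equal(abs(ez$vectors[1, 1, 1, , 1]), c(0, 0, 1))
})

test_that("spectral reconstruction recovers random symmetric tensors", {
  set.seed(21)
  n <- 20
  D <- array(0, dim = c(n, 1L, 1L, 6L))
  for (i in 1:n) {
    A <- matrix(rnorm(9), 3, 3)
    M <- crossprod(A) * 1e-4
    D[i, 1, 1, ] <- c(diag(M), M[1, 2], M[1, 3], M[2, 3])
  }
  f <- tensor_field(D, c(1, 1, 1))
  e <- tensor_eigensystem(f)
  for (i in 1:n) {
    V <- e$vectors[i, 1, 1, , ]
    L <- e$values[i, 1, 1, ]
    M <- V %*% diag(L) %*% t(V)
    expect_equal(c(diag(M), M[1, 2], M[1, 3], M[2, 3]),
                 unname(D[i, 1, 1, ]), tolerance = 1e-12)
    expect_equal(crossprod(V), diag(3), tolerance = 1e-6)   # orthonormal
    expect_true(all(diff(L) <= 0))                          # descending
  }
})

test_that("negative eigenvalues are clamped and counted", {
  f <- uniform_field(c(-2e-4, 5e-4, 8e-4), shape = c(2L, 1L, 1L))
  expect_message(e <- tensor_eigensystem(f), "clamped.*2 voxels")
  expect_true(all(e$values >= 0))
  expect_equal(attr(e, "n_clamped"), 2L)
})

test_that("FA matches the closed form and stays in [0, 1]", {
  fa_oracle <- function(l) {                 # independent closed form
    sqrt(0.5 * ((l[1] - l[2])^2 + (l[2] - l[3])^2 + (l[1] - l[3])^2) / sum(l^2))
  }
  cases <- list(c(1, 1, 1) * 1e-3, c(1, 0, 0), c(1.4, 0.4, 0.4) * 1e-3,
                c(2, 1, 0.5) * 1e-3)
  expected <- vapply(cases, fa_oracle, numeric(1))
  expect_equal(expected[1], 0)
  expect_equal(expected[2], 1)
  expect_equal(expected[3], 0.66227, tolerance = 1e-5)
  for (k in seq_along(cases)) {
    f <- uniform_field(cases[[k]], shape = c(1L, 1L, 1L))
    fa <- fractional_anisotropy(tensor_eigensystem(f))
    expect_equal(fa[1, 1, 1], expected[k], tolerance = 1e-12)
  }
  # zero tensor: 0/0 convention
  f0 <- uniform_field(c(0, 0, 0), shape = c(1L, 1L, 1L))
  expect_equal(fractional_anisotropy(tensor_eigensystem(f0))[1, 1, 1], 0)
})

test_that("FA is scale-invariant and monotone in the leading eigenvalue", {
  set.seed(4)
  for (rep in 1:20) {
    l <- sort(runif(3, 0.1, 2), decreasing = TRUE) * 1e-3
    f1 <- uniform_field(l, shape = c(1L, 1L, 1L))
    f2 <- uniform_field(l * 7.3, shape = c(1L, 1L, 1L))
    fa1 <- fractional_anisotropy(tensor_eigensystem(f1))[1, 1, 1]
    fa2 <- fractional_anisotropy(tensor_eigensystem(f2))[1, 1, 1]
    expect_equal(fa1, fa2, tolerance = 1e-12)
    f3 <- uniform_field(c(l[1] * 1.5, l[2], l[3]), shape = c(1L, 1L, 1L))
    fa3 <- fractional_anisotropy(tensor_eigensystem(f3))[1, 1, 1]
    expect_gt(fa3, fa1)
    expect_true(fa1 >= 0 && fa1 <= 1)
  }
})

test_that("color FA renders the tract colors of the ALPS geometry", {
  ez <- tensor_eigensystem(uniform_field(c(0.4, 0.4, 1.4) * 1e-3,
                                         shape = c(1L, 1L, 1L)))
  rgbz <- color_fa(ez)
  expect_equal(which.max(rgbz[1, 1, 1, ]), 3L)        # z fibers -> blue
  expect_equal(rgbz[1, 1, 1, 1:2], c(0, 0))
  ex <- tensor_eigensystem(uniform_field(c(1.4, 0.4, 0.4) * 1e-3,
                                         shape = c(1L, 1L, 1L)))
  rgbx <- color_fa(ex)
  expect_equal(which.max(rgbx[1, 1, 1, ]), 1L)        # x fibers -> red
  # whole phantom: dominant channel per tract matches the convention
  spec <- small_phantom_spec()
  f <- make_phantom(spec, 1.45)
  e <- tensor_eigensystem(f)
  rgb <- color_fa(e)
  r <- spec$regions
  dominant <- function(reg) which.max(rgb[reg$x[1], reg$y[1], reg$z[1], ])
  expect_equal(dominant(r$projection), 3L)    # blue
  expect_equal(dominant(r$association), 2L)   # green
  expect_equal(dominant(r$subcortical), 1L)   # red
  expect_true(all(rgb >= 0 & rgb <= 1))
})
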