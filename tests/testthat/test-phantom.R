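test_that("perivascular diffusivity inversion round-trips through the ALPS formula", {
  expect_equal(solve_perivascular_dxx(1.0, 0.4e-3, 0.4e-3), 0.4e-3)
  expect_equal(solve_perivascular_dxx(1.45, 0.4e-3, 0.4e-3), 0.58e-3)
  expect_equal(solve_perivascular_dxx(1.66, 0.35e-3, 0.45e-3), 0.664e-3)
  for (tgt in c(0.6, 1.0, 1.45, 1.66, 2.3)) {
    for (pair in list(c(0.4e-3, 0.4e-3), c(0.35e-3, 0.45e-3))) {
      d <- solve_perivascular_dxx(tgt, pair[1], pair[2])
      expect_equal(compute_alps(d, pair[1], d, pair[2]), tgt)
    }
  }
  expect_error(solve_perivascular_dxx(-1, 0.4e-3, 0.4e-3), "positive")
  expect_error(solve_perivascular_dxx(1, 0, 0.4e-3), "positive")
})

test_that("phantom region means reproduce the target ALPS exactly", {
  spec <- small_phantom_spec()
  for (tgt in c(0.8, 1.0, 1.45, 1.66, 2.1)) {
    f <- make_phantom(spec, tgt)
    r <- spec$regions
    proj <- f$D[r$projection$x[1]:r$projection$x[2],
                r$projection$y[1]:r$projection$y[2],
                r$projection$z[1]:r$projection$z[2], , drop = FALSE]
    asso <- f$D[r$association$x[1]:r$association$x[2],
                r$association$y[1]:r$association$y[2],
                r$association$z[1]:r$association$z[2], , drop = FALSE]
    alps <- mean(c(mean(proj[, , , 1]), mean(asso[, , , 1]))) /
            mean(c(mean(proj[, , , 2]), mean(asso[, , , 3])))
    expect_equal(alps, tgt, tolerance = 1e-15)
  }
})

test_that("phantom tensors are axis-aligned with the fiber axis dominant", {
  spec <- small_phantom_spec()
  f <- make_phantom(spec, 1.45)
  r <- spec$regions
  vox <- function(reg) f$D[reg$x[1], reg$y[1], reg$z[1], ]
  p <- vox(r$projection); a <- vox(r$association); s <- vox(r$subcortical)
  expect_equal(p[4:6], rep(0, 3))                    # no off-diagonals
  expect_equal(which.max(p[1:3]), 3L)                # projection: z largest
  expect_equal(which.max(a[1:3]), 2L)                # association: y largest
  expect_equal(which.max(s[1:3]), 1L)                # subcortical: x largest
  bg <- f$D[1, 1, 1, ]
  expect_equal(bg, c(rep(spec$d_background, 3), rep(0, 3)))
})

test_that("targets that would flip the principal axis are rejected", {
  spec <- small_phantom_spec()   # d_parallel/d_perp = 3.5
  expect_error(expect_warning(make_phantom(spec, 3.6), "principal axis"),
               "incompatible")
  iso <- small_phantom_spec(d_parallel = 0.4000001e-3)
  expect_error(suppressWarnings(make_phantom(iso, 1.45)), "incompatible")
  expect_error(make_phantom(spec, -0.2), "positive")
})

test_that("phantom_spec rejects overlapping or out-of-grid tracts", {
  regions <- default_phantom_regions()
  regions$association$x <- c(10L, 25L)   # overlaps projection at default? no
  regions$association$x <- c(6L, 25L)    # overlaps projection x 6..15
  expect_error(phantom_spec(regions = regions), "overlap")
  regions2 <- default_phantom_regions()
  regions2$subcortical$x <- c(34L, 60L)
  expect_error(phantom_spec(regions = regions2), "out of grid")
})
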