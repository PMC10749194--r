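test_that("raw and summary t-tests agree exactly on the same data", {
  set.seed(3)
  for (rep in 1:10) {
    a <- rnorm(sample(5:40, 1), mean = 2, sd = 1.4)
    b <- rnorm(sample(5:40, 1), mean = 2.5, sd = 0.8)
    tr <- t_test_raw(a, b)
    ts <- t_test_summary(mean(a), sd(a), length(a), mean(b), sd(b), length(b))
    expect_equal(tr$t, ts$t, tolerance = 1e-12)
    expect_equal(tr$df, ts$df)
    expect_equal(tr$p, ts$p, tolerance = 1e-12)
    expect_equal(tr$df, length(a) + length(b) - 2)
  }
})

test_that("t-test edge cases: identical groups and degenerate input", {
  r <- t_test_raw(c(2, 2, 2), c(2, 2, 2))
  expect_equal(r$t, 0); expect_equal(r$p, 1)
  expect_equal(t_test_summary(5, 1, 10, 5, 1, 10)$t, 0)
  expect_error(t_test_raw(c(1), c(2, 3)), "at least 2")
  expect_error(t_test_raw(c(1, 1), c(2, 2)), "zero variance")
})

test_that("t statistic matches a from-scratch pooled computation", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  # oracle: hand-evaluated pooled formula
  sp <- sqrt((2 * var(a) + 2 * var(b)) / 4)
  t_hand <- (mean(b) - mean(a)) / (sp * sqrt(1/3 + 1/3))
  p_hand <- 2 * pt(-abs(t_hand), 4)
  r <- t_test_raw(a, b)
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$p, p_hand, tolerance = 1e-12)
  # and the sign convention: b larger than a gives positive t
  expect_gt(r$t, 0)
})

test_that("Pearson correlation handles exact, perfect, and permutation cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_cor(x, x)$r, 1)
  expect_equal(pearson_cor(x, -2 * x + 3)$r, -1)
  expect_lt(pearson_cor(x, x)$p, 1e-300)
  y <- c(2, 1, 4, 3, 5)
  res <- pearson_cor(x, y)
  expect_equal(res$r, 0.8, tolerance = 1e-12)
  expect_error(pearson_cor(x, rep(1, 5)), "constant")
  expect_error(pearson_cor(1:2, 2:1), "at least 3")
})

test_that("correlation p-values track exact permutation enumeration for n <= 7", {
  perm_p <- function(x, y) {   # oracle: exhaustive two-sided permutation test
    perms <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (i in seq_along(v)) {
        for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
      }
      out
    }
    r0 <- abs(cor(x, y))
    rs <- vapply(perms(y), function(p) abs(cor(x, p)), numeric(1))
    mean(rs >= r0 - 1e-12)
  }
  cases <- list(list(x = c(1, 2, 3, 4, 5), y = c(2, 1, 4, 3, 5)),
                list(x = c(1, 2, 3, 4, 5, 6), y = c(2, 4, 1, 3, 6, 5)),
                list(x = c(0.5, 1.1, 1.9, 3.2, 4.1), y = c(5, 3, 4, 1, 2)))
  for (cs in cases) {
    p_exact <- perm_p(cs$x, cs$y)
    p_t <- pearson_cor(cs$x, cs$y)$p
    # t-approximation and exact enumeration agree to within a few points
    expect_lt(abs(p_t - p_exact), 0.06)
  }
})

test_that("Pearson r respects affine invariance and sign flips", {
  set.seed(8)
  x <- rnorm(30); y <- 0.6 * x + rnorm(30, sd = 0.5)
  r0 <- pearson_cor(x, y)$r
  expect_equal(pearson_cor(2 * x + 5, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_cor(x, 0.1 * y - 3)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_cor(-x, y)$r, -r0, tolerance = 1e-12)
})

test_that("chi-square matches the hand expected-count formula", {
  m <- matrix(c(20, 22, 22, 28), 2, byrow = TRUE)
  # oracle: sum (O - E)^2 / E
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  x2_hand <- sum((m - E)^2 / E)
  res <- chi_square_2x2(m)
  expect_equal(res$chisq, x2_hand, tolerance = 1e-12)
  expect_equal(res$chisq, 0.1205, tolerance = 1e-3)
  expect_equal(res$df, 1L)
  expect_equal(chi_square_2x2(matrix(10, 2, 2))$chisq, 0)
  expect_equal(chi_square_2x2(matrix(10, 2, 2))$p, 1)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "zero marginal")
  # identity with the squared two-proportion z statistic
  p1 <- 20 / 42; p2 <- 22 / 50; pp <- 42 / 92 * p1 + 50 / 92 * p2
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / 42 + 1 / 50))
  expect_equal(res$chisq, z^2, tolerance = 1e-12)
})

test_that("the cohort battery reports all comparisons and skips missing covariates", {
  co <- sample_cohort(cohort_config(seed = 2L))
  rep <- analyze_cohort(co, alps_col = "alps_true")
  expect_equal(nrow(rep), 5L)
  expect_setequal(unique(rep$group), c("both", "CAE", "HC"))
  co2 <- co[, setdiff(names(co), "duration_months")]
  expect_warning(rep2 <- analyze_cohort(co2, alps_col = "alps_true"),
                 "duration")
  expect_equal(nrow(rep2), 4L)
  # null cohort: nothing should be strongly significant
  co0 <- sample_cohort(cohort_config(r_alps_age_cae = 0, r_alps_age_hc = 0,
                                     r_alps_duration = 0,
                                     alps_hc = c(1.45, 0.36), seed = 31L))
  rep0 <- analyze_cohort(co0, alps_col = "alps_true")
  expect_true(all(abs(rep0$estimate[rep0$analysis != "ALPS CAE vs HC (t-test)"]) < 0.45))
})

test_that("type-I error of the group test is calibrated near 0.05", {
  set.seed(99)
  n_rep <- 1000
  rejections <- vapply(seq_len(n_rep), function(i) {
    a <- rnorm(42, 1.5, 0.3); b <- rnorm(50, 1.5, 0.3)
    t_test_raw(a, b)$p < 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})
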