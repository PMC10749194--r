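test_that("cohorts are seed-deterministic with the configured sizes and schema", {
  cfg <- cohort_config(seed = 123L)
  co1 <- sample_cohort(cfg)
  co2 <- sample_cohort(cfg)
  expect_identical(co1, co2)
  expect_equal(nrow(co1), 92L)
  expect_equal(sum(co1$group == "CAE"), 42L)
  expect_equal(sum(co1$group == "HC"), 50L)
  expect_true(all(is.na(co1$duration_months[co1$group == "HC"])))
  expect_true(all(!is.na(co1$duration_months[co1$group == "CAE"])))
  expect_true(all(co1$alps_true > 0))
  expect_true(all(co1$age_years >= 4 & co1$age_years <= 12))
  expect_true(all(co1$duration_months[co1$group == "CAE"] >= 0))
  co3 <- sample_cohort(cohort_config(seed = 124L))
  expect_false(identical(co1$alps_true, co3$alps_true))
})

test_that("zero-correlation targets give independent draws in the large-n limit", {
  cfg <- cohort_config(n_cae = 5000L, n_hc = 5000L,
                       r_alps_age_cae = 0, r_alps_age_hc = 0,
                       r_alps_duration = 0, r_alps_frequency = 0,
                       seed = 55L)
  co <- sample_cohort(cfg)
  cae <- co[co$group == "CAE", ]
  expect_lt(abs(cor(cae$alps_true, cae$age_years)), 0.05)
  expect_lt(abs(cor(cae$alps_true, cae$duration_months)), 0.05)
  expect_lt(abs(cor(cae$alps_true, cae$frequency_per_day)), 0.05)
  hc <- co[co$group == "HC", ]
  expect_lt(abs(cor(hc$alps_true, hc$age_years)), 0.05)
})

test_that("copula targets are recovered at n = 5000 within 0.03", {
  co <- sample_cohort(cohort_config(n_cae = 5000L, n_hc = 5000L, seed = 9L))
  cae <- co[co$group == "CAE", ]
  hc <- co[co$group == "HC", ]
  expect_lt(abs(cor(cae$alps_true, cae$age_years) - 0.766), 0.03)
  expect_lt(abs(cor(cae$alps_true, cae$duration_months) - (-0.48)), 0.03)
  expect_lt(abs(cor(hc$alps_true, hc$age_years) - 0.651), 0.03)
})

test_that("empirical correlation error shrinks roughly like 1/sqrt(n)", {
  err_at <- function(n, seeds) {
    mean(vapply(seeds, function(s) {
      co <- sample_cohort(cohort_config(n_cae = n, n_hc = 3L, seed = s))
      cae <- co[co$group == "CAE", ]
      abs(cor(cae$alps_true, cae$age_years) - 0.766)
    }, numeric(1)))
  }
  e_small <- err_at(50L, 1:20)
  e_large <- err_at(1250L, 1:20)
  # 25x the sample -> ~5x smaller error; allow slack for copula attenuation
  expect_lt(e_large, e_small / 2)
})

test_that("marginal moments match the configured truncated normals at n = 5000", {
  cfg <- cohort_config(n_cae = 5000L, n_hc = 5000L, seed = 77L)
  co <- sample_cohort(cfg)
  cae <- co[co$group == "CAE", ]
  checks <- list(
    list(x = cae$alps_true, mom = truncnorm_moments(1.45, 0.36, lo = 0)),
    list(x = cae$age_years, mom = truncnorm_moments(8.31, 2.12, 4, 12)),
    list(x = cae$duration_months, mom = truncnorm_moments(10.71, 4.97, lo = 0)),
    list(x = cae$frequency_per_day, mom = truncnorm_moments(7.71, 2.00, lo = 0)),
    list(x = co$alps_true[co$group == "HC"],
         mom = truncnorm_moments(1.66, 0.30, lo = 0)))
  for (ck in checks) {
    n <- length(ck$x)
    se_mean <- ck$mom["sd"] / sqrt(n)
    expect_lt(abs(mean(ck$x) - ck$mom["mean"]), 3 * se_mean)
    se_sd <- ck$mom["sd"] / sqrt(2 * (n - 1))   # normal-theory SE of the sd
    expect_lt(abs(sd(ck$x) - ck$mom["sd"]), 4 * se_sd)
  }
})

test_that("impossible correlation targets are rejected naming a pair", {
  expect_error(cohort_config(r_alps_age_cae = 1.2), "outside")
  expect_error(cohort_config(r_alps_age_cae = 0.9, r_alps_duration = 0.9,
                             r_age_duration = -0.9),
               "not positive semi-definite.*\\(")
})
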