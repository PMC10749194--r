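#' Configure the synthetic cohort
#'
#' Defaults reproduce the study conditions: 42 childhood-absence-epilepsy
#' (CAE) patients and 50 healthy controls (HC); true ALPS ~ N(1.45, 0.36)
#' in CAE and N(1.66, 0.30) in HC; age (years) matched between groups
#' (8.31 +/- 2.12 vs 8.44 +/- 1.94), truncated to [4, 12] (the typical CAE
#' onset range); disease duration 10.71 +/- 4.97 months and seizure
#' frequency 7.71 +/- 2.00 events/day in CAE only, truncated at 0. Target
#' correlations (imposed on the Gaussian copula scores): ALPS-age 0.766
#' (CAE) and 0.651 (HC), ALPS-duration -0.48, ALPS-frequency 0.
#'
#' @param n_cae,n_hc subjects per group (>= 3).
#' @param alps_cae,alps_hc `(mean, sd)` of true ALPS per group.
#' @param age_cae,age_hc `(mean, sd)` of age in years per group.
#' @param age_bounds truncation bounds for age, years.
#' @param duration `(mean, sd)` of disease duration, months (CAE only,
#'   truncated at 0).
#' @param frequency `(mean, sd)` of seizure frequency, events/day (CAE only,
#'   truncated at 0).
#' @param r_alps_age_cae,r_alps_age_hc,r_alps_duration,r_alps_frequency
#'   target correlations between ALPS and each covariate.
#' @param r_age_duration,r_age_frequency,r_duration_frequency covariate
#'   cross-correlations within CAE (default 0; not reported clinically).
#' @param seed integer seed making the cohort fully reproducible.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_cae = 42L, n_hc = 50L,
                          alps_cae = c(1.45, 0.36), alps_hc = c(1.66, 0.30),
                          age_cae = c(8.31, 2.12), age_hc = c(8.44, 1.94),
                          age_bounds = c(4, 12),
                          duration = c(10.71, 4.97),
                          frequency = c(7.71, 2.00),
                          r_alps_age_cae = 0.766, r_alps_age_hc = 0.651,
                          r_alps_duration = -0.48, r_alps_frequency = 0,
                          r_age_duration = 0, r_age_frequency = 0,
                          r_duration_frequency = 0,
                          seed = 0L) {
  stopifnot(n_cae >= 3, n_hc >= 3,
            alps_cae[2] > 0, alps_hc[2] > 0, age_cae[2] > 0, age_hc[2] > 0,
            duration[2] > 0, frequency[2] > 0,
            age_bounds[1] < age_bounds[2])
  cfg <- structure(list(
    n_cae = as.integer(n_cae), n_hc = as.integer(n_hc),
    alps_cae = alps_cae, alps_hc = alps_hc,
    age_cae = age_cae, age_hc = age_hc, age_bounds = age_bounds,
    duration = duration, frequency = frequency,
    r_alps_age_cae = r_alps_age_cae, r_alps_age_hc = r_alps_age_hc,
    r_alps_duration = r_alps_duration, r_alps_frequency = r_alps_frequency,
    r_age_duration = r_age_duration, r_age_frequency = r_age_frequency,
    r_duration_frequency = r_duration_frequency,
    seed = as.integer(seed)), class = "cohort_config")
  check_psd(corr_matrix_cae(cfg))   # errors name the offending pair
  check_psd(corr_matrix_hc(cfg))
  cfg
}

# 4x4 correlation target for (alps, age, duration, frequency) in CAE
corr_matrix_cae <- function(cfg) {
  R <- diag(4)
  dimnames(R) <- rep(list(c("alps", "age", "duration", "frequency")), 2)
  R["alps", "age"] <- R["age", "alps"] <- cfg$r_alps_age_cae
  R["alps", "duration"] <- R["duration", "alps"] <- cfg$r_alps_duration
  R["alps", "frequency"] <- R["frequency", "alps"] <- cfg$r_alps_frequency
  R["age", "duration"] <- R["duration", "age"] <- cfg$r_age_duration
  R["age", "frequency"] <- R["frequency", "age"] <- cfg$r_age_frequency
  R["duration", "frequency"] <- R["frequency", "duration"] <- cfg$r_duration_frequency
  R
}

# 2x2 target for (alps, age) in HC
corr_matrix_hc <- function(cfg) {
  R <- diag(2)
  dimnames(R) <- rep(list(c("alps", "age")), 2)
  R["alps", "age"] <- R["age", "alps"] <- cfg$r_alps_age_hc
  R
}

check_psd <- function(R, tol = 1e-10) {
  if (any(abs(R[upper.tri(R)]) > 1)) {
    ij <- which(abs(R) > 1 & upper.tri(R), arr.ind = TRUE)[1, ]
    stop(sprintf("correlation target (%s, %s) = %.3f outside [-1, 1]",
                 rownames(R)[ij[1]], colnames(R)[ij[2]], R[ij[1], ij[2]]))
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    off <- abs(R); diag(off) <- 0
    ij <- which(off == max(off), arr.ind = TRUE)[1, ]
    stop(sprintf(paste0(
      "correlation targets are not positive semi-definite (min eigenvalue ",
      "%.3g); largest-magnitude pair is (%s, %s) = %.3f"),
      min(ev), rownames(R)[ij[1]], colnames(R)[ij[2]], R[ij[1], ij[2]]))
  }
  invisible(TRUE)
}

# inverse CDF of a truncated normal: map p in (0,1) to N(mean, sd) restricted
# to [lo, hi]
qnorm_trunc <- function(p, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + p * (phi - plo), mean, sd)
}

# Gaussian copula draw: n x k normal scores with correlation R, mapped to
# uniforms
copula_uniforms <- function(n, R) {
  U <- chol(R + diag(1e-12, nrow(R)))
  Z <- matrix(stats::rnorm(n * nrow(R)), n, nrow(R)) %*% U
  P <- stats::pnorm(Z)
  colnames(P) <- colnames(R)
  P
}

#' Sample a synthetic cohort with prescribed correlation structure
#'
#' Per group, draws (ALPS, age, duration, frequency) from a Gaussian copula
#' carrying the target correlation matrix, then transforms each coordinate
#' to its configured marginal by inverse CDF (truncated normal where bounds
#' apply; ALPS is bounded below at 0). Duration and frequency are generated
#' for CAE subjects only. Empirical correlations converge to the targets as
#' n grows; the cohort is fully determined by `cfg$seed`.
#'
#' @param cfg a [cohort_config()].
#'
#' @return A data frame with columns `id`, `group` ("CAE"/"HC"),
#'   `age_years`, `duration_months`, `frequency_per_day` (NA for HC), and
#'   `alps_true`.
#' @export
sample_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)

  P <- copula_uniforms(cfg$n_cae, corr_matrix_cae(cfg))
  cae <- data.frame(
    id = sprintf("CAE%02d", seq_len(cfg$n_cae)),
    group = "CAE",
    age_years = qnorm_trunc(P[, "age"], cfg$age_cae[1], cfg$age_cae[2],
                            cfg$age_bounds[1], cfg$age_bounds[2]),
    duration_months = qnorm_trunc(P[, "duration"], cfg$duration[1],
                                  cfg$duration[2], lo = 0),
    frequency_per_day = qnorm_trunc(P[, "frequency"], cfg$frequency[1],
                                    cfg$frequency[2], lo = 0),
    alps_true = qnorm_trunc(P[, "alps"], cfg$alps_cae[1], cfg$alps_cae[2],
                            lo = 0))

  Q <- copula_uniforms(cfg$n_hc, corr_matrix_hc(cfg))
  hc <- data.frame(
    id = sprintf("HC%02d", seq_len(cfg$n_hc)),
    group = "HC",
    age_years = qnorm_trunc(Q[, "age"], cfg$age_hc[1], cfg$age_hc[2],
                            cfg$age_bounds[1], cfg$age_bounds[2]),
    duration_months = NA_real_,
    frequency_per_day = NA_real_,
    alps_true = qnorm_trunc(Q[, "alps"], cfg$alps_hc[1], cfg$alps_hc[2],
                            lo = 0))

  rbind(cae, hc)
}
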