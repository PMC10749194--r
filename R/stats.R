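#' Pooled-variance two-sample t-test from raw data
#'
#' Student's independent-samples t-test with pooled variance (the form whose
#' p-values the clinical tables report). The t statistic is signed as
#' mean(b) - mean(a), so a positive t means group b is larger.
#'
#' @param values_a,values_b numeric vectors (n >= 2 each, positive variance
#'   in at least one).
#'
#' @return An object of class `group_comparison`: list with per-group means,
#'   sds, ns, `t`, `df` (n_a + n_b - 2), and two-tailed `p`.
#' @export
t_test_raw <- function(values_a, values_b) {
  values_a <- as.numeric(values_a); values_b <- as.numeric(values_b)
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("t_test_raw: need at least 2 observations per group")
  }
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) {
      return(group_comparison(mean(values_a), 0, length(values_a),
                              mean(values_b), 0, length(values_b),
                              t = 0, df = length(values_a) + length(values_b) - 2,
                              p = 1))
    }
    stop("t_test_raw: zero variance in both groups with unequal means")
  }
  ht <- stats::t.test(values_b, values_a, var.equal = TRUE)
  group_comparison(mean(values_a), stats::sd(values_a), length(values_a),
                   mean(values_b), stats::sd(values_b), length(values_b),
                   t = unname(ht$statistic), df = unname(ht$parameter),
                   p = ht$p.value)
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' Reconstructs the Student t-test from printed mean +/- SD and n, so
#' published group comparisons can be reproduced without raw data:
#' t = (mean_b - mean_a) / (s_p * sqrt(1/n_a + 1/n_b)) with the pooled
#' s_p^2 = ((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2).
#'
#' @param mean_a,sd_a,n_a group a summary statistics.
#' @param mean_b,sd_b,n_b group b summary statistics.
#'
#' @return A `group_comparison` (see [t_test_raw()]).
#' @export
#' @examples
#' t_test_summary(8.31, 2.12, 42, 8.44, 1.94, 50)$p  # 0.76
t_test_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (sd_a < 0 || sd_b < 0) stop("t_test_summary: sds must be nonnegative")
  if (n_a < 2 || n_b < 2) stop("t_test_summary: need n >= 2 per group")
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  if (sp2 == 0) {
    if (mean_a == mean_b) {
      return(group_comparison(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                              t = 0, df = df, p = 1))
    }
    stop("t_test_summary: zero pooled variance with unequal means")
  }
  t <- (mean_b - mean_a) / (sqrt(sp2) * sqrt(1 / n_a + 1 / n_b))
  group_comparison(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                   t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

group_comparison <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b, t, df, p) {
  structure(list(mean_a = mean_a, sd_a = sd_a, n_a = n_a,
                 mean_b = mean_b, sd_b = sd_b, n_b = n_b,
                 t = t, df = df, p = p),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "two-sample t-test (pooled): %.3f +/- %.3f (n=%d) vs %.3f +/- %.3f (n=%d)\n  t = %.3f, df = %d, p = %.4g\n",
    x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b, x$t, x$df, x$p))
  invisible(x)
}

#' Pearson correlation with two-tailed p-value
#'
#' r with the usual t-based two-tailed p, t = r * sqrt((n-2) / (1-r^2)).
#' For numerically perfect correlation (|r| = 1) the p-value is reported as
#' the smallest representable positive double rather than 0.
#'
#' @param x,y numeric vectors of equal length (n >= 3, nonzero variance in
#'   both).
#'
#' @return An object of class `correlation_result`: list with `r`, `n`, `t`,
#'   and two-tailed `p`.
#' @export
pearson_cor <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("pearson_cor: need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("pearson_cor: constant input has no defined correlation")
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-15) {
    r <- sign(r)
    return(structure(list(r = r, n = n, t = sign(r) * Inf,
                          p = .Machine$double.xmin),
                     class = "correlation_result"))
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ht$estimate), n = n,
                 t = unname(ht$statistic), p = ht$p.value),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.3f (n = %d), t = %.3f, p = %.4g\n",
              x$r, x$n, x$t, x$p))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Plain Pearson chi-square (no continuity correction), df = 1.
#'
#' @param counts 2x2 matrix (or coercible) of nonnegative counts with all
#'   marginals positive.
#'
#' @return An object of class `contingency_result`: list with `counts`,
#'   `chisq`, `df` (= 1), and `p`.
#' @export
chi_square_2x2 <- function(counts) {
  counts <- matrix(as.numeric(counts), 2L, 2L)
  if (any(counts < 0)) stop("chi_square_2x2: counts must be nonnegative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("chi_square_2x2: zero marginal")
  }
  ht <- stats::chisq.test(counts, correct = FALSE)
  structure(list(counts = counts, chisq = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square (2x2): X^2 = %.4f, df = %d, p = %.4g\n",
              x$chisq, x$df, x$p))
  invisible(x)
}

#' Run the cohort statistical battery
#'
#' The full between-group and within-group analysis on a measured cohort:
#' pooled t-test of ALPS between CAE and HC, and Pearson correlations of
#' ALPS with age (both groups) and with disease duration and seizure
#' frequency (CAE only; skipped with a warning when a covariate is missing).
#'
#' @param cohort data frame with columns `group`, `age_years`,
#'   `duration_months`, `frequency_per_day`, and an ALPS column.
#' @param alps_col which ALPS column to analyze (default `"alps_measured"`,
#'   falling back to `"alps_true"` if absent).
#' @param alpha two-tailed significance level used for flagging (default
#'   0.05).
#'
#' @return A data frame report with one row per comparison: `analysis`,
#'   `group`, `estimate` (t-test mean difference b - a, or r), `stat`, `df`,
#'   `p`, `n`, `significant`.
#' @export
analyze_cohort <- function(cohort, alps_col = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(cohort), "group" %in% names(cohort))
  if (is.null(alps_col)) {
    alps_col <- if ("alps_measured" %in% names(cohort)) "alps_measured"
                else "alps_true"
  }
  if (!alps_col %in% names(cohort)) stop("no ALPS column '", alps_col, "'")
  alps <- cohort[[alps_col]]
  is_cae <- cohort$group == "CAE"

  rows <- list()
  tt <- t_test_raw(alps[is_cae], alps[!is_cae])
  rows[[1]] <- data.frame(analysis = "ALPS CAE vs HC (t-test)", group = "both",
                          estimate = tt$mean_b - tt$mean_a, stat = tt$t,
                          df = tt$df, p = tt$p, n = tt$n_a + tt$n_b)

  add_cor <- function(label, grp, xcol) {
    sel <- if (grp == "CAE") is_cae else !is_cae
    xv <- if (xcol %in% names(cohort)) cohort[[xcol]][sel]
    if (is.null(xv) || all(is.na(xv))) {
      warning(sprintf("skipping '%s' in %s: covariate '%s' missing",
                      label, grp, xcol))
      return(NULL)
    }
    ct <- pearson_cor(alps[sel], xv)
    data.frame(analysis = label, group = grp, estimate = ct$r, stat = ct$t,
               df = ct$n - 2, p = ct$p, n = ct$n)
  }
  rows <- c(rows, list(
    add_cor("ALPS ~ age (Pearson)", "CAE", "age_years"),
    add_cor("ALPS ~ age (Pearson)", "HC", "age_years"),
    add_cor("ALPS ~ duration (Pearson)", "CAE", "duration_months"),
    add_cor("ALPS ~ frequency (Pearson)", "CAE", "frequency_per_day")))
  report <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(report) <- NULL
  report$significant <- report$p < alpha
  report
}

#' Write a cohort statistics report
#'
#' Writes the [analyze_cohort()] table as CSV and a human-readable text
#' summary alongside it.
#'
#' @param report data frame from [analyze_cohort()].
#' @param path CSV output path; the text summary goes to `<path>.txt`.
#' @export
write_cohort_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  lines <- c("Cohort statistics report", strrep("-", 60),
             sprintf("%-28s %-4s est=%8.3f stat=%7.3f df=%3d p=%.4g%s",
                     report$analysis, report$group, report$estimate,
                     report$stat, report$df, report$p,
                     ifelse(report$significant, "  *", "")))
  writeLines(lines, paste0(path, ".txt"))
  invisible(path)
}
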