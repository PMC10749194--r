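#!/usr/bin/env Rscript
# Stage 3 — covariate-correlation recovery through the imaging pipeline.
#
# The cohort generator imposes the clinical correlation structure on true
# ALPS and covariates via a Gaussian copula: ALPS-age r = 0.766 (CAE) and
# 0.651 (HC), ALPS-duration r = -0.48, ALPS-frequency r = 0. Each subject's
# true ALPS is embedded in a phantom, imaged at SNR 30, and measured; the
# recovered ALPS is then correlated against the simulated covariates. At
# the clinical sample sizes (42 / 50) sampling error of r dominates, so the
# generator-level correlations are also verified on true values at
# n = 2000.

suppressPackageStartupMessages(library(dtialps))

out_dir <- "results"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

spec <- phantom_spec()
gtab <- build_gradient_table(30, 1000, 1)

cat("CAE cohort (n = 42, seed 7): imaging and measuring ...\n")
cae <- sample_cohort(cohort_config(seed = 7L))
cae <- measure_cohort(cae[cae$group == "CAE", ], spec, gtab, snr = 30,
                      seed = 7L)
cat("HC cohort (n = 50, seed 11): imaging and measuring ...\n")
hc <- sample_cohort(cohort_config(seed = 11L))
hc <- measure_cohort(hc[hc$group == "HC", ], spec, gtab, snr = 30,
                     seed = 11L)
write_cohort(rbind(cae, hc), file.path(out_dir, "correlation_cohort.csv"))

row <- function(label, n, target, r_true, r_meas) {
  data.frame(comparison = label, n = n, target_r = target,
             r_true_alps = r_true, r_measured_alps = r_meas)
}
tab <- rbind(
  row("ALPS ~ duration (CAE)", nrow(cae), -0.48,
      cor(cae$alps_true, cae$duration_months),
      cor(cae$alps_measured, cae$duration_months)),
  row("ALPS ~ age (CAE)", nrow(cae), 0.766,
      cor(cae$alps_true, cae$age_years),
      cor(cae$alps_measured, cae$age_years)),
  row("ALPS ~ frequency (CAE)", nrow(cae), 0,
      cor(cae$alps_true, cae$frequency_per_day),
      cor(cae$alps_measured, cae$frequency_per_day)),
  row("ALPS ~ age (HC)", nrow(hc), 0.651,
      cor(hc$alps_true, hc$age_years),
      cor(hc$alps_measured, hc$age_years)))
write.csv(tab, file.path(out_dir, "correlation_recovery.csv"),
          row.names = FALSE)
print(tab, digits = 3, row.names = FALSE)

cat("\ngenerator-level check on true ALPS at n = 2000 per group:\n")
big <- sample_cohort(cohort_config(n_cae = 2000L, n_hc = 2000L, seed = 7L))
bc <- big[big$group == "CAE", ]
bh <- big[big$group == "HC", ]
big_tab <- data.frame(
  comparison = c("ALPS ~ duration (CAE)", "ALPS ~ age (CAE)", "ALPS ~ age (HC)"),
  target_r = c(-0.48, 0.766, 0.651),
  empirical_r = c(cor(bc$alps_true, bc$duration_months),
                  cor(bc$alps_true, bc$age_years),
                  cor(bh$alps_true, bh$age_years)))
write.csv(big_tab, file.path(out_dir, "correlation_recovery_n2000.csv"),
          row.names = FALSE)
print(big_tab, digits = 3, row.names = FALSE)
cat("\nnote: at n = 42/50 a single cohort's r scatters with SD ~0.07-0.13\n",
    "around the target; the n = 2000 check isolates the generator itself.\n")
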