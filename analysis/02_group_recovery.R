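#!/usr/bin/env Rscript
# Stage 2 — group-mean recovery at clinical noise levels.
#
# Draws per-subject true ALPS values from the two group distributions
# (CAE: 1.45 +/- 0.36, n = 42; HC: 1.66 +/- 0.30, n = 50), embeds each in
# its own phantom, simulates the acquisition at SNR 30, and measures every
# subject with the full fit -> ROI -> ALPS pipeline. The question: do the
# recovered group means and their comparison reproduce the generating
# conditions (means 1.45 / 1.66, t-test p < 0.01)?

suppressPackageStartupMessages(library(dtialps))

out_dir <- "results"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

spec <- phantom_spec()
gtab <- build_gradient_table(30, 1000, 1)

run_group <- function(group, n, mu, sigma, seed) {
  set.seed(seed)
  truths <- rnorm(n, mu, sigma)
  rec <- vapply(seq_len(n), function(k) {
    simulate_and_measure(spec, truths[k], gtab, snr = 30,
                         seed = seed * 1000L + k)$alps
  }, numeric(1))
  data.frame(id = sprintf("%s%02d", group, seq_len(n)), group = group,
             alps_true = truths, alps_measured = rec)
}

cat("simulating and measuring 92 subjects at SNR 30 ...\n")
subjects <- rbind(run_group("CAE", 42L, 1.45, 0.36, 42L),
                  run_group("HC", 50L, 1.66, 0.30, 43L))
write.csv(subjects, file.path(out_dir, "group_recovery_subjects.csv"),
          row.names = FALSE)

summ <- do.call(rbind, lapply(split(subjects, subjects$group), function(g) {
  data.frame(group = g$group[1], n = nrow(g),
             mean_true = mean(g$alps_true), sd_true = sd(g$alps_true),
             mean_measured = mean(g$alps_measured),
             sd_measured = sd(g$alps_measured))
}))
write.csv(summ, file.path(out_dir, "group_recovery_summary.csv"),
          row.names = FALSE)
print(summ, digits = 4, row.names = FALSE)

tt <- t_test_raw(subjects$alps_measured[subjects$group == "CAE"],
                 subjects$alps_measured[subjects$group == "HC"])
cat("\nrecovered group comparison:\n")
print(tt)
cat(sprintf("recovery errors: CAE %+.4f, HC %+.4f (generating means 1.45 / 1.66)\n",
            summ$mean_measured[summ$group == "CAE"] - 1.45,
            summ$mean_measured[summ$group == "HC"] - 1.66))
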