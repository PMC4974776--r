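#!/usr/bin/env Rscript
# Stage 3: time-course statistics.
#
# Summarises the enrichment records per metabolite, quantity and time point
# (mean +/- SD over kidneys) and tests the 6 h vs 24 h contrasts with the
# pooled two-tailed Student's t test at alpha = 0.05.

suppressPackageStartupMessages(library(hsqcdecon))

records <- read.csv("results/records.csv", stringsAsFactors = FALSE)
manifest <- read_manifest("scratch/cohort/manifest.csv")

res <- run_timecourse(records, manifest)

write.csv(res$summary, "results/summary.csv", row.names = FALSE, quote = FALSE)
write.csv(res$tests, "results/tests.csv", row.names = FALSE, quote = FALSE)

cat("Per-time-point summaries (results/summary.csv):\n")
enr <- res$summary[res$summary$quantity == "enrichment_pct", ]
for (i in seq_len(nrow(enr))) {
  cat(sprintf("  %-8s %2d h: %5.2f%% +/- %.2f (n=%d)\n", enr$metabolite[i],
              enr$time_h[i], enr$mean[i], enr$sd[i], enr$n[i]))
}
cat("\n6 h vs 24 h comparisons (results/tests.csv):\n")
for (i in seq_len(nrow(res$tests))) {
  tt <- res$tests[i, ]
  cat(sprintf("  %-8s %-14s t=%6.2f df=%d p=%.2g%s\n", tt$metabolite,
              tt$quantity, tt$t, tt$df, tt$p,
              if (tt$significant) " *" else ""))
}
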