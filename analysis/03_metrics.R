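#!/usr/bin/env Rscript
# Extract the conventional volume-transient metrics for the simulated cohort
# (phase durations, diastasis, passive/active filling split, velocities, RR
# statistics) and summarize them by MACE class, mirroring the usual
# biomarker table layout. Requires 01_simulate.R.

suppressPackageStartupMessages(library(lvtransient))

out_dir <- "results"
transients <- read_transients_csv(file.path(out_dir, "transients.csv"))
rr <- read.csv(file.path(out_dir, "rr_metadata.csv"))
baseline <- read.csv(file.path(out_dir, "features_baseline.csv"))

rr_lists <- lapply(seq_len(nrow(rr)), function(i) as.numeric(rr[i, 2:4]))
metrics <- compute_metrics_cohort(transients[rr$patient_id], rr_lists)
write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)

merged <- merge(metrics, baseline[c("patient_id", "outcome")],
                by = "patient_id")
fmt <- function(x) {
  q <- quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE, names = FALSE)
  sprintf("%.1f (%.1f-%.1f)", q[1], q[2], q[3])
}
vars <- c("rr_ms", "rr_variability_pct_rr", "systolic_time_ms",
          "diastolic_time_ms", "diastasis_ms", "time_to_diastasis_ms",
          "passive_filling_ml", "active_filling_ml", "ef_pct")
summary_tab <- data.frame(
  metric = vars,
  all = vapply(vars, function(v) fmt(merged[[v]]), character(1)),
  mace = vapply(vars, function(v) fmt(merged[[v]][merged$outcome == 1]),
                character(1)),
  no_mace = vapply(vars, function(v) fmt(merged[[v]][merged$outcome == 0]),
                   character(1)),
  p_wilcoxon = vapply(vars, function(v) {
    suppressWarnings(wilcox.test(merged[[v]][merged$outcome == 1],
                                 merged[[v]][merged$outcome == 0],
                                 exact = FALSE)$p.value)
  }, numeric(1)),
  row.names = NULL)
write.csv(summary_tab, file.path(out_dir, "metrics_by_class.csv"),
          row.names = FALSE)
print(summary_tab, row.names = FALSE, digits = 3)
message(sprintf("diastasis not detected in %d / %d transients (%.1f%%)",
                sum(!metrics$diastasis_found), nrow(metrics),
                100 * mean(!metrics$diastasis_found)))
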