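#!/usr/bin/env Rscript
# Prognostic evaluation: univariate summaries, backward stepwise LDA and Cox
# selection over nested feature blocks (EF alone; ESV+EDV; adding
# conventional transient metrics; adding atlas mode weights), and repeated
# stratified 10-fold cross-validation (100 random splits) of each selected
# model. Requires 01-04.

suppressPackageStartupMessages(library(lvtransient))

out_dir <- "results"
metrics <- read.csv(file.path(out_dir, "metrics.csv"))
weights <- read.csv(file.path(out_dir, "weights.csv"))
baseline <- read.csv(file.path(out_dir, "features_baseline.csv"))

feats <- merge(baseline[c("patient_id", "outcome", "time_months", "censored",
                          "noise1", "noise2")],
               metrics, by = "patient_id")
feats <- merge(feats, weights, by = "patient_id")
vt_ai <- grep("^vt_ai_", names(weights), value = TRUE)

blocks <- list(
  lvef = "ef_pct",
  cmr = c("esv_ml", "edv_ml"),
  cmr_vt = c("esv_ml", "edv_ml", "rr_ms", "diastolic_time_ms",
             "active_filling_ml"),
  cmr_vt_ai = c("esv_ml", "edv_ml", "ef_pct", vt_ai)
)

# univariate biomarker table (discriminative AUC + per-SD hazard ratios)
uni_vars <- c("ef_pct", "esv_ml", "rr_ms", "rr_variability_pct_rr",
              "diastasis_ms", "active_filling_ml", vt_ai)
uni <- do.call(rbind, lapply(uni_vars, function(v) {
  univariate_summary(feats, v, n_splits = 25, seed = 11)
}))
write.csv(uni, file.path(out_dir, "univariate_summary.csv"),
          row.names = FALSE)
print(uni[c("feature", "auc_k", "p_value", "hr", "hr_p_value")],
      row.names = FALSE, digits = 3)

perf <- list()
report <- list()
for (family in c("lda", "cox")) {
  for (b in names(blocks)) {
    sel <- backward_stepwise(feats, blocks[[b]], family = family)
    vars <- if (length(sel$selected)) sel$selected else blocks[[b]]
    cv <- evaluate_cv(feats, vars, family = family, k = 10, n_splits = 100,
                      seed = 7)
    key <- paste(family, b, sep = ".")
    perf[[key]] <- cv
    report[[key]] <- data.frame(
      family = family, block = b,
      selected = paste(sel$selected, collapse = "+"),
      metric = cv$metric, resubstitution = cv$resubstitution,
      cv_median = cv$median, cv_q25 = cv$iqr[1], cv_q75 = cv$iqr[2],
      stringsAsFactors = FALSE)
    message(sprintf("%-4s %-10s -> %-38s %s  rs %.3f | cv %.3f (%.3f-%.3f)",
                    family, b, report[[key]]$selected, cv$metric,
                    cv$resubstitution, cv$median, cv$iqr[1], cv$iqr[2]))
  }
}
tab <- do.call(rbind, report)
write.csv(tab, file.path(out_dir, "model_performance.csv"),
          row.names = FALSE)

p_gain <- compare_performance(perf[["lda.cmr_vt_ai"]], perf[["lda.lvef"]])
message(sprintf(
  "contraction-mode model vs EF alone: CV AUC %.3f vs %.3f (rank-sum p = %.2g)",
  perf[["lda.cmr_vt_ai"]]$median, perf[["lda.lvef"]]$median, p_gain))
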