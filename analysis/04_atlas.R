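#!/usr/bin/env Rscript
# Build the unsupervised contraction-mode atlas: min-max normalize each
# transient onto a common cycle-fraction grid, run PCA, retain the modes
# covering 95% of the variance, and project every patient to mode weights
# (the per-patient contraction biomarkers). Also writes the 10th/90th
# percentile traces of each retained mode for interpretation. Requires
# 01_simulate.R.

suppressPackageStartupMessages(library(lvtransient))

out_dir <- "results"
transients <- read_transients_csv(file.path(out_dir, "transients.csv"))

norm <- lapply(transients, normalize_transient, G = 100)
atlas <- fit_atlas(norm, variance_threshold = 0.95)
write_atlas_json(atlas, file.path(out_dir, "atlas.json"))
print(atlas)

W <- project_transient(atlas, lvtransient:::as_curve_matrix(norm))
weights <- data.frame(patient_id = rownames(W), W, row.names = NULL)
write.csv(weights, file.path(out_dir, "weights.csv"), row.names = FALSE)

traces <- do.call(rbind, lapply(seq_len(atlas$n_modes), function(k) {
  tr <- mode_extreme_traces(atlas, W, k, lo_pct = 10, hi_pct = 90)
  data.frame(mode = k, cycle_fraction = seq(0, 1, length.out = atlas$G + 1)[1:atlas$G],
             p10 = tr$lo, p90 = tr$hi, mean = atlas$mean_curve)
}))
write.csv(traces, file.path(out_dir, "mode_traces.csv"), row.names = FALSE)

# how the modes relate to the planted physiology
planted <- read.csv(file.path(out_dir, "planted_truth.csv"))
planted <- planted[match(weights$patient_id, planted$patient_id), ]
cors <- sapply(list(rr = planted$rr_ms,
                    diastasis_frac = planted$diastasis_ms / planted$rr_ms,
                    passive_fraction = planted$passive_fraction,
                    systolic_frac = planted$systolic_ms / planted$rr_ms),
               function(v) cor(W, v))
rownames(cors) <- colnames(W)
write.csv(round(cors, 3), file.path(out_dir, "mode_correlations.csv"))
message("mode-weight correlations with planted generator factors:")
print(round(cors, 2))
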