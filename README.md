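# lvtransient

Analysis of left-ventricular (LV) **volume transients** — cavity volume as a
function of time over one cardiac cycle — and of their prognostic value for
post-infarction risk assessment.

After an acute myocardial infarction, risk stratification relies on the LV
ejection fraction, `LVEF = (EDV − ESV)/EDV`, a two-time-point summary that
discards the contraction dynamics in between. This package implements the
full transient pipeline for researchers studying those dynamics:

1. **Volume reconstruction** — per-frame binary short-axis segmentation
   stacks are integrated to cavity volumes with the trapezoidal rule over
   slice cross-sections, `V = Δz · (A₁/2 + A₂ + … + Aₙ/2)`, and resampled
   with a periodic cubic spline.
2. **Conventional phase metrics** — detection of the eight cardiac-phase
   landmarks (end-diastole, systolic peak velocity, end-systole, passive
   filling peak velocity, diastasis begin/mid/end, active filling peak
   velocity); diastasis is the mid-diastolic region with filling velocity
   below 0.8 stroke volumes per second, and the passive/active filling
   split is taken at mid-diastasis so that passive + active = SV exactly.
3. **Contraction-mode atlas** — min-max-normalized transients on a common
   cycle-fraction grid are decomposed by PCA; the modes reaching 95% of the
   population variance define per-patient weights `vt_ai_k`, compact
   unsupervised biomarkers of contraction shape.
4. **Prognostic models** — backward stepwise LDA (significance via the
   binomial GLM approximation) and Cox selection at p < 0.05, evaluated by
   rank AUC / Harrell's C-index under resubstitution and repeated
   stratified 10-fold cross-validation (100 random splits), with a
   composite 12-month endpoint adjudicated by the priority death >
   reinfarction > congestive heart failure.

Patient data of this kind cannot be redistributed, so the package ships a
parametric **synthetic-cohort generator**: piecewise raised-cosine
transients with closed-form landmarks, per-class parameter distributions
(shorter, more variable RR-interval, lower EF, shorter diastasis in the
event class), mask phantoms with analytic volumes, covariates, outcomes and
event times. Every stage is tested against this planted ground truth; the
methods vignette (`vignettes/volume-transient-analysis.Rmd`) documents the
model, the estimators, the chosen defaults and what the synthetic results
do and do not show about real data.

## Worked example

The `analysis/` directory is a numbered workflow over the package
(`01_simulate` → `05_models`) writing its tables under `results/`. A
condensed version:

```r
library(lvtransient)

coh <- generate_cohort(cohort_spec(n_patients = 1000, seed = 20240901))
metrics <- compute_metrics_cohort(coh$transients, coh$rr_lists)
norm  <- lapply(coh$transients, normalize_transient, G = 100)
atlas <- fit_atlas(norm, variance_threshold = 0.95)
atlas
#> Transient atlas: 1000 subjects, grid G = 100, 4 mode(s) for 95% variance
#>   variance fractions: 0.557 0.294 0.064 0.038
```

Four shape modes carry 95% of the variance; their weights correlate with
the planted physiology (mode 1 with the relative systolic duration and RR,
mode 4 with the diastasis fraction, r = 0.59). Feeding the volumetric
analogues plus mode weights into the stepwise discriminant analysis and
cross-validating (`analysis/05_models.R` prints):

```
lda  lvef       -> ef_pct                                 auc  rs 0.695 | cv 0.692 (0.691-0.693)
lda  cmr        -> esv_ml+edv_ml                          auc  rs 0.706 | cv 0.698 (0.696-0.700)
lda  cmr_vt     -> esv_ml+rr_ms+active_filling_ml         auc  rs 0.748 | cv 0.737 (0.736-0.740)
lda  cmr_vt_ai  -> edv_ml+ef_pct+vt_ai_4                  auc  rs 0.725 | cv 0.712 (0.709-0.714)
contraction-mode model vs EF alone: CV AUC 0.712 vs 0.692 (rank-sum p = 2.6e-34)
```

`rs` is the apparent (resubstitution) performance, `cv` the median and IQR
over 100 random 10-fold splits. The selected contraction-mode model keeps a
diastolic mode and beats ejection fraction alone — the qualitative finding
that contraction dynamics add prognostic value over LVEF, reproduced at
synthetic scale. In this cohort 207/1000 transients (20.7%) have no
detectable diastasis and their passive/active filling metrics are reported
missing.

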