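# Shared fixtures: all synthetic, built in code.

# A canonical mid-cohort patient: RR 845 ms, EDV 160 / ESV 80 mL (EF 50%),
# systole 297 ms, passive filling 310 ms, diastasis 120 ms, 66.5% passive.
canonical_params <- function(rr_ms = 845, edv_ml = 160, ef_pct = 50,
                             systolic_ms = 297, passive_ms = 310,
                             diastasis_ms = 120, passive_fraction = 0.665) {
  transient_params(rr_ms, edv_ml, ef_pct, systolic_ms, passive_ms,
                   diastasis_ms, passive_fraction)
}

# One random patient drawn from the default class distributions. For
# landmark-recovery experiments the planted diastasis is floored at
# `td_floor` ms (shorter plateaus are below the detector's reporting floor,
# so all eight landmarks exist and are identifiable); the floor is taken out
# of the passive segment so the cycle arithmetic is unchanged.
draw_recovery_params <- function(td_floor = 30) {
  cls <- if (stats::runif(1) < 0.5) "no_mace" else "mace"
  cl <- cohort_spec()$classes[[cls]]
  dp <- lvtransient:::draw_patient_params(cl, c(25, 30))
  if (td_floor > 0 && dp$diastasis_ms < td_floor) {
    dp$passive_ms <- dp$passive_ms - (td_floor - dp$diastasis_ms)
    dp$diastasis_ms <- td_floor
  }
  dp$params <- transient_params(dp$rr_ms, dp$edv_ml, dp$ef_pct,
                                dp$systolic_ms, dp$passive_ms,
                                dp$diastasis_ms, dp$passive_fraction)
  dp
}

# Transient with a raised-cosine systolic descent and strictly linear
# diastolic filling at a constant velocity of `vel_sv_s` stroke volumes per
# second (used to exercise the diastasis threshold semantics).
linear_filling_transient <- function(vel_sv_s, edv = 160, esv = 80,
                                     systolic_ms = 297, n_frames = 40) {
  sv <- edv - esv
  diastole_ms <- 1000 / vel_sv_s  # refill SV at vel_sv_s * SV mL/s
  rr <- systolic_ms + diastole_ms
  tt <- seq(0, rr, length.out = n_frames + 1)[seq_len(n_frames)]
  vol <- ifelse(tt <= systolic_ms,
                esv + sv * (1 + cos(pi * tt / systolic_ms)) / 2,
                esv + sv * (tt - systolic_ms) / diastole_ms)
  volume_transient(tt, vol, rr_ms = rr, patient_id = "linear")
}

# Synthetic feature table: two classes with chosen per-feature standardized
# location shifts, plus event times (cases uniform on (0, 12], controls
# censored at 12).
make_feature_table <- function(n, prevalence = 0.5, shifts = c(x1 = 1),
                               n_noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  outcome <- stats::rbinom(n, 1, prevalence)
  df <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                   outcome = outcome)
  for (v in names(shifts)) {
    df[[v]] <- stats::rnorm(n) + shifts[[v]] * outcome
  }
  if (n_noise > 0) {
    for (j in seq_len(n_noise)) {
      df[[paste0("z", j)]] <- stats::rnorm(n)
    }
  }
  df$time_months <- ifelse(outcome == 1, stats::runif(n, 0, 12), 12)
  df$censored <- outcome == 0
  df
}
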