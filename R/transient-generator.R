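#' Parametric left-ventricular volume transient
#'
#' Defines a closed-form, piecewise raised-cosine LV cavity volume curve over
#' one cardiac cycle. The cycle starts at end-diastole (ED, volume `edv_ml`),
#' descends to end-systole (ES, volume `esv_ml`) over `systolic_ms`, refills
#' passively by `passive_fraction * SV` mL over `passive_ms`, rests on a flat
#' diastasis plateau of `diastasis_ms`, and refills actively back to `edv_ml`
#' over the remaining time, closing the cycle at `t = rr_ms`. All four
#' segments are raised cosines (or constants), so the curve is C1 (zero
#' velocity at every join) and all eight cardiac-phase landmarks have
#' closed-form locations.
#'
#' @param rr_ms cycle length (RR-interval), ms.
#' @param edv_ml end-diastolic volume, mL.
#' @param ef_pct ejection fraction, percent; `esv = edv * (1 - ef/100)`.
#' @param systolic_ms duration of the systolic descent, ms.
#' @param passive_ms duration of the passive-filling segment, ms.
#' @param diastasis_ms duration of the flat diastasis plateau, ms (0 merges
#'   the filling phases).
#' @param passive_fraction fraction of stroke volume refilled passively,
#'   in (0, 1].
#' @return an object of class `vt_params`.
#' @examples
#' p <- transient_params(845, 160, 50, 297, 310, 120, 0.665)
#' vt_value(p, c(0, p$t_es, p$rr_ms))
#' @export
transient_params <- function(rr_ms, edv_ml, ef_pct, systolic_ms,
                             passive_ms, diastasis_ms, passive_fraction) {
  stopifnot(rr_ms > 0, edv_ml > 0, ef_pct > 0, ef_pct < 100,
            systolic_ms > 0, passive_ms > 0, diastasis_ms >= 0,
            passive_fraction > 0, passive_fraction <= 1)
  active_ms <- rr_ms - systolic_ms - passive_ms - diastasis_ms
  if (active_ms <= 0) {
    stop("infeasible durations: systolic + passive + diastasis must leave ",
         "a positive active-filling time within rr_ms")
  }
  esv_ml <- edv_ml * (1 - ef_pct / 100)
  sv_ml <- edv_ml - esv_ml
  p <- list(
    rr_ms = rr_ms, edv_ml = edv_ml, esv_ml = esv_ml, sv_ml = sv_ml,
    ef_pct = ef_pct,
    systolic_ms = systolic_ms, passive_ms = passive_ms,
    diastasis_ms = diastasis_ms, active_ms = active_ms,
    passive_ml = passive_fraction * sv_ml,
    active_ml = (1 - passive_fraction) * sv_ml,
    passive_fraction = passive_fraction,
    t_es = systolic_ms,
    t_diastasis_begin = systolic_ms + passive_ms,
    t_diastasis_end = systolic_ms + passive_ms + diastasis_ms
  )
  class(p) <- "vt_params"
  p
}

#' @export
print.vt_params <- function(x, ...) {
  cat(sprintf(
    "LV transient parameters: RR %.0f ms | EDV %.1f mL, ESV %.1f mL (EF %.1f%%)\n",
    x$rr_ms, x$edv_ml, x$esv_ml, x$ef_pct))
  cat(sprintf(
    "  phases (ms): systole %.0f | passive %.0f | diastasis %.0f | active %.0f\n",
    x$systolic_ms, x$passive_ms, x$diastasis_ms, x$active_ms))
  cat(sprintf("  filling split: passive %.1f mL / active %.1f mL\n",
              x$passive_ml, x$active_ml))
  invisible(x)
}

# half-cosine easing from 0 at s=0 to 1 at s=1 (zero slope at both ends)
.ease <- function(s) (1 - cos(pi * s)) / 2

#' Evaluate the analytic transient volume
#'
#' @param p a [transient_params()] object.
#' @param t times in ms; interpreted modulo `p$rr_ms`.
#' @return volumes in mL.
#' @export
vt_value <- function(p, t) {
  tm <- t %% p$rr_ms
  tm[t == p$rr_ms] <- p$rr_ms  # keep exact right endpoint
  v <- numeric(length(tm))
  ts <- p$systolic_ms; te <- p$t_diastasis_begin; tg <- p$t_diastasis_end
  i1 <- tm <= ts
  v[i1] <- p$esv_ml + p$sv_ml * (1 - .ease(tm[i1] / ts))
  i2 <- tm > ts & tm <= te
  v[i2] <- p$esv_ml + p$passive_ml * .ease((tm[i2] - ts) / p$passive_ms)
  i3 <- tm > te & tm <= tg
  v[i3] <- p$esv_ml + p$passive_ml
  i4 <- tm > tg
  v[i4] <- p$esv_ml + p$passive_ml +
    p$active_ml * .ease((tm[i4] - tg) / p$active_ms)
  v
}

#' Evaluate the analytic transient velocity (dV/dt)
#'
#' @inheritParams vt_value
#' @return velocities in mL/ms.
#' @export
vt_velocity <- function(p, t) {
  tm <- t %% p$rr_ms
  v <- numeric(length(tm))
  ts <- p$systolic_ms; te <- p$t_diastasis_begin; tg <- p$t_diastasis_end
  i1 <- tm <= ts
  v[i1] <- -p$sv_ml * pi / (2 * ts) * sin(pi * tm[i1] / ts)
  i2 <- tm > ts & tm <= te
  v[i2] <- p$passive_ml * pi / (2 * p$passive_ms) *
    sin(pi * (tm[i2] - ts) / p$passive_ms)
  i4 <- tm > tg
  v[i4] <- p$active_ml * pi / (2 * p$active_ms) *
    sin(pi * (tm[i4] - tg) / p$active_ms)
  v
}

#' Closed-form cardiac-phase landmark times of a parametric transient
#'
#' Landmarks, in cycle order: end-diastole, systolic peak velocity,
#' end-systole, passive-filling peak velocity, diastasis begin, mid-diastasis,
#' diastasis end, active-filling peak velocity. For `diastasis_ms = 0` the
#' three diastasis landmarks coincide at the filling-phase join.
#'
#' @inheritParams vt_value
#' @return named list of times in ms.
#' @export
vt_landmarks <- function(p) {
  list(
    t_ed = 0,
    t_sys_peak_vel = p$systolic_ms / 2,
    t_es = p$systolic_ms,
    t_passive_peak_vel = p$systolic_ms + p$passive_ms / 2,
    t_diastasis_begin = p$t_diastasis_begin,
    t_mid_diastasis = (p$t_diastasis_begin + p$t_diastasis_end) / 2,
    t_diastasis_end = p$t_diastasis_end,
    t_active_peak_vel = p$t_diastasis_end + p$active_ms / 2
  )
}

#' Closed-form conventional metrics of a parametric transient
#'
#' The oracle counterpart of [compute_conventional_metrics()]: every Table-style
#' phase metric evaluated analytically from the generating parameters, with the
#' passive/active boundary at mid-diastasis. Velocities are in mL/s.
#'
#' @inheritParams vt_value
#' @param rr_list optional per-scan RR metadata (ms) for the RR statistics;
#'   defaults to the single planted `rr_ms`.
#' @return named list of metrics.
#' @export
vt_analytic_metrics <- function(p, rr_list = NULL) {
  rr_list <- rr_list %||% p$rr_ms
  rr <- mean(rr_list)
  lm <- vt_landmarks(p)
  ttd <- lm$t_mid_diastasis - lm$t_es
  t_active_phase <- rr - lm$t_mid_diastasis
  list(
    rr_ms = rr,
    rr_variability_pct_rr = 100 * (max(rr_list) - min(rr_list)) / rr,
    systolic_time_ms = p$systolic_ms,
    diastolic_time_ms = rr - p$systolic_ms,
    diastasis_ms = p$diastasis_ms,
    diastasis_pct = 100 * p$diastasis_ms / rr,
    time_to_diastasis_ms = ttd,
    time_to_diastasis_pct = 100 * ttd / rr,
    passive_filling_ml = p$passive_ml,
    passive_filling_pct_sv = 100 * p$passive_fraction,
    active_filling_ml = p$active_ml,
    active_filling_pct_sv = 100 * (1 - p$passive_fraction),
    systolic_vel_avg_mls = 1000 * p$sv_ml / p$systolic_ms,
    systolic_vel_avg_pct_sv = 1000 * 100 / p$systolic_ms,
    systolic_vel_peak_mls = 1000 * p$sv_ml * pi / (2 * p$systolic_ms),
    diastolic_vel_avg_mls = 1000 * p$sv_ml / (rr - p$systolic_ms),
    diastolic_vel_avg_pct_sv = 1000 * 100 / (rr - p$systolic_ms),
    passive_vel_avg_mls = 1000 * p$passive_ml / ttd,
    passive_vel_avg_pct_sv = 1000 * 100 * p$passive_fraction / ttd,
    passive_vel_peak_mls = 1000 * p$passive_ml * pi / (2 * p$passive_ms),
    active_vel_avg_mls = 1000 * p$active_ml / t_active_phase,
    active_vel_avg_pct_sv = 1000 * 100 * (1 - p$passive_fraction) / t_active_phase,
    active_vel_peak_mls = 1000 * p$active_ml * pi / (2 * p$active_ms),
    sv_ml = p$sv_ml, esv_ml = p$esv_ml, edv_ml = p$edv_ml, ef_pct = p$ef_pct
  )
}

#' Sample a volume transient from its parametric curve
#'
#' Samples the analytic curve at `n_frames` equispaced trigger times over
#' `[0, rr_ms)` (frame 0 at end-diastole, the ECG trigger) and optionally adds
#' i.i.d. Gaussian volume noise. The generating parameters and closed-form
#' landmark times are attached as the `planted` attribute, the ground-truth
#' carrier for recovery tests.
#'
#' @inheritParams vt_value
#' @param n_frames number of frames per cycle (>= 10).
#' @param noise_sd_ml additive volume noise standard deviation, mL.
#' @param patient_id identifier stored on the transient.
#' @return a [volume_transient()] with attribute `planted`.
#' @export
generate_transient <- function(p, n_frames = 28, noise_sd_ml = 0,
                               patient_id = "synthetic") {
  stopifnot(inherits(p, "vt_params"), n_frames >= 10, noise_sd_ml >= 0)
  tt <- seq(0, p$rr_ms, length.out = n_frames + 1)[seq_len(n_frames)]
  vol <- vt_value(p, tt)
  if (noise_sd_ml > 0) vol <- pmax(vol + stats::rnorm(n_frames, 0, noise_sd_ml), 0)
  out <- volume_transient(tt, vol, rr_ms = p$rr_ms, patient_id = patient_id)
  attr(out, "planted") <- list(params = p, landmarks = vt_landmarks(p),
                               noise_sd_ml = noise_sd_ml)
  out
}
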