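#' Conventional volume-transient metrics
#'
#' Computes the full block of conventional transient markers from the dense
#' resampled curve and its phase landmarks: RR statistics from scan metadata,
#' phase durations, the diastasis interval, the passive/active filling split
#' at mid-diastasis (the boundary between the two filling contributions), and
#' average/peak phase velocities. When no diastasis is found the passive and
#' active filling metrics (mL, %SV and velocities) are reported missing, as
#' is conventional for transients without a reliable quiescent phase.
#'
#' Conventions: the passive phase runs from end-systole to mid-diastasis and
#' the active phase from mid-diastasis to end-diastole, so
#' `passive + active = SV` exactly; velocities are mL/s (durations in ms,
#' factor 1000) and `%SV/s = 100 * (mL/s) / SV`; percentage times are % of
#' the RR-interval; RR variability is `100 * (max - min) / mean` over the
#' per-scan RR list.
#'
#' @param t a [volume_transient()].
#' @param lm optional [detect_landmarks()] result for `t`; computed when
#'   missing.
#' @param rr_list RR-interval metadata values, ms; when empty the transient's
#'   own cycle length is used and `rr_from_metadata` is flagged `FALSE` with a
#'   warning.
#' @param ... passed to [detect_landmarks()] when `lm` is missing.
#' @return an object of class `transient_metrics`: a named list of metrics
#'   with logical `missing_flags`, convertible via `as.data.frame()`.
#' @export
compute_conventional_metrics <- function(t, lm = NULL, rr_list = NULL, ...) {
  if (is.null(lm)) lm <- detect_landmarks(t, ...)
  stopifnot(inherits(lm, "phase_landmarks"))
  rt <- attr(lm, "resampled")
  sp <- attr(rt, "spline")
  V <- rt$volumes_ml
  v <- rt$dvdt_ml_ms
  tt <- rt$trigger_times_ms

  rr_from_metadata <- TRUE
  if (is.null(rr_list) || !length(rr_list)) {
    warning("empty RR metadata: using the transient cycle length")
    rr_list <- rt$rr_ms
    rr_from_metadata <- FALSE
  }
  rr <- mean(rr_list)
  rr_var <- 100 * (max(rr_list) - min(rr_list)) / rr

  edv <- max(V); esv <- min(V); sv <- edv - esv
  ef <- 100 * sv / edv
  systolic_time <- lm$t_es - lm$t_ed
  diastolic_time <- rr - systolic_time

  m <- list(
    rr_ms = rr, rr_variability_pct_rr = rr_var,
    systolic_time_ms = systolic_time, diastolic_time_ms = diastolic_time,
    diastasis_ms = lm$diastasis_ms,
    diastasis_pct = 100 * lm$diastasis_ms / rr,
    time_to_diastasis_ms = NA_real_, time_to_diastasis_pct = NA_real_,
    passive_filling_ml = NA_real_, passive_filling_pct_sv = NA_real_,
    active_filling_ml = NA_real_, active_filling_pct_sv = NA_real_,
    systolic_vel_avg_mls = 1000 * sv / systolic_time,
    systolic_vel_avg_pct_sv = 1000 * 100 / systolic_time,
    systolic_vel_peak_mls = 1000 * abs(min(v)),
    diastolic_vel_avg_mls = 1000 * sv / diastolic_time,
    diastolic_vel_avg_pct_sv = 1000 * 100 / diastolic_time,
    passive_vel_avg_mls = NA_real_, passive_vel_avg_pct_sv = NA_real_,
    passive_vel_peak_mls = NA_real_,
    active_vel_avg_mls = NA_real_, active_vel_avg_pct_sv = NA_real_,
    active_vel_peak_mls = NA_real_,
    sv_ml = sv, esv_ml = esv, edv_ml = edv, ef_pct = ef,
    diastasis_found = lm$diastasis_found,
    rr_from_metadata = rr_from_metadata
  )

  if (lm$diastasis_found) {
    t_mid <- lm$t_mid_diastasis
    v_mid <- sp(t_mid)
    ttd <- t_mid - lm$t_es
    passive_ml <- v_mid - esv
    active_ml <- edv - v_mid
    t_active_phase <- rr - t_mid
    pass_idx <- tt > lm$t_es & tt <= t_mid
    act_idx <- tt > t_mid
    m$time_to_diastasis_ms <- ttd
    m$time_to_diastasis_pct <- 100 * ttd / rr
    m$passive_filling_ml <- passive_ml
    m$passive_filling_pct_sv <- 100 * passive_ml / sv
    m$active_filling_ml <- active_ml
    m$active_filling_pct_sv <- 100 * active_ml / sv
    m$passive_vel_avg_mls <- 1000 * passive_ml / ttd
    m$passive_vel_avg_pct_sv <- 100 * m$passive_vel_avg_mls / sv
    m$passive_vel_peak_mls <- 1000 * max(v[pass_idx])
    m$active_vel_avg_mls <- 1000 * active_ml / t_active_phase
    m$active_vel_avg_pct_sv <- 100 * m$active_vel_avg_mls / sv
    m$active_vel_peak_mls <- 1000 * max(v[act_idx])
  }

  m$missing_flags <- vapply(m[setdiff(names(m), "missing_flags")],
                            function(x) any(is.na(x)), logical(1))
  class(m) <- "transient_metrics"
  m
}

#' @export
as.data.frame.transient_metrics <- function(x, ...) {
  as.data.frame(x[setdiff(names(x), "missing_flags")],
                stringsAsFactors = FALSE)
}

#' @export
print.transient_metrics <- function(x, ...) {
  cat(sprintf("Transient metrics: RR %.0f ms (var %.1f%%RR), EDV %.1f / ESV %.1f mL, EF %.1f%%\n",
              x$rr_ms, x$rr_variability_pct_rr, x$edv_ml, x$esv_ml, x$ef_pct))
  cat(sprintf("  systole %.0f ms, diastole %.0f ms, diastasis %s\n",
              x$systolic_time_ms, x$diastolic_time_ms,
              if (x$diastasis_found) sprintf("%.0f ms", x$diastasis_ms)
              else "not found"))
  if (x$diastasis_found) {
    cat(sprintf("  filling: passive %.1f mL (%.1f%%SV) / active %.1f mL (%.1f%%SV)\n",
                x$passive_filling_ml, x$passive_filling_pct_sv,
                x$active_filling_ml, x$active_filling_pct_sv))
  }
  invisible(x)
}

#' Conventional metrics for a whole cohort
#'
#' @param transients list of [volume_transient()] objects.
#' @param rr_lists optional list of per-patient RR metadata vectors (ms),
#'   matched by position.
#' @param ... passed to [compute_conventional_metrics()].
#' @return a data.frame with one row per patient (`patient_id` first).
#' @export
compute_metrics_cohort <- function(transients, rr_lists = NULL, ...) {
  rows <- lapply(seq_along(transients), function(i) {
    tr <- transients[[i]]
    rr <- if (is.null(rr_lists)) tr$rr_ms else rr_lists[[i]]
    df <- as.data.frame(compute_conventional_metrics(tr, rr_list = rr, ...))
    cbind(patient_id = tr$patient_id, df, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
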