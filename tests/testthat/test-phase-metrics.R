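test_that("a single-dip cosine yields the analytic ES and systolic peak-velocity times", {
  rr <- 800
  tt <- seq(0, rr, length.out = 41)[1:40]
  vol <- 100 + 20 * cos(2 * pi * tt / rr)
  tr <- volume_transient(tt, vol, rr_ms = rr)
  lm <- detect_landmarks(tr)
  expect_equal(lm$t_ed, 0, tolerance = 2 * lm$step_ms)
  expect_equal(lm$t_es, rr / 2, tolerance = lm$step_ms)
  expect_equal(lm$t_sys_peak_vel, rr / 4, tolerance = lm$step_ms)
})

test_that("degenerate transients raise structural errors", {
  const <- volume_transient(seq(0, 780, by = 60), rep(90, 14), rr_ms = 840)
  expect_error(detect_landmarks(const), "structural")
  rising <- volume_transient(seq(0, 780, by = 60), seq(50, 120, length.out = 14),
                             rr_ms = 840)
  expect_error(detect_landmarks(rising), "structural")
})

test_that("all eight landmarks and the diastasis duration recover planted values on noise-free transients", {
  set.seed(41)
  for (i in 1:50) {
    dp <- draw_recovery_params()
    tr <- generate_transient(dp$params, dp$n_frames, noise_sd_ml = 0)
    lm <- detect_landmarks(tr)
    truth <- unlist(vt_landmarks(dp$params))
    est <- unlist(lm[names(truth)])
    expect_true(all(abs(est - truth) <= lm$step_ms),
                info = sprintf("patient %d: max err %.2f steps", i,
                               max(abs(est - truth)) / lm$step_ms))
    expect_lt(abs(lm$diastasis_ms - dp$params$diastasis_ms), lm$step_ms)
  }
})

test_that("the diastasis velocity threshold is 80% of stroke volume per second", {
  # constant filling at 1.2 SV/s: everywhere above threshold, no diastasis
  fast <- linear_filling_transient(1.2)
  expect_false(detect_diastasis(fast)$found)
  # constant filling at 0.7 SV/s: everywhere below, the whole mid-diastole
  # is quiescent by the threshold rule
  slow <- linear_filling_transient(0.7)
  d <- detect_diastasis(slow)
  expect_true(d$found)
  expect_gt(d$duration_ms, 100)
})

test_that("merged filling phases (no plateau) report diastasis absent, not an error", {
  p <- canonical_params(diastasis_ms = 0, passive_ms = 430)
  tr <- generate_transient(p, 28)
  d <- detect_diastasis(tr)
  expect_false(d$found)
  expect_equal(d$duration_ms, 0)
  m <- compute_conventional_metrics(tr, rr_list = 845)
  expect_true(is.na(m$passive_filling_ml))
  expect_true(is.na(m$active_vel_peak_mls))
  expect_true(m$missing_flags[["passive_filling_ml"]])
  expect_false(m$missing_flags[["systolic_time_ms"]])
})

test_that("RR statistics follow the max-minus-min-over-mean definition", {
  p <- canonical_params()
  tr <- generate_transient(p, 28)
  m <- compute_conventional_metrics(tr, rr_list = c(700, 800, 900))
  expect_equal(m$rr_ms, 800)
  expect_equal(m$rr_variability_pct_rr, 25)
  expect_warning(m2 <- compute_conventional_metrics(tr, rr_list = NULL),
                 "RR metadata")
  expect_equal(m2$rr_ms, p$rr_ms)
  expect_false(m2$rr_from_metadata)
})

test_that("volume metrics satisfy the conservation and normalization identities", {
  set.seed(43)
  checked <- 0
  for (i in 1:30) {
    dp <- draw_recovery_params()
    tr <- generate_transient(dp$params, dp$n_frames,
                             noise_sd_ml = dp$noise_sd_ml)
    m <- compute_conventional_metrics(tr, rr_list = dp$rr_ms)
    expect_equal(m$systolic_time_ms + m$diastolic_time_ms, m$rr_ms)
    expect_equal(m$ef_pct, 100 * m$sv_ml / m$edv_ml, tolerance = 1e-12)
    if (m$diastasis_found) {
      checked <- checked + 1
      expect_equal(m$passive_filling_ml + m$active_filling_ml, m$sv_ml,
                   tolerance = 1e-9)
      for (fld in c("passive_filling", "active_filling")) {
        expect_equal(m[[paste0(fld, "_pct_sv")]] * m$sv_ml / 100,
                     m[[paste0(fld, "_ml")]], tolerance = 1e-9)
      }
      expect_equal(m$diastasis_pct, 100 * m$diastasis_ms / m$rr_ms,
                   tolerance = 1e-12)
      expect_equal(m$passive_vel_avg_pct_sv * m$sv_ml / 100,
                   m$passive_vel_avg_mls, tolerance = 1e-9)
    }
  }
  expect_gt(checked, 10)
})

test_that("computed metrics match closed-form oracle values on noise-free patients", {
  set.seed(47)
  for (i in 1:60) {
    dp <- draw_recovery_params()
    tr <- generate_transient(dp$params, dp$n_frames, noise_sd_ml = 0)
    lm <- detect_landmarks(tr)
    m <- compute_conventional_metrics(tr, lm = lm, rr_list = dp$rr_ms)
    o <- vt_analytic_metrics(dp$params, rr_list = dp$rr_ms)
    step <- lm$step_ms
    expect_equal(m$systolic_time_ms, o$systolic_time_ms, tolerance = 0.01)
    expect_equal(m$diastasis_ms, o$diastasis_ms, tolerance = step,
                 info = "diastasis duration")
    expect_equal(m$time_to_diastasis_ms, o$time_to_diastasis_ms,
                 tolerance = 2 * step)
    expect_lt(abs(m$passive_filling_ml - o$passive_filling_ml),
              0.01 * o$sv_ml)
    expect_lt(abs(m$active_filling_ml - o$active_filling_ml),
              0.01 * o$sv_ml)
    expect_equal(m$edv_ml, o$edv_ml, tolerance = 0.01)
    expect_equal(m$esv_ml, o$esv_ml, tolerance = 0.01)
    expect_equal(m$systolic_vel_peak_mls, o$systolic_vel_peak_mls,
                 tolerance = 0.02)
    expect_equal(m$passive_vel_peak_mls, o$passive_vel_peak_mls,
                 tolerance = 0.02)
    # narrow atrial phases (down to the 80 ms floor) are resolution-limited
    # at 25-30 frames/cycle: the spline underestimates the peak by up to ~8%
    expect_equal(m$active_vel_peak_mls, o$active_vel_peak_mls,
                 tolerance = 0.10)
    expect_equal(m$systolic_vel_avg_mls, o$systolic_vel_avg_mls,
                 tolerance = 0.02)
    expect_equal(m$passive_vel_avg_mls, o$passive_vel_avg_mls,
                 tolerance = 0.05)
    expect_equal(m$active_vel_avg_mls, o$active_vel_avg_mls,
                 tolerance = 0.05)
  }
})

test_that("landmark estimates are stable under 1%-SV volume noise", {
  set.seed(53)
  moves <- NULL
  for (i in 1:30) {
    dp <- draw_recovery_params()
    clean <- generate_transient(dp$params, dp$n_frames, noise_sd_ml = 0)
    noisy <- generate_transient(dp$params, dp$n_frames,
                                noise_sd_ml = 0.01 * dp$params$sv_ml)
    lmc <- detect_landmarks(clean)
    lmn <- detect_landmarks(noisy)
    keep <- c("t_ed", "t_sys_peak_vel", "t_es", "t_passive_peak_vel",
              "t_active_peak_vel")
    moves <- rbind(moves, abs(unlist(lmn[keep]) - unlist(lmc[keep])) /
                     lmc$step_ms)
  }
  # anchor landmarks: median displacement well under a frame interval
  # (~10 dense steps), worst case bounded (regression bounds from the
  # measured estimator behaviour at this noise level)
  expect_lt(max(apply(moves, 2, stats::median)), 6)
  expect_lt(max(moves), 25)
})
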