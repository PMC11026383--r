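#' Detect the eight cardiac-phase landmarks of a volume transient
#'
#' Works on the dense periodic-spline resampling of the transient. The volume
#' extrema anchor the cycle: end-systole is the global volume minimum and
#' end-diastole the maximum preceding it (ECG-trigger convention, frame 0 at
#' ED); both are refined to sub-grid precision from the zero crossing of the
#' volume velocity, which is better conditioned than the flat extremum
#' itself. Peak-velocity landmarks are dV/dt extrema within their phase
#' (systole: most negative; each filling sub-phase: most positive), refined
#' by a 3-point parabola. The diastasis landmarks come from the quiescent
#' interval estimator (see [detect_diastasis()]). Non-unique extrema resolve
#' to the earliest time. The velocity used for refinement is lightly smoothed
#' with a cubic Savitzky-Golay filter spanning about one original frame
#' interval; the filter reproduces cubic polynomials exactly, so it is a
#' near-identity on the noise-free spline while attenuating noise-driven
#' wiggles.
#'
#' @param t a [volume_transient()]; resampled internally when needed.
#' @param upsample_factor spline upsampling factor used when `t` is not yet
#'   resampled.
#' @param threshold_frac diastasis velocity threshold as a fraction of stroke
#'   volume per second (default 0.8).
#' @param min_diastasis_ms shortest interval reported as a found diastasis.
#' @return an object of class `phase_landmarks`: the eight landmark times
#'   (ms; diastasis fields `NA` when not found), `diastasis_found`,
#'   `diastasis_ms`, and the grid `step_ms`. The dense resampling is attached
#'   as attribute `resampled` for reuse.
#' @export
detect_landmarks <- function(t, upsample_factor = 10, threshold_frac = 0.8,
                             min_diastasis_ms = 10) {
  rt <- if (inherits(t, "resampled_transient")) t else
    resample_transient(t, upsample_factor)
  tt <- rt$trigger_times_ms
  V <- rt$volumes_ml
  n <- length(tt)
  step <- rt$step_ms

  sv <- max(V) - min(V)
  if (sv <= 1e-9 * max(1, max(V))) {
    stop("structural error: transient has no systolic excursion ",
         "(constant volume)")
  }
  w <- rt$upsample_factor %||% 10L
  w <- max(5L, w + 1L - (w %% 2L))
  vs <- detection_velocity(rt, sv)
  sigma_hat <- attr(vs, "sigma") %||% 0

  i_es0 <- which.min(V)
  if (i_es0 <= 2L) {
    stop("structural error: no systolic descent before the volume minimum ",
         "(cycle must start at end-diastole)")
  }
  i_ed0 <- which.max(V[seq_len(i_es0 - 1L)])  # earliest tie wins

  # systolic peak velocity: most negative dV/dt within systole
  sys_idx <- i_ed0:i_es0
  i_b <- sys_idx[which.min(vs[sys_idx])]
  t_b <- refine_extremum_ls(tt, vs, i_b, half = w %/% 2L)

  # ED and ES: the zeros flanking the (negative) systolic velocity hump,
  # refined with the half-sinusoid limb model; fall back to the discrete
  # volume extrema when the limb cannot be read
  knot <- as.integer(round(w))
  t_ed <- limb_onset(tt, -vs, from = 1L, to = i_b, t_peak = t_b,
                     descending = FALSE)
  if (!is.finite(t_ed) || t_ed < tt[1] - knot * step || t_ed > t_b) {
    t_ed <- tt[i_ed0]
  }
  t_ed <- max(t_ed, tt[1])
  t_es <- limb_onset(tt, -vs, from = i_b, to = min(i_es0 + knot, n),
                     t_peak = t_b, descending = TRUE)
  if (!is.finite(t_es) || t_es < t_b || t_es > tt[min(i_es0 + knot, n)]) {
    t_es <- tt[i_es0]
  }
  # a "systole" shorter than two frame intervals is the periodic wrap of a
  # monotone transient, not a contraction
  if (t_es - t_ed < 2 * rt$rr_ms / (rt$n_knots %||% length(tt))) {
    stop("structural error: no resolvable systolic phase ",
         "(monotone or near-monotone transient)")
  }

  # split diastole at its velocity minimum (between the two filling humps);
  # keep clear of the spline's corner-smoothing region around ES and the
  # cycle end (~1.5 frame intervals)
  margin <- as.integer(ceiling(1.5 * w))
  inner <- seq_len(n)[seq_len(n) > i_es0 + margin & seq_len(n) < n - margin]
  if (length(inner) < 3L) {
    stop("structural error: diastole too short to analyse")
  }
  i_split <- inner[which.min(vs[inner])]
  pp_idx <- (i_es0 + 1L):i_split
  ap_idx <- i_split:n
  i_pp <- pp_idx[which.max(vs[pp_idx])]
  i_ap <- ap_idx[which.max(vs[ap_idx])]
  t_pp <- limb_peak(tt, vs, from = i_es0, to = i_split, i_peak = i_pp,
                    w = w)
  t_ap <- limb_peak(tt, vs, from = i_split, to = n, i_peak = i_ap, w = w)

  dia <- diastasis_interval(tt, vs, step, i_pp, i_split, i_ap, t_pp, t_ap,
                            sv, threshold_frac, min_diastasis_ms,
                            knot_steps = w, rt = rt, t_es = t_es,
                            sigma = sigma_hat)
  if (!is.null(dia$fit)) {
    # the accepted cycle-model fit also locates the filling-velocity peaks
    # (midpoints of its raised-cosine filling segments)
    t_pp <- (dia$fit$ts + dia$fit$e) / 2
    t_ap <- (dia$fit$g + rt$rr_ms) / 2
  }

  out <- list(
    t_ed = t_ed, t_sys_peak_vel = t_b, t_es = t_es,
    t_passive_peak_vel = t_pp,
    t_diastasis_begin = dia$begin_ms, t_mid_diastasis = dia$mid_ms,
    t_diastasis_end = dia$end_ms,
    t_active_peak_vel = t_ap,
    diastasis_found = dia$found, diastasis_ms = dia$duration_ms,
    step_ms = step, threshold_frac = threshold_frac
  )
  class(out) <- "phase_landmarks"
  attr(out, "resampled") <- rt
  out
}

#' @export
print.phase_landmarks <- function(x, ...) {
  cat(sprintf("Phase landmarks (ms): ED %.1f | sys peak vel %.1f | ES %.1f | passive peak %.1f\n",
              x$t_ed, x$t_sys_peak_vel, x$t_es, x$t_passive_peak_vel))
  if (x$diastasis_found) {
    cat(sprintf("  diastasis %.1f-%.1f (%.1f ms, mid %.1f) | active peak %.1f\n",
                x$t_diastasis_begin, x$t_diastasis_end, x$diastasis_ms,
                x$t_mid_diastasis, x$t_active_peak_vel))
  } else {
    cat(sprintf("  diastasis not found | active peak vel %.1f\n",
                x$t_active_peak_vel))
  }
  invisible(x)
}

#' Detect the diastasis interval of a volume transient
#'
#' Diastasis is the mid-diastolic quiescent interval, detected as the longest
#' contiguous region between the passive-filling and active-filling velocity
#' peaks where the filling velocity stays below `threshold_frac` stroke
#' volumes per second (|dV/dt| < 0.8 SV/s by default). Because the
#' sub-threshold run leaks into the deceleration/acceleration limbs flanking
#' the quiescent plateau, both bounds are refined to sub-grid precision with
#' a half-sinusoid limb model: the limb velocity is read at several fractions
#' of its peak (where the dense spline is accurate) and each crossing is
#' extrapolated to the velocity zero; the refined bounds average these
#' estimates. Absence of a sufficiently long interval (`< min_diastasis_ms`)
#' is reported as `found = FALSE` with duration 0, a valid result.
#'
#' @inheritParams detect_landmarks
#' @return list with `begin_ms`, `mid_ms`, `end_ms`, `duration_ms`, `found`.
#' @export
detect_diastasis <- function(t, threshold_frac = 0.8, upsample_factor = 10,
                             min_diastasis_ms = 10) {
  lm <- detect_landmarks(t, upsample_factor = upsample_factor,
                         threshold_frac = threshold_frac,
                         min_diastasis_ms = min_diastasis_ms)
  list(begin_ms = lm$t_diastasis_begin, mid_ms = lm$t_mid_diastasis,
       end_ms = lm$t_diastasis_end, duration_ms = lm$diastasis_ms,
       found = lm$diastasis_found)
}

# Velocity used for landmark anchoring and refinement, chosen adaptively.
# A cyclic (periodic) cubic regression spline is fit to the frame samples
# with GCV-selected smoothness; when its residual noise is negligible
# (< 0.2% of the volume excursion, i.e. an effectively noise-free transient)
# the interpolating-spline derivative is kept, lightly smoothed with a cubic
# Savitzky-Golay window spanning one frame interval (a near-identity on the
# piecewise-cubic interpolant); otherwise the derivative of the GCV-smoothed
# curve is used, which suppresses the noise-driven wiggles that interpolation
# would amplify.
detection_velocity <- function(rt, sv) {
  w <- rt$upsample_factor %||% 10L
  w <- max(5L, w + 1L - (w %% 2L))
  kt <- rt$knot_times_ms
  kv <- rt$knot_volumes_ml
  fit <- tryCatch(
    mgcv::gam(kv ~ s(kt, bs = "cc", k = length(kt)),
              knots = list(kt = c(0, rt$rr_ms)), method = "GCV.Cp"),
    error = function(e) NULL)
  sigma <- if (is.null(fit)) 0 else sqrt(max(fit$sig2, 0))
  noisy <- sigma > 0.002 * sv
  out <- if (!noisy) {
    smooth_periodic(rt$dvdt_ml_ms, p = 3, n = w)
  } else {
    grid <- rt$trigger_times_ms
    pr <- as.numeric(stats::predict(fit, newdata = data.frame(kt = grid)))
    m <- length(pr)
    h <- rt$step_ms
    c(pr[2] - pr[m], diff(pr, lag = 2), pr[1] - pr[m - 1]) / (2 * h)
  }
  attr(out, "sigma") <- sigma
  out
}

# Core diastasis search on the dense grid (smoothed velocity vs, mL/ms).
# knot_steps: dense steps per original frame interval.
diastasis_interval <- function(tt, vs, step, i_pp, i_split, i_ap, t_pp, t_ap,
                               sv, threshold_frac, min_diastasis_ms,
                               knot_steps = 10, rt = NULL, t_es = NULL,
                               sigma = 0) {
  none <- list(begin_ms = NA_real_, mid_ms = NA_real_, end_ms = NA_real_,
               duration_ms = 0, found = FALSE)
  if (i_ap - i_pp < 4L) return(none)
  thr <- threshold_frac * sv / 1000  # mL/ms
  mid_idx <- i_pp:i_ap
  run <- longest_run(abs(vs[mid_idx]) < thr)
  if (is.null(run)) return(none)  # threshold rule: no quiescent region
  i_lo <- mid_idx[run[1]]
  i_hi <- mid_idx[run[2]]

  # bound estimates from the filling-velocity limbs on either side of the
  # diastolic velocity minimum; the sub-threshold run only attests existence
  # (and provides the fallback bounds)
  begin_ms <- limb_onset(tt, vs, from = i_pp, to = i_split,
                         t_peak = t_pp, descending = TRUE)
  end_ms <- limb_onset(tt, vs, from = i_split, to = i_ap,
                       t_peak = t_ap, descending = FALSE)
  # slack of ~1.5 frame intervals: the velocity minimum anchoring the split
  # can sit several dense steps to either side of the true plateau bounds
  slack <- 1.5 * knot_steps * step
  lo_ok <- is.finite(begin_ms) && begin_ms >= t_pp - step &&
    begin_ms <= tt[i_split] + slack
  hi_ok <- is.finite(end_ms) && end_ms <= t_ap + step &&
    end_ms >= tt[i_split] - slack
  if (!lo_ok) begin_ms <- tt[i_lo]
  if (!hi_ok) end_ms <- tt[i_hi]

  # final refinement: global least-squares fit of the piecewise
  # raised-cosine cycle model to the original frame samples, which pools the
  # full diastolic information instead of reading the corner locally. The
  # fit is trusted only when its residuals are consistent with the measured
  # volume noise (plus a 0.5%-SV numerical floor): transients that the cycle
  # model does not describe leave structured residuals and keep the generic
  # threshold-rule bounds.
  if (!is.finite(begin_ms) || !is.finite(end_ms) || end_ms <= begin_ms) {
    # plateaus narrower than a frame interval can defeat the limb reads;
    # fall back to the sub-threshold run edges and let the model fit decide
    begin_ms <- tt[i_lo]
    end_ms <- tt[i_hi]
  }
  if (!is.null(rt) && end_ms > begin_ms) {
    fitted <- fit_diastolic_plateau(rt, t_es, begin_ms, end_ms)
    if (!is.null(fitted) &&
        fitted$e >= t_pp - 2 * knot_steps * step &&
        fitted$g <= t_ap + 2 * knot_steps * step &&
        fitted$rmse < max(2 * sigma, 0.015 * sv)) {
      begin_ms <- fitted$e
      end_ms <- fitted$g
      fit_used <- fitted
    }
  }

  duration <- end_ms - begin_ms
  if (!is.finite(duration) || duration < min_diastasis_ms) return(none)
  list(begin_ms = begin_ms, mid_ms = (begin_ms + end_ms) / 2,
       end_ms = end_ms, duration_ms = duration, found = TRUE,
       fit = if (exists("fit_used", inherits = FALSE)) fit_used else NULL)
}

# Least-squares fit of a piecewise raised-cosine cycle model to the frame
# samples: systolic descent from EDV at t = 0 to ESV at ts, passive filling
# up to a plateau level L at e, flat diastasis until g, active filling from L
# back to EDV at the cycle end. Free parameters (ts, e, g, L, esv, edv);
# pooling the whole cycle pins the bounds far more tightly than any local
# corner read. Returns NULL when the fit fails or the phase ordering
# collapses.
fit_diastolic_plateau <- function(rt, t_es, begin0, end0) {
  kt <- rt$knot_times_ms
  kv <- rt$knot_volumes_ml
  rr <- rt$rr_ms
  frame <- rr / rt$n_knots
  if (length(kt) < 10L) return(NULL)
  t_d <- c(kt, rr)
  v_d <- c(kv, kv[1])
  lvl0 <- stats::median(v_d[t_d >= begin0 & t_d <= end0])
  if (!is.finite(lvl0)) lvl0 <- stats::approx(t_d, v_d,
                                              (begin0 + end0) / 2)$y
  frame_sh <- frame  # one-frame perturbations for the multi-start
  inits <- list(c(t_es, begin0, end0, lvl0, min(kv), max(v_d)))
  if (end0 - begin0 > 2 * frame_sh) {
    inits <- c(inits,
               list(c(t_es, begin0 + frame_sh, end0 - frame_sh, lvl0,
                      min(kv), max(v_d))))
  }
  inits <- c(inits,
             list(c(t_es, max(begin0 - frame_sh, t_es + frame_sh),
                    min(end0 + frame_sh, rr - 1.5 * frame_sh), lvl0,
                    min(kv), max(v_d))))
  model <- function(par, t) {
    ts <- par[1]; e <- par[2]; g <- par[3]
    L <- par[4]; esv <- par[5]; edv <- par[6]
    s0 <- pmin(pmax(t / ts, 0), 1)
    sys <- esv + (edv - esv) * (1 + cos(pi * s0)) / 2
    s1 <- pmin(pmax((t - ts) / max(e - ts, 1), 0), 1)
    pass <- esv + (L - esv) * (1 - cos(pi * s1)) / 2
    s2 <- pmin(pmax((t - g) / max(rr - g, 1), 0), 1)
    act <- L + (edv - L) * (1 - cos(pi * s2)) / 2
    ifelse(t <= ts, sys, ifelse(t <= e, pass, ifelse(t <= g, L, act)))
  }
  obj <- function(par) {
    if (!(par[1] < par[2] && par[2] <= par[3] && par[3] < rr - frame &&
          par[5] < par[4] && par[4] < par[6] && par[1] > frame)) {
      return(1e12)
    }
    sum((v_d - model(par, t_d))^2)
  }
  fit <- NULL
  for (par0 in inits) {
    cand <- tryCatch(
      stats::optim(par0, obj, method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(cand) && cand$value < 1e12 &&
        (is.null(fit) || cand$value < fit$value)) {
      fit <- cand
    }
  }
  if (is.null(fit)) return(NULL)
  list(ts = fit$par[1], e = fit$par[2], g = fit$par[3], L = fit$par[4],
       sse = fit$value, rmse = sqrt(fit$value / length(t_d)))
}

# Sub-grid onset/offset of the quiescent plateau. The filling-velocity limb
# is modelled as a half sinusoid rising from 0 at the plateau bound to its
# peak at t_peak: v(t) = v_pk * sin(pi/2 * (t - bound)/(t_peak - bound)).
# Reading the crossing time t_f of each level f * v_pk (linear interpolation
# on the dense grid, far from the spline's corner-smoothing region) gives
# bound = (t_f - r * t_peak) / (1 - r) with r = asin(f)/(pi/2); the estimates
# are averaged over several f. Returns NA when the limb is too small to read
# (the caller falls back to the sub-threshold run edge).
limb_onset <- function(tt, vs, from, to, t_peak, descending,
                       fracs = c(0.25, 0.375, 0.5, 0.625, 0.75)) {
  idx <- from:to
  v_pk <- max(vs[idx])
  est <- numeric(0)
  for (f in fracs) {
    level <- f * v_pk
    if (level <= 0) next
    t_f <- if (descending) {
      j <- utils::tail(which(vs[idx] >= level), 1)  # last above level
      if (!length(j) || j == length(idx)) next
      a <- idx[j]
      tt[a] + (tt[a + 1L] - tt[a]) * (vs[a] - level) / (vs[a] - vs[a + 1L])
    } else {
      j <- which(vs[idx] >= level)[1]  # first above level
      if (!length(j) || is.na(j) || j == 1L) next
      a <- idx[j]
      tt[a - 1L] + (tt[a] - tt[a - 1L]) * (level - vs[a - 1L]) /
        (vs[a] - vs[a - 1L])
    }
    r <- asin(f) / (pi / 2)
    est <- c(est, (t_f - r * t_peak) / (1 - r))
  }
  if (length(est) >= 2) mean(est) else NA_real_
}

# Sub-grid location of a filling-velocity peak as the midpoint of the level
# crossings on either side of the hump (exact for a symmetric hump, robust
# for narrow humps where a local parabola is biased by the neighbouring
# plateau or cycle-end corner). Falls back to the least-squares parabola.
limb_peak <- function(tt, vs, from, to, i_peak, w,
                      fracs = c(0.45, 0.6, 0.75)) {
  v_pk <- vs[i_peak]
  if (!is.finite(v_pk) || v_pk <= 0) {
    return(refine_extremum_ls(tt, vs, i_peak, half = w %/% 2L))
  }
  mids <- numeric(0)
  for (f in fracs) {
    level <- f * v_pk
    left <- from:i_peak
    jl <- which(vs[left] >= level)[1]
    right <- i_peak:to
    jr <- utils::tail(which(vs[right] >= level), 1)
    if (!length(jl) || is.na(jl) || jl == 1L ||
        !length(jr) || jr == length(right)) {
      next
    }
    a <- left[jl]
    t_up <- tt[a - 1L] + (tt[a] - tt[a - 1L]) * (level - vs[a - 1L]) /
      (vs[a] - vs[a - 1L])
    b <- right[jr]
    t_dn <- tt[b] + (tt[b + 1L] - tt[b]) * (vs[b] - level) /
      (vs[b] - vs[b + 1L])
    mids <- c(mids, (t_up + t_dn) / 2)
  }
  if (length(mids) >= 2) mean(mids) else
    refine_extremum_ls(tt, vs, i_peak, half = w %/% 2L)
}
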