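#' Volume transient container
#'
#' One cardiac cycle of LV cavity volume: strictly increasing trigger times
#' (ms, starting at 0) and one volume (mL) per frame, plus the cycle length
#' `rr_ms` (at least the last trigger time). When `rr_ms` is not supplied it
#' is extrapolated as the last trigger time plus one median frame interval
#' and the transient is flagged (`attr(x, "rr_source") == "extrapolated"`).
#'
#' @param trigger_times_ms frame trigger times, ms.
#' @param volumes_ml cavity volumes, mL (non-negative).
#' @param rr_ms cycle length, ms, or `NULL` to extrapolate.
#' @param patient_id identifier.
#' @return an object of class `volume_transient`.
#' @export
volume_transient <- function(trigger_times_ms, volumes_ml, rr_ms = NULL,
                             patient_id = "unknown") {
  stopifnot(length(trigger_times_ms) == length(volumes_ml),
            length(trigger_times_ms) >= 1,
            all(is.finite(trigger_times_ms)), all(is.finite(volumes_ml)))
  if (length(trigger_times_ms) > 1 && any(diff(trigger_times_ms) <= 0)) {
    stop("trigger times must be strictly increasing")
  }
  if (trigger_times_ms[1] < 0) stop("trigger times must start at or after 0")
  if (any(volumes_ml < 0)) stop("volumes must be non-negative")
  rr_source <- "metadata"
  if (is.null(rr_ms)) {
    dt <- if (length(trigger_times_ms) > 1) {
      stats::median(diff(trigger_times_ms))
    } else {
      1
    }
    rr_ms <- utils::tail(trigger_times_ms, 1) + dt
    rr_source <- "extrapolated"
  }
  if (rr_ms < utils::tail(trigger_times_ms, 1)) {
    stop("rr_ms must be at least the last trigger time")
  }
  out <- list(trigger_times_ms = as.numeric(trigger_times_ms),
              volumes_ml = as.numeric(volumes_ml),
              rr_ms = as.numeric(rr_ms), patient_id = patient_id)
  class(out) <- "volume_transient"
  attr(out, "rr_source") <- rr_source
  out
}

#' @export
print.volume_transient <- function(x, ...) {
  cat(sprintf(
    "Volume transient '%s': %d frames over RR %.0f ms, V in [%.1f, %.1f] mL\n",
    x$patient_id, length(x$trigger_times_ms), x$rr_ms,
    min(x$volumes_ml), max(x$volumes_ml)))
  invisible(x)
}

#' Segmentation stack container
#'
#' Binary LV-cavity masks over the cardiac cycle: `frames x slices x rows x
#' cols`, with in-plane pixel spacing (mm), slice spacing (mm) and per-frame
#' trigger times (ms). Slice positions are taken at slice centers with uniform
#' spacing.
#'
#' @param masks 4-d binary array `frames x slices x rows x cols`.
#' @param pixel_spacing_mm length-2 in-plane spacing (row, col), mm.
#' @param slice_spacing_mm distance between slice centers, mm.
#' @param trigger_times_ms strictly increasing frame times starting at 0.
#' @param patient_id identifier.
#' @return an object of class `segmentation_stack`.
#' @export
segmentation_stack <- function(masks, pixel_spacing_mm, slice_spacing_mm,
                               trigger_times_ms, patient_id = "unknown") {
  stopifnot(length(dim(masks)) == 4, length(pixel_spacing_mm) == 2,
            all(pixel_spacing_mm > 0), slice_spacing_mm > 0)
  if (!is_binary01(masks)) stop("masks must be binary (0/1)")
  if (length(trigger_times_ms) != dim(masks)[1]) {
    stop("one trigger time per frame required")
  }
  if (trigger_times_ms[1] != 0 || any(diff(trigger_times_ms) <= 0)) {
    stop("trigger times must start at 0 and be strictly increasing")
  }
  out <- list(masks = masks, pixel_spacing_mm = as.numeric(pixel_spacing_mm),
              slice_spacing_mm = as.numeric(slice_spacing_mm),
              trigger_times_ms = as.numeric(trigger_times_ms),
              patient_id = patient_id)
  class(out) <- "segmentation_stack"
  out
}

#' Integrate cavity volume from a segmentation stack
#'
#' Per frame, each slice contributes a cross-sectional area `A_i = (pixel
#' count) * (pixel area)`; the cavity volume is the trapezoidal rule over the
#' uniformly spaced slice positions, `spacing * (A_1/2 + A_2 + ... + A_n/2)`,
#' converted from mm^3 to mL. Frames whose masks are empty in all slices get
#' volume 0 with a warning.
#'
#' @param stack a [segmentation_stack()].
#' @param rr_ms optional cycle length from scan metadata; extrapolated from
#'   the trigger times when absent.
#' @return a [volume_transient()].
#' @export
integrate_cavity_volume <- function(stack, rr_ms = NULL) {
  stopifnot(inherits(stack, "segmentation_stack"))
  d <- dim(stack$masks)
  pixel_area <- prod(stack$pixel_spacing_mm)
  vols <- vapply(seq_len(d[1]), function(f) {
    areas <- vapply(seq_len(d[2]), function(s) {
      sum(stack$masks[f, s, , ]) * pixel_area
    }, numeric(1))
    n <- length(areas)
    if (n < 2) return(stack$slice_spacing_mm * areas[1])
    stack$slice_spacing_mm * (sum(areas) - (areas[1] + areas[n]) / 2)
  }, numeric(1))
  if (any(vols == 0)) {
    warning("frame(s) with empty masks in all slices: volume set to 0")
  }
  volume_transient(stack$trigger_times_ms, vols / 1000, rr_ms = rr_ms,
                   patient_id = stack$patient_id)
}

#' Resample a transient with a periodic cubic spline
#'
#' Interpolates the one-cycle transient with a periodic cubic spline (the
#' curve is one cardiac cycle, so V(rr) = V(0)) onto a uniform grid of
#' `upsample_factor * n` points over `[0, rr_ms)`, reproducing the original
#' knot values exactly, and evaluates the first and second derivatives on the
#' same grid. Slope-sensitive metrics (peak velocities, diastasis) are
#' computed from this dense grid.
#'
#' @param t a [volume_transient()].
#' @param upsample_factor integer >= 1; default 10.
#' @return a `volume_transient` with additional fields `dvdt_ml_ms`,
#'   `d2vdt2`, `step_ms`, and the interpolant stored as attribute `spline`.
#' @export
resample_transient <- function(t, upsample_factor = 10) {
  stopifnot(inherits(t, "volume_transient"), upsample_factor >= 1)
  n <- length(t$trigger_times_ms)
  if (n < 4) stop("at least 4 samples required for spline interpolation")
  kt <- t$trigger_times_ms
  kv <- t$volumes_ml
  if (utils::tail(kt, 1) < t$rr_ms) {  # close the cycle: V(rr) = V(0)
    kt <- c(kt, t$rr_ms)
    kv <- c(kv, kv[1])
  } else {
    kv[length(kv)] <- kv[1]
  }
  sp <- stats::splinefun(kt, kv, method = "periodic")
  m <- as.integer(upsample_factor) * n
  grid <- seq(0, t$rr_ms, length.out = m + 1)[seq_len(m)]
  out <- volume_transient(grid, pmax(sp(grid), 0), rr_ms = t$rr_ms,
                          patient_id = t$patient_id)
  out$dvdt_ml_ms <- sp(grid, deriv = 1)
  out$d2vdt2 <- sp(grid, deriv = 2)
  out$step_ms <- t$rr_ms / m
  out$n_knots <- n
  out$knot_times_ms <- t$trigger_times_ms
  out$knot_volumes_ml <- t$volumes_ml
  out$upsample_factor <- as.integer(upsample_factor)
  attr(out, "spline") <- sp
  attr(out, "rr_source") <- attr(t, "rr_source")
  attr(out, "planted") <- attr(t, "planted")
  class(out) <- c("resampled_transient", "volume_transient")
  out
}
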