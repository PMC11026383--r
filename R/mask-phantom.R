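#' Generate an ellipsoidal cavity mask phantom
#'
#' Builds per-frame binary masks of an ellipsoidal cavity cross-sectioned at
#' uniformly spaced slice centers, mimicking a short-axis segmentation stack.
#' The analytic volume `4/3 * pi * a * b * c` is attached per frame as ground
#' truth, which makes the phantom the oracle for trapezoidal volume
#' integration. Slice centers are placed symmetrically about the ellipsoid
#' center at `z_k = (k - (n_slices + 1)/2) * slice_spacing_mm`; a voxel is in
#' the cavity when `(x/a)^2 + (y/b)^2 + (z/c)^2 <= 1` at its slice center.
#'
#' @param semi_axes_mm numeric length-3 `(a, b, c)` in mm (c along the slice
#'   axis), or an `n_frames x 3` matrix for a multi-frame phantom. Axes of 0
#'   give empty masks.
#' @param pixel_mm in-plane pixel size, mm (isotropic).
#' @param slice_spacing_mm distance between slice centers, mm.
#' @param n_slices number of slices; must cover the ellipsoid.
#' @param trigger_times_ms optional frame times; defaults to 40 ms spacing.
#' @param margin_mm in-plane padding around the largest semi-axis.
#' @return a [segmentation_stack()] with attribute `analytic_volume_ml`.
#' @examples
#' st <- generate_mask_stack(c(25, 25, 40), pixel_mm = 1.25,
#'                           slice_spacing_mm = 8, n_slices = 11)
#' attr(st, "analytic_volume_ml")  # 104.72 mL
#' @export
generate_mask_stack <- function(semi_axes_mm, pixel_mm = 1.25,
                                slice_spacing_mm = 8, n_slices = 12,
                                trigger_times_ms = NULL, margin_mm = 4) {
  if (is.null(dim(semi_axes_mm))) semi_axes_mm <- matrix(semi_axes_mm, nrow = 1)
  stopifnot(ncol(semi_axes_mm) == 3, all(semi_axes_mm >= 0),
            pixel_mm > 0, slice_spacing_mm > 0, n_slices >= 2)
  n_frames <- nrow(semi_axes_mm)
  trigger_times_ms <- trigger_times_ms %||% (40 * (seq_len(n_frames) - 1))

  z <- (seq_len(n_slices) - (n_slices + 1) / 2) * slice_spacing_mm
  if (max(semi_axes_mm[, 3]) > max(abs(z)) + slice_spacing_mm / 2) {
    stop("ellipsoid exceeds the slice coverage: increase n_slices")
  }
  half_extent <- max(semi_axes_mm[, 1:2]) + margin_mm
  npix <- 2L * ceiling(half_extent / pixel_mm) + 1L
  xy <- (seq_len(npix) - (npix + 1) / 2) * pixel_mm

  masks <- array(0L, dim = c(n_frames, n_slices, npix, npix))
  for (f in seq_len(n_frames)) {
    a <- semi_axes_mm[f, 1]; b <- semi_axes_mm[f, 2]; cc <- semi_axes_mm[f, 3]
    if (a == 0 || b == 0 || cc == 0) next
    q <- outer((xy / a)^2, (xy / b)^2, `+`)  # rows = x, cols = y
    for (s in seq_len(n_slices)) {
      rem <- 1 - (z[s] / cc)^2
      if (rem > 0) masks[f, s, , ] <- (q <= rem) * 1L
    }
  }
  st <- segmentation_stack(masks, pixel_spacing_mm = c(pixel_mm, pixel_mm),
                           slice_spacing_mm = slice_spacing_mm,
                           trigger_times_ms = trigger_times_ms,
                           patient_id = "phantom")
  attr(st, "analytic_volume_ml") <-
    4 / 3 * pi * semi_axes_mm[, 1] * semi_axes_mm[, 2] * semi_axes_mm[, 3] / 1000
  st
}

#' Write a segmentation stack as NIfTI plus a JSON sidecar
#'
#' The mask array is stored as a 4-d NIfTI volume (rows x cols x slices x
#' frames) with the voxel spacings in `pixdim`; trigger times, patient id and
#' spacings are duplicated in a JSON sidecar next to the image.
#'
#' @param stack a [segmentation_stack()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_mask_stack <- function(stack, path) {
  stopifnot(inherits(stack, "segmentation_stack"))
  d <- dim(stack$masks)
  arr <- aperm(stack$masks, c(3, 4, 2, 1))  # rows, cols, slices, frames
  img <- RNifti::asNifti(arr)
  dt <- if (d[1] > 1) stats::median(diff(stack$trigger_times_ms)) else 1
  img <- RNifti::`pixdim<-`(img, c(stack$pixel_spacing_mm,
                                   stack$slice_spacing_mm, dt))
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(patient_id = stack$patient_id,
         trigger_times_ms = stack$trigger_times_ms,
         pixel_spacing_mm = stack$pixel_spacing_mm,
         slice_spacing_mm = stack$slice_spacing_mm),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a segmentation stack written by [write_mask_stack()]
#'
#' @param path path to the NIfTI file (JSON sidecar expected alongside).
#' @return a [segmentation_stack()].
#' @export
read_mask_stack <- function(path) {
  img <- RNifti::readNifti(path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  d <- dim(img)
  if (length(d) == 3) d <- c(d, 1L)  # single-frame stacks drop the 4th dim
  arr <- aperm(array(as.integer(img > 0.5), dim = d), c(4, 3, 1, 2))
  segmentation_stack(arr, pixel_spacing_mm = meta$pixel_spacing_mm,
                     slice_spacing_mm = meta$slice_spacing_mm,
                     trigger_times_ms = meta$trigger_times_ms,
                     patient_id = meta$patient_id)
}
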