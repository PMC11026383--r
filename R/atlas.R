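#' Min-max normalize a transient onto a common cycle-fraction grid
#'
#' Resamples the transient with a periodic cubic spline onto `G` uniform
#' points of cycle fraction `u in [0, 1)` and maps the values through
#' `(V - Vmin) / (Vmax - Vmin)`, standardizing away ventricle size and stroke
#' volume so that only contraction shape remains. Time is expressed as cycle
#' fraction, so absolute RR-interval length is also removed; RR-related
#' information survives only through shape (e.g. the relative diastasis
#' length).
#'
#' @param t a [volume_transient()].
#' @param G grid size (default 100).
#' @return an object of class `normalized_transient`: numeric length `G` in
#'   `[0, 1]` with attributes `patient_id` and `G`.
#' @export
normalize_transient <- function(t, G = 100) {
  stopifnot(inherits(t, "volume_transient"), G >= 8)
  rt <- if (inherits(t, "resampled_transient")) t else resample_transient(t, 1)
  sp <- attr(rt, "spline")
  u <- seq(0, 1, length.out = G + 1)[seq_len(G)]
  vals <- sp(u * t$rr_ms)
  rng <- range(vals)
  if (diff(rng) < 1e-9 * max(1, abs(rng[2]))) {
    stop("degenerate transient: constant volume cannot be min-max normalized")
  }
  out <- (vals - rng[1]) / diff(rng)
  attr(out, "patient_id") <- t$patient_id
  attr(out, "G") <- as.integer(G)
  class(out) <- "normalized_transient"
  out
}

# Coerce a list of normalized transients (or a matrix) to an n x G matrix.
as_curve_matrix <- function(cohort) {
  if (is.matrix(cohort)) return(cohort)
  stopifnot(length(cohort) >= 1)
  X <- do.call(rbind, lapply(cohort, as.numeric))
  rownames(X) <- vapply(seq_along(cohort), function(i) {
    attr(cohort[[i]], "patient_id") %||% sprintf("S%04d", i)
  }, character(1))
  X
}

#' Fit a PCA atlas of normalized volume transients
#'
#' Mean-centers the cohort of min-max normalized curves and eigendecomposes
#' the sample covariance (deterministic, no randomized solver). The retained
#' modes are the smallest set whose cumulative variance fraction reaches
#' `variance_threshold`; each mode's sign is fixed by making its
#' largest-magnitude loading positive. A cohort of identical curves yields a
#' valid atlas with zero modes.
#'
#' @param cohort list of [normalize_transient()] curves (or an `n x G`
#'   matrix, rows = patients).
#' @param variance_threshold fraction of total variance to retain (default
#'   0.95).
#' @return an object of class `transient_atlas`: `mean_curve`, `modes`
#'   (`G x m`, orthonormal columns), `eigenvalues` (all), `variance_fractions`,
#'   `cumulative_variance`, `n_modes`, `G`, `n_subjects`,
#'   `variance_threshold`.
#' @export
fit_atlas <- function(cohort, variance_threshold = 0.95) {
  stopifnot(variance_threshold > 0, variance_threshold <= 1)
  X <- as_curve_matrix(cohort)
  n <- nrow(X); G <- ncol(X)
  if (n < 2) stop("at least 2 curves required")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / (n - 1)
  ee <- eigen(C, symmetric = TRUE)
  ev <- pmax(ee$values, 0)
  total <- sum(ev)
  if (total <= 1e-12 * G) {
    atlas <- list(mean_curve = mu, modes = matrix(0, G, 0),
                  eigenvalues = rep(0, length(ev)),
                  variance_fractions = rep(0, length(ev)),
                  cumulative_variance = rep(0, length(ev)),
                  n_modes = 0L, G = G, n_subjects = n,
                  variance_threshold = variance_threshold)
    class(atlas) <- "transient_atlas"
    return(atlas)
  }
  vf <- ev / total
  cv <- cumsum(vf)
  m <- which(cv >= variance_threshold - 1e-12)[1]
  modes <- ee$vectors[, seq_len(m), drop = FALSE]
  for (k in seq_len(m)) {  # deterministic sign: largest |loading| positive
    j <- which.max(abs(modes[, k]))
    if (modes[j, k] < 0) modes[, k] <- -modes[, k]
  }
  atlas <- list(mean_curve = mu, modes = modes, eigenvalues = ev,
                variance_fractions = vf, cumulative_variance = cv,
                n_modes = as.integer(m), G = G, n_subjects = n,
                variance_threshold = variance_threshold)
  class(atlas) <- "transient_atlas"
  atlas
}

#' @export
print.transient_atlas <- function(x, ...) {
  cat(sprintf(
    "Transient atlas: %d subjects, grid G = %d, %d mode(s) for %.0f%% variance\n",
    x$n_subjects, x$G, x$n_modes, 100 * x$variance_threshold))
  if (x$n_modes > 0) {
    cat("  variance fractions:",
        paste(sprintf("%.3f", x$variance_fractions[seq_len(x$n_modes)]),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Project a normalized transient onto the atlas modes
#'
#' The mode weights (the per-patient transient biomarkers) are the inner
#' products of the mean-centered curve with each retained mode.
#'
#' @param atlas a [fit_atlas()] result.
#' @param nt a [normalize_transient()] curve on the atlas grid, or an
#'   `n x G` matrix of curves.
#' @return numeric vector of weights (or `n x m` matrix), named
#'   `vt_ai_1 ... vt_ai_m`.
#' @export
project_transient <- function(atlas, nt) {
  stopifnot(inherits(atlas, "transient_atlas"))
  X <- if (is.matrix(nt)) nt else matrix(as.numeric(nt), nrow = 1)
  if (ncol(X) != atlas$G) stop("grid mismatch: curve length != atlas G")
  W <- sweep(X, 2, atlas$mean_curve) %*% atlas$modes
  colnames(W) <- sprintf("vt_ai_%d", seq_len(atlas$n_modes))
  if (nrow(W) == 1 && !is.matrix(nt)) drop(W) else W
}

#' Reconstruct a curve from atlas mode weights
#'
#' Returns `mean_curve + sum_k w_k * mode_k`. Values may leave `[0, 1]` for
#' extreme weights; they are flagged (attribute `out_of_range`), not clipped.
#'
#' @param atlas a [fit_atlas()] result.
#' @param w weight vector (length <= number of retained modes).
#' @return numeric length-`G` curve.
#' @export
reconstruct_transient <- function(atlas, w) {
  stopifnot(inherits(atlas, "transient_atlas"),
            length(w) <= atlas$n_modes)
  out <- atlas$mean_curve
  if (length(w)) {
    out <- out + drop(atlas$modes[, seq_along(w), drop = FALSE] %*% w)
  }
  attr(out, "out_of_range") <- any(out < 0 | out > 1)
  out
}

#' Percentile traces of one atlas mode
#'
#' Visualization curves for a mode's effect: the mean curve displaced along
#' the mode by the `lo_pct` and `hi_pct` percentiles of the cohort's weights
#' for that mode (defaults 10 and 90).
#'
#' @param atlas a [fit_atlas()] result.
#' @param cohort_weights numeric vector (weights of `mode_index` across the
#'   cohort) or the full weight matrix from [project_transient()].
#' @param mode_index which mode.
#' @param lo_pct,hi_pct percentiles in (0, 100).
#' @return list with curves `lo`, `hi` and the two quantiles.
#' @export
mode_extreme_traces <- function(atlas, cohort_weights, mode_index,
                                lo_pct = 10, hi_pct = 90) {
  stopifnot(inherits(atlas, "transient_atlas"),
            mode_index >= 1, mode_index <= atlas$n_modes)
  w <- if (is.matrix(cohort_weights)) cohort_weights[, mode_index]
       else as.numeric(cohort_weights)
  if (!length(w)) stop("empty cohort weights")
  q <- stats::quantile(w, c(lo_pct, hi_pct) / 100, names = FALSE)
  mode <- atlas$modes[, mode_index]
  list(lo = atlas$mean_curve + q[1] * mode,
       hi = atlas$mean_curve + q[2] * mode,
       q_lo = q[1], q_hi = q[2])
}

#' Serialize an atlas to JSON
#'
#' Stores everything needed for independent reuse: mean curve, modes,
#' eigenvalues, variance fractions and metadata.
#'
#' @param atlas a [fit_atlas()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_atlas_json <- function(atlas, path) {
  stopifnot(inherits(atlas, "transient_atlas"))
  obj <- unclass(atlas)
  obj$modes <- apply(atlas$modes, 2, identity, simplify = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an atlas written by [write_atlas_json()]
#'
#' @param path JSON path.
#' @return a `transient_atlas`.
#' @export
read_atlas_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  modes <- if (is.matrix(obj$modes)) {
    t(obj$modes)  # jsonlite simplifies the column list to a row matrix
  } else if (length(obj$modes)) {
    do.call(cbind, lapply(obj$modes, as.numeric))
  } else {
    matrix(0, length(obj$mean_curve), 0)
  }
  atlas <- list(mean_curve = as.numeric(obj$mean_curve), modes = modes,
                eigenvalues = as.numeric(obj$eigenvalues),
                variance_fractions = as.numeric(obj$variance_fractions),
                cumulative_variance = as.numeric(obj$cumulative_variance),
                n_modes = as.integer(obj$n_modes), G = as.integer(obj$G),
                n_subjects = as.integer(obj$n_subjects),
                variance_threshold = obj$variance_threshold)
  class(atlas) <- "transient_atlas"
  atlas
}
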