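# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw from a lognormal distribution parameterized by median and quartiles
#'
#' Convenience for cohort specifications given as `median (q25--q75)`:
#' `meanlog = log(median)` and `sdlog = log(q75/q25) / (2 * qnorm(0.75))`.
#'
#' @param n number of draws.
#' @param median,q25,q75 target median and quartiles (all > 0).
#' @return numeric vector of length `n`.
#' @keywords internal
rlnorm_mq <- function(n, median, q25, q75) {
  stopifnot(median > 0, q25 > 0, q75 > q25)
  sdlog <- log(q75 / q25) / (2 * stats::qnorm(0.75))
  stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)
}

#' Draw from a truncated normal parameterized by median and quartiles
#'
#' Mean = median, sd from the IQR of a normal; draws outside `[lo, hi]`
#' are redrawn (rejection), so the realized quantiles are mildly shrunk
#' when the bounds are active.
#'
#' @inheritParams rlnorm_mq
#' @param lo,hi truncation bounds.
#' @keywords internal
rtnorm_mq <- function(n, median, q25, q75, lo = -Inf, hi = Inf) {
  stopifnot(q75 > q25, lo < hi)
  sd <- (q75 - q25) / (2 * stats::qnorm(0.75))
  out <- stats::rnorm(n, median, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), median, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

# Parabolic (3-point) refinement of a discrete extremum: returns the abscissa
# of the vertex of the parabola through (x[i-1..i+1], y[i-1..i+1]). Falls back
# to x[i] at the boundary or for a degenerate (flat) triple.
refine_extremum <- function(x, y, i) {
  n <- length(x)
  if (i <= 1L || i >= n) return(x[i])
  d1 <- y[i] - y[i - 1L]
  d2 <- y[i] - y[i + 1L]
  denom <- d1 + d2
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps * max(abs(y[i]), 1)) {
    return(x[i])
  }
  h <- x[i + 1L] - x[i]
  x[i] + h * (d1 - d2) / (2 * denom)
}

# Least-squares parabola through the points within +/- `half` indices of a
# discrete extremum; returns the vertex abscissa. More robust to dense-grid
# wiggles than a 3-point parabola. Falls back to x[i] near the boundary or
# for a flat fit.
refine_extremum_ls <- function(x, y, i, half = 5L) {
  n <- length(x)
  lo <- max(1L, i - half)
  hi <- min(n, i + half)
  if (hi - lo < 4L) return(refine_extremum(x, y, i))
  xx <- x[lo:hi] - x[i]
  fit <- stats::lm.fit(cbind(1, xx, xx^2), y[lo:hi])
  a <- fit$coefficients[3]
  b <- fit$coefficients[2]
  if (!is.finite(a) || abs(a) < .Machine$double.eps) return(x[i])
  vertex <- x[i] - b / (2 * a)
  if (vertex < x[lo] || vertex > x[hi]) return(x[i])
  unname(vertex)
}

# Savitzky-Golay smoothing with periodic padding (the transient is one cycle).
smooth_periodic <- function(y, p, n) {
  if (n >= length(y)) return(y)
  pad <- (n - 1L) %/% 2L + 1L
  yy <- c(utils::tail(y, pad), y, utils::head(y, pad))
  out <- signal::sgolayfilt(yy, p = p, n = n)
  out[(pad + 1L):(pad + length(y))]
}

# Longest run of TRUE in a logical vector; returns c(start, end) indices or NULL.
longest_run <- function(flag) {
  if (!any(flag)) return(NULL)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  best <- keep[which.max(r$lengths[keep])]
  c(starts[best], ends[best])
}

is_binary01 <- function(x) all(x %in% c(0, 1) | x %in% c(FALSE, TRUE))
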