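test_that("min-max normalization hits [0, 1] and is affine invariant", {
  p <- canonical_params()
  tr <- generate_transient(p, 28)
  nt <- normalize_transient(tr, G = 100)
  expect_length(nt, 100)
  expect_equal(min(nt), 0)
  expect_equal(max(nt), 1)

  scaled <- volume_transient(tr$trigger_times_ms, 2.5 * tr$volumes_ml + 30,
                             rr_ms = tr$rr_ms)
  expect_equal(as.numeric(normalize_transient(scaled, 100)), as.numeric(nt),
               tolerance = 1e-12)

  const <- volume_transient(seq(0, 780, by = 60), rep(90, 14), rr_ms = 840)
  expect_error(normalize_transient(const), "degenerate")
})

test_that("transients differing only in ventricle size and stroke volume normalize identically", {
  base <- canonical_params(edv_ml = 120, ef_pct = 45)
  big <- canonical_params(edv_ml = 210, ef_pct = 45)
  n1 <- normalize_transient(generate_transient(base, 28), 100)
  n2 <- normalize_transient(generate_transient(big, 28), 100)
  expect_lt(max(abs(n1 - n2)), 1e-6)
})

planted_mode_cohort <- function(n = 500, sds = c(0.5, 0.3, 0.15),
                                noise_sd = 0.01, G = 100, seed = 101) {
  set.seed(seed)
  u <- seq(0, 1, length.out = G + 1)[seq_len(G)]
  raw <- cbind(sin(2 * pi * u), cos(2 * pi * u), sin(4 * pi * u))
  modes <- qr.Q(qr(raw))                  # orthonormal planted modes
  for (k in 1:3) if (modes[which.max(abs(modes[, k])), k] < 0) {
    modes[, k] <- -modes[, k]
  }
  mean_curve <- (1 + cos(2 * pi * u)) / 2
  W <- sapply(sds, function(s) rnorm(n, 0, s))
  X <- matrix(mean_curve, n, G, byrow = TRUE) + W %*% t(modes) +
    matrix(rnorm(n * G, 0, noise_sd), n, G)
  list(X = X, modes = modes, W = W, mean_curve = mean_curve)
}

test_that("PCA atlas recovers a planted 3-mode subspace and its weight variances", {
  pc <- planted_mode_cohort()
  atlas <- fit_atlas(pc$X, variance_threshold = 0.95)
  expect_gte(atlas$n_modes, 3)

  # principal angles between planted and recovered 3-dim subspaces
  sv <- svd(t(pc$modes) %*% atlas$modes[, 1:3])$d
  angles <- acos(pmin(sv, 1)) * 180 / pi
  expect_lt(max(angles), 5)

  # eigenvalues against the sample covariance of the planted weights
  planted_ev <- sort(eigen(stats::cov(pc$W), symmetric = TRUE)$values,
                     decreasing = TRUE)
  expect_equal(atlas$eigenvalues[1:3], planted_ev, tolerance = 0.1)
})

test_that("an identical-curve cohort yields a zero-mode atlas reconstructing the mean", {
  X <- matrix(rep(seq(0, 1, length.out = 50), each = 20), nrow = 20)
  atlas <- fit_atlas(X)
  expect_equal(atlas$n_modes, 0L)
  expect_equal(reconstruct_transient(atlas, numeric(0)),
               seq(0, 1, length.out = 50), ignore_attr = TRUE)
})

test_that("the retained-mode count is the smallest reaching the variance threshold", {
  set.seed(7)
  pc <- planted_mode_cohort(n = 2000, sds = c(sqrt(0.6), sqrt(0.3), sqrt(0.1)),
                            noise_sd = 0)
  cv <- fit_atlas(pc$X, variance_threshold = 0.95)$cumulative_variance
  for (thr in c(0.5, 0.85, 0.95, 0.999)) {
    atlas <- fit_atlas(pc$X, variance_threshold = thr)
    expect_equal(atlas$n_modes, which(cv >= thr - 1e-12)[1])
  }
  expect_equal(fit_atlas(pc$X, variance_threshold = 0.85)$n_modes, 2L)
})

test_that("projection and reconstruction are exact inverses on the mode span", {
  pc <- planted_mode_cohort(n = 200, noise_sd = 0.005, seed = 11)
  atlas <- fit_atlas(pc$X, variance_threshold = 0.999)
  # project the mean: zero weights
  expect_lt(max(abs(project_transient(atlas, atlas$mean_curve))), 1e-10)
  # round trip w -> curve -> w is the identity (orthonormality)
  set.seed(12)
  w <- rnorm(atlas$n_modes, 0, 0.3)
  x <- reconstruct_transient(atlas, w)
  expect_equal(as.numeric(project_transient(atlas, as.numeric(x))), w,
               tolerance = 1e-8)
  # orthonormality of modes
  gram <- t(atlas$modes) %*% atlas$modes
  expect_lt(max(abs(gram - diag(atlas$n_modes))), 1e-8)
  # training-cohort weights average to ~0
  W <- project_transient(atlas, pc$X)
  expect_lt(max(abs(colMeans(W))), 1e-10)
})

test_that("reconstruction error is non-increasing in the number of modes", {
  pc <- planted_mode_cohort(n = 150, noise_sd = 0.02, seed = 21)
  atlas <- fit_atlas(pc$X, variance_threshold = 0.999)
  x <- pc$X[5, ]
  errs <- vapply(0:atlas$n_modes, function(m) {
    w <- if (m == 0) numeric(0) else
      as.numeric(project_transient(atlas, x))[seq_len(m)]
    sqrt(sum((x - reconstruct_transient(atlas, w))^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("atlas fitting is deterministic with the documented sign convention", {
  pc <- planted_mode_cohort(n = 100, seed = 31)
  a1 <- fit_atlas(pc$X)
  a2 <- fit_atlas(pc$X)
  expect_identical(a1, a2)
  for (k in seq_len(a1$n_modes)) {
    expect_gt(a1$modes[which.max(abs(a1$modes[, k])), k], 0)
  }
})

test_that("mode extreme traces realize the 10th/90th percentile displacements", {
  pc <- planted_mode_cohort(n = 400, seed = 41)
  atlas <- fit_atlas(pc$X)
  W <- project_transient(atlas, pc$X)
  tr <- mode_extreme_traces(atlas, W, mode_index = 1)
  q <- stats::quantile(W[, 1], c(0.1, 0.9), names = FALSE)
  expect_equal(tr$lo, atlas$mean_curve + q[1] * atlas$modes[, 1])
  expect_equal(tr$hi, atlas$mean_curve + q[2] * atlas$modes[, 1])
  # symmetric weights give traces symmetric about the mean curve
  Wsym <- c(-2, -1, 0, 1, 2)
  tr2 <- mode_extreme_traces(atlas, Wsym, 1, lo_pct = 10, hi_pct = 90)
  expect_equal(tr2$lo + tr2$hi, 2 * atlas$mean_curve)
  expect_error(mode_extreme_traces(atlas, numeric(0), 1), "empty")
})

test_that("atlas serialization round-trips through JSON", {
  pc <- planted_mode_cohort(n = 80, seed = 51)
  atlas <- fit_atlas(pc$X)
  path <- file.path(tempdir(), "atlas.json")
  write_atlas_json(atlas, path)
  back <- read_atlas_json(path)
  expect_equal(back$mean_curve, atlas$mean_curve)
  expect_equal(back$modes, atlas$modes, ignore_attr = TRUE)
  expect_equal(back$eigenvalues, atlas$eigenvalues)
  expect_equal(back$n_modes, atlas$n_modes)
  w1 <- project_transient(atlas, pc$X[1, ])
  w2 <- project_transient(back, pc$X[1, ])
  expect_equal(as.numeric(w1), as.numeric(w2))
  unlink(path)
})

test_that("grid mismatches are rejected", {
  pc <- planted_mode_cohort(n = 50, seed = 61)
  atlas <- fit_atlas(pc$X)
  expect_error(project_transient(atlas, rep(0.5, 42)), "grid mismatch")
})
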