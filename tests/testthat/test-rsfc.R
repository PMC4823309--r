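toy_vol <- function(nt = 20, d = c(4, 4, 3), vox = 2.5, seed = 1, tr = 2.52) {
  set.seed(seed)
  volume_series(array(stats::rnorm(prod(d) * nt), c(d, nt)),
                affine = diag(c(rep(vox, 3), 1)), tr_s = tr)
}

test_that("initial volumes are discarded as specified", {
  v <- toy_vol(nt = 240)
  expect_equal(dim(discard_initial(v, 5)$data)[4], 235)
  expect_identical(discard_initial(v, 0), v)
  v5 <- toy_vol(nt = 5)
  expect_error(discard_initial(v5, 5), "cannot discard")
})

test_that("quadratic detrending projects out polynomial trends", {
  nt <- 235
  t <- seq_len(nt)
  x <- 3 + 0.5 * t - 0.01 * t^2
  expect_lt(max(abs(detrend_quadratic(x))), 1e-8 * max(abs(x)))
  set.seed(2)
  w <- stats::rnorm(nt)
  r <- detrend_quadratic(w)
  expect_lt(abs(sum(r)), 1e-8)
  expect_lt(abs(sum(r * t) / sum(t^2)), 1e-8)
  expect_lt(abs(sum(r * t^2) / sum(t^4)), 1e-8)
  # a slow in-band sinusoid survives nearly intact (RMS amplitude)
  s <- sin(2 * pi * 0.05 * (t - 1) * 2.52)
  ds <- detrend_quadratic(s)
  expect_lt(abs(sqrt(2 * mean(ds^2)) / sqrt(2 * mean(s^2)) - 1), 0.02)
  expect_error(detrend_quadratic(c(1, 2)), "at least 3")
})

test_that("BOLD band-pass keeps the band and rejects outside it", {
  nt <- 235; tr <- 2.52
  t <- (seq_len(nt) - 1) * tr
  trim <- seq(nt %/% 4, 3 * nt %/% 4)
  inband <- bandpass_bold(sin(2 * pi * 0.04 * t), tr)
  expect_gt(max(abs(inband[trim])), 0.9)
  outband <- bandpass_bold(sin(2 * pi * 0.3 * t) , tr)
  expect_lt(max(abs(outband[trim])), 0.1)
  expect_equal(bandpass_bold(numeric(nt), tr), numeric(nt))
  expect_error(bandpass_bold(sin(t), tr_s = 10, high_hz = 0.08), "Nyquist")
})

test_that("confound regression leaves residuals orthogonal to confounds", {
  nt <- 100
  set.seed(5)
  conf <- cbind(a = stats::rnorm(nt), b = stats::rnorm(nt))
  # a voxel equal to a confound column vanishes
  r <- regress_confounds(conf[, 1], conf)
  expect_lt(max(abs(r)), 1e-10)
  # intercept only = mean centering
  x <- stats::rnorm(nt) + 7
  expect_equal(regress_confounds(x, matrix(0, nt, 0)), x - mean(x))
  # planted mixture: residual keeps the independent part, drops the confound
  sig <- stats::rnorm(nt)
  vox <- 0.6 * conf[, 1] + sig
  res <- regress_confounds(vox, conf)
  expect_gt(stats::cor(res, sig), 0.99)
  expect_lt(abs(sum(res * conf[, 1])), 1e-8)
  expect_lt(abs(sum(res * conf[, 2])), 1e-8)
  expect_error(regress_confounds(x, cbind(c1 = conf[, 1], c2 = conf[, 1])),
               "rank deficient")
})

test_that("global signal is the per-volume mask mean", {
  v <- toy_vol(nt = 10, d = c(4, 4, 2))
  m <- array(TRUE, c(4, 4, 2))
  u <- stats::rnorm(10)
  v$data <- array(rep(u, each = 32), c(4, 4, 2, 10))
  expect_equal(global_signal(v, m), u)
  m1 <- array(FALSE, c(4, 4, 2)); m1[2, 3, 1] <- TRUE
  expect_equal(global_signal(v, m1), v$data[2, 3, 1, ])
  # +a/-a checkerboard cancels over an even-count mask
  chk <- array(rep(c(1, -1), 16), c(4, 4, 2))
  v$data <- array(outer(as.numeric(chk), u), c(4, 4, 2, 10))
  expect_equal(global_signal(v, m), rep(0, 10))
  expect_error(global_signal(v, array(FALSE, c(4, 4, 2))), "empty mask")
})

test_that("Gaussian smoothing has the requested FWHM and preserves mass", {
  d <- c(21, 21, 15)
  v <- volume_series(array(0, c(d, 3)), affine = diag(c(2.5, 2.5, 2.5, 1)))
  v$data[11, 11, 8, ] <- 1
  s <- smooth_gaussian(v, fwhm_mm = 6)
  prof <- s$data[, 11, 8, 1]
  half <- max(prof) / 2
  above <- which(prof >= half)
  # linear interpolation at the half-maximum crossings, in mm
  lo <- above[1]; hi <- above[length(above)]
  f1 <- lo - 1 + (half - prof[lo - 1]) / (prof[lo] - prof[lo - 1])
  f2 <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1])
  fwhm_mm <- (f2 - f1) * 2.5
  expect_lt(abs(fwhm_mm - 6) / 6, 0.05)
  expect_equal(sum(s$data[, , , 1]), 1, tolerance = 1e-6)
  # constant image unchanged away from the zero-padded border
  v$data <- array(5, c(d, 3))
  sc <- smooth_gaussian(v, 6)
  expect_equal(sc$data[8:14, 8:14, 6:10, 2], array(5, c(7, 7, 5)),
               tolerance = 1e-9)
})

test_that("seed sphere membership matches exhaustive enumeration", {
  v <- toy_vol(nt = 4, d = c(9, 9, 9), vox = 2.5)
  ts <- extract_seed(v, seed_spec(c(10, 10, 10), 5))  # on the (4,4,4) voxel center
  # oracle: integer offsets with i^2+j^2+k^2 <= (5/2.5)^2
  g <- expand.grid(i = -2:2, j = -2:2, k = -2:2)
  n_oracle <- sum(g$i^2 + g$j^2 + g$k^2 <= 4)
  expect_equal(attr(ts, "n_voxels"), n_oracle)
  expect_equal(n_oracle, 33)
  expect_equal(attr(extract_seed(v, seed_spec(c(10, 10, 10), 1.0)), "n_voxels"), 1)
  expect_error(extract_seed(v, seed_spec(c(500, 500, 500), 5)), "no voxel")
  # translation invariance: shift grid and seed by the same world vector
  v2 <- v; v2$affine[1:3, 4] <- v2$affine[1:3, 4] + c(7, -3, 2)
  ts2 <- extract_seed(v2, seed_spec(c(10, 10, 10) + c(7, -3, 2), 5))
  expect_equal(attr(ts2, "n_voxels"), 33)
  expect_equal(as.numeric(ts2), as.numeric(ts))
})

test_that("seed maps are Fisher-z with clipping and zero-variance masking", {
  d <- c(4, 4, 2); nt <- 235
  set.seed(8)
  v <- toy_vol(nt = nt, d = d)
  seed_ts <- stats::rnorm(nt)
  v$data[1, 1, 1, ] <- seed_ts
  v$data[2, 1, 1, ] <- -seed_ts
  v$data[3, 1, 1, ] <- 0                                  # zero variance
  v$data[4, 1, 1, ] <- 0.5 * scale(seed_ts)[, 1] + sqrt(0.75) * stats::rnorm(nt)
  m <- seed_map(v, seed_ts)
  expect_gt(m$z[1, 1, 1], 13)
  expect_equal(m$z[2, 1, 1], -m$z[1, 1, 1])
  expect_gte(m$n_clipped, 2)
  expect_equal(m$z[3, 1, 1], 0)
  expect_false(m$mask[3, 1, 1])
  expect_lt(abs(m$z[4, 1, 1] - atanh(0.5)), 0.15)
  expect_error(seed_map(v, seed_ts[-1]), "length")
})

test_that("volume series round-trips through NIfTI-1", {
  v <- toy_vol(nt = 6, d = c(5, 4, 3), vox = 2.5, tr = 2.52)
  v$affine[1:3, 4] <- c(-10, -8, -6)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume_series(v, f)
  r <- read_volume_series(f)
  expect_equal(r$data, v$data, tolerance = 1e-6)
  expect_equal(r$affine, v$affine, tolerance = 1e-5)
  expect_equal(r$tr_s, 2.52, tolerance = 1e-6)
})

test_that("the frozen temporal chain is bit-reproducible", {
  ph <- phantom_spec(shape = c(6, 6, 4), n_volumes = 40, coupling_r = 0.4, seed = 3)
  run <- function() {
    v <- gen_session_volume(ph)
    v <- discard_initial(v, 5)
    v <- detrend_quadratic(v)
    v <- bandpass_bold(v)
    seed_map(v, extract_seed(v, phantom_seed_spec(ph)))$z
  }
  expect_identical(run(), run())
})

test_that("3D statistic maps round-trip through NIfTI-1", {
  z <- array(stats::rnorm(5 * 4 * 3), c(5, 4, 3))
  aff <- diag(c(2.5, 2.5, 2.5, 1)); aff[1:3, 4] <- c(-4, 2, 0)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_map_nifti(z, aff, f)
  back <- read_map_nifti(f)
  expect_equal(back$z, z, tolerance = 1e-6)
  expect_equal(back$affine, aff, tolerance = 1e-5)
})
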