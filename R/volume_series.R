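#' 4D BOLD volume series
#'
#' Carrier for a resting-state acquisition: a 4D array (x, y, z, t), the
#' voxel-to-world affine (RAS mm, 0-based voxel indices) and the repetition
#' time.
#'
#' @param data 4D numeric array.
#' @param affine 4x4 invertible voxel-to-world transform (mm).
#' @param tr_s Repetition time (s).
#' @return An object of class \code{volume_series}.
#' @export
volume_series <- function(data, affine = diag(4), tr_s = 2.52) {
  if (length(dim(data)) != 4L) stop("data must be a 4D array", call. = FALSE)
  if (dim(data)[4] < 3L) stop("need at least 3 volumes", call. = FALSE)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12) {
    stop("affine must be an invertible 4x4 matrix", call. = FALSE)
  }
  if (!(tr_s > 0)) stop("tr_s must be > 0", call. = FALSE)
  structure(list(data = data, affine = affine, tr_s = tr_s),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_series> %dx%dx%d voxels x %d volumes, TR %.3g s\n",
              d[1], d[2], d[3], d[4], x$tr_s))
  invisible(x)
}

#' Read / write a volume series as NIfTI-1
#'
#' @param vol A \code{volume_series}.
#' @param path Path to a \code{.nii} / \code{.nii.gz} file.
#' @return \code{write_volume_series} returns \code{path} invisibly;
#'   \code{read_volume_series} returns a \code{volume_series}.
#' @export
write_volume_series <- function(vol, path) {
  stopifnot(inherits(vol, "volume_series"))
  vox <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- c(vox, vol$tr_s)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_series
#' @export
read_volume_series <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  tr <- RNifti::pixdim(img)[4]
  volume_series(array(as.numeric(img), dim = dim(img)), affine = aff,
                tr_s = if (is.finite(tr) && tr > 0) tr else 2.52)
}

# (t x v) matrix view of the voxel time courses and its inverse
vol_as_matrix <- function(vol) {
  d <- dim(vol$data)
  t(matrix(vol$data, nrow = prod(d[1:3]), ncol = d[4]))
}

matrix_as_vol <- function(m, vol) {
  d <- dim(vol$data)
  vol$data <- array(t(m), dim = d)
  vol
}

# dispatch helper: apply a (t x v)-matrix transform to a vector, matrix
# (time in rows) or volume_series, returning the same shape
apply_timewise <- function(x, fun) {
  if (inherits(x, "volume_series")) {
    matrix_as_vol(fun(vol_as_matrix(x)), x)
  } else if (is.matrix(x)) {
    fun(x)
  } else {
    as.numeric(fun(matrix(as.numeric(x), ncol = 1L)))
  }
}

#' Discard initial volumes of a series
#'
#' Drops the first \code{n} volumes (steady-state magnetization convention:
#' 240 acquired, first 5 discarded, 235 analyzed).
#'
#' @param vol A \code{volume_series}.
#' @param n Number of initial volumes to drop (default 5).
#' @return The shortened \code{volume_series}.
#' @export
discard_initial <- function(vol, n = 5L) {
  stopifnot(inherits(vol, "volume_series"))
  nt <- dim(vol$data)[4]
  if (nt <= n) stop(sprintf("cannot discard %d of %d volumes", n, nt), call. = FALSE)
  if (n == 0L) return(vol)
  vol$data <- vol$data[, , , -(seq_len(n)), drop = FALSE]
  vol
}

#' Remove constant, linear and quadratic trends
#'
#' Least-squares projection of each time course onto the orthogonal
#' complement of \{1, t, t^2\}; residuals have zero mean.
#'
#' @param x Numeric time course, matrix (time in rows) or
#'   \code{volume_series}.
#' @return Same shape as the input.
#' @export
detrend_quadratic <- function(x) {
  apply_timewise(x, function(m) {
    nt <- nrow(m)
    if (nt < 3L) stop("detrending needs at least 3 time points", call. = FALSE)
    X <- cbind(1, stats::poly(seq_len(nt), degree = 2))
    m - X %*% qr.solve(X, m)
  })
}

#' Temporal band-pass filter for BOLD time courses
#'
#' Zero-phase FFT projection: Fourier coefficients with frequency inside
#' \code{[low_hz, high_hz]} are kept, all others (including DC) are zeroed.
#' Gain is exactly 1 at in-band bin frequencies and 0 out of band, with no
#' phase distortion - the convention of resting-state band-pass tools.
#'
#' @param x Numeric time course, matrix (time in rows) or \code{volume_series}.
#' @param tr_s Sampling interval (s); taken from the volume when \code{x} is
#'   a \code{volume_series}.
#' @param low_hz,high_hz Band edges (Hz), default 0.01-0.08;
#'   \code{high_hz} must be below the Nyquist frequency \code{1/(2 tr_s)}.
#' @return Same shape as the input.
#' @export
bandpass_bold <- function(x, tr_s = NULL, low_hz = 0.01, high_hz = 0.08) {
  if (inherits(x, "volume_series")) tr_s <- x$tr_s
  if (is.null(tr_s)) stop("tr_s required for non-volume input", call. = FALSE)
  if (!(low_hz >= 0 && low_hz < high_hz)) stop("need 0 <= low_hz < high_hz", call. = FALSE)
  if (high_hz >= 1 / (2 * tr_s)) {
    stop(sprintf("high_hz = %g is not below the Nyquist frequency %g Hz",
                 high_hz, 1 / (2 * tr_s)), call. = FALSE)
  }
  apply_timewise(x, function(m) {
    nt <- nrow(m)
    freq <- seq(0, nt - 1) / (nt * tr_s)
    freq <- pmin(freq, 1 / tr_s - freq)          # fold to [0, Nyquist]
    keep <- freq >= low_hz & freq <= high_hz
    fm <- stats::mvfft(m)
    fm[!keep, ] <- 0
    Re(stats::mvfft(fm, inverse = TRUE)) / nt
  })
}

#' Regress confound time courses out of a volume
#'
#' Voxelwise least squares against an intercept plus the supplied confound
#' columns (head motion, global signal, CSF/white matter, ...); returns the
#' residuals, which are orthogonal to every confound column.
#'
#' @param x Numeric time course, matrix (time in rows) or \code{volume_series}.
#' @param confounds Numeric matrix or data frame with one row per time point.
#' @return Same shape as the input.
#' @export
regress_confounds <- function(x, confounds) {
  C <- as.matrix(confounds)
  apply_timewise(x, function(m) {
    if (nrow(C) != nrow(m)) {
      stop(sprintf("confounds have %d rows but the series has %d time points",
                   nrow(C), nrow(m)), call. = FALSE)
    }
    X <- cbind(intercept = 1, C)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      stop("confound design is rank deficient; collinear columns: ",
           paste(dropped, collapse = ", "), call. = FALSE)
    }
    m - X %*% qr.coef(qrX, m)
  })
}

#' Mean signal over a mask, per volume
#'
#' @param vol A \code{volume_series}.
#' @param mask 3D logical array matching the spatial grid.
#' @return Numeric time course of per-volume means over mask voxels.
#' @export
global_signal <- function(vol, mask) {
  stopifnot(inherits(vol, "volume_series"))
  d <- dim(vol$data)
  if (!all(dim(mask) == d[1:3])) stop("mask does not match the spatial grid", call. = FALSE)
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty mask", call. = FALSE)
  m <- matrix(vol$data, nrow = prod(d[1:3]))
  colMeans(m[idx, , drop = FALSE])
}

# banded 1D Gaussian smoothing matrix (zero padding: interior mass preserved)
gauss_band <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  S <- matrix(0, n, n)
  for (off in -r:r) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1L & j <= n
    S[cbind(i[ok], j[ok])] <- k[off + r + 1L]
  }
  S
}

#' Spatial Gaussian smoothing of a volume series
#'
#' Separable per-axis Gaussian with \code{sigma_vox = fwhm_mm / (2.3548 *
#' voxel_mm)} derived per axis from the affine (anisotropic voxels get
#' per-axis sigmas). Zero-padded convolution with a normalized kernel, so
#' total intensity is preserved for interior support.
#'
#' @param vol A \code{volume_series}.
#' @param fwhm_mm Full width at half maximum of the kernel (mm); 6 mm is the
#'   whole-brain convention, 4 mm the brainstem/cerebellum one.
#' @return Smoothed \code{volume_series}.
#' @export
smooth_gaussian <- function(vol, fwhm_mm = 6.0) {
  stopifnot(inherits(vol, "volume_series"))
  vox <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / vox
  d <- dim(vol$data)
  a <- vol$data
  # axis 1
  S <- gauss_band(d[1], sig[1])
  a <- array(S %*% matrix(a, nrow = d[1]), dim = d)
  # axis 2
  S <- gauss_band(d[2], sig[2])
  ap <- aperm(a, c(2, 1, 3, 4))
  ap <- array(S %*% matrix(ap, nrow = d[2]), dim = d[c(2, 1, 3, 4)])
  a <- aperm(ap, c(2, 1, 3, 4))
  # axis 3
  S <- gauss_band(d[3], sig[3])
  ap <- aperm(a, c(3, 1, 2, 4))
  ap <- array(S %*% matrix(ap, nrow = d[3]), dim = d[c(3, 1, 2, 4)])
  vol$data <- aperm(ap, c(2, 3, 1, 4))
  vol
}
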