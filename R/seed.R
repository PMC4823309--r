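#' Spherical seed region in world coordinates
#'
#' @param center_mm Length-3 world (RAS mm) center.
#' @param radius_mm Sphere radius in mm (> 0).
#' @param name Optional label.
#' @return An object of class \code{seed_spec}.
#' @export
seed_spec <- function(center_mm, radius_mm = 5, name = NULL) {
  center_mm <- as.numeric(center_mm)
  if (length(center_mm) != 3L) stop("center_mm must have length 3", call. = FALSE)
  if (!(radius_mm > 0)) stop("radius_mm must be > 0", call. = FALSE)
  structure(list(center_mm = center_mm, radius_mm = radius_mm, name = name),
            class = "seed_spec")
}

#' Canonical anterior-hippocampus seeds
#'
#' 5-mm spheres at the anterior hippocampal coordinates used throughout the
#' package: right (28, -12, -20) and left (-28, -12, -20) in MNI mm.
#'
#' @param side "right" or "left".
#' @return A \code{seed_spec}.
#' @export
ahc_seed <- function(side = c("right", "left")) {
  side <- match.arg(side)
  if (side == "right") seed_spec(c(28, -12, -20), 5, "right_aHC")
  else seed_spec(c(-28, -12, -20), 5, "left_aHC")
}

# linear voxel indices (1-based) of voxels whose CENTERS lie within the
# sphere (inclusive <=), using 0-based voxel indices through the affine
seed_voxel_indices <- function(vol, seed) {
  d <- dim(vol$data)[1:3]
  A <- vol$affine
  ijk <- as.matrix(expand.grid(i = 0:(d[1] - 1L), j = 0:(d[2] - 1L),
                               k = 0:(d[3] - 1L)))
  world <- ijk %*% t(A[1:3, 1:3]) +
    matrix(A[1:3, 4], nrow(ijk), 3, byrow = TRUE)
  dist2 <- (world[, 1] - seed$center_mm[1])^2 +
    (world[, 2] - seed$center_mm[2])^2 +
    (world[, 3] - seed$center_mm[3])^2
  which(dist2 <= seed$radius_mm^2 + 1e-9)
}

#' Extract the mean seed time course from a volume series
#'
#' Sphere membership is decided by voxel centers (inclusive \code{<=} on the
#' radius) in world space through the affine.
#'
#' @param vol A \code{volume_series}.
#' @param seed A [seed_spec()].
#' @return Numeric time course (mean over member voxels) with attribute
#'   \code{n_voxels}.
#' @export
extract_seed <- function(vol, seed) {
  stopifnot(inherits(vol, "volume_series"), inherits(seed, "seed_spec"))
  idx <- seed_voxel_indices(vol, seed)
  if (length(idx) == 0L) {
    stop("seed sphere contains no voxel centers of the grid", call. = FALSE)
  }
  d <- dim(vol$data)
  m <- matrix(vol$data, nrow = prod(d[1:3]))
  structure(colMeans(m[idx, , drop = FALSE]), n_voxels = length(idx))
}

#' Voxelwise Fisher-z seed correlation map
#'
#' Pearson correlation of every voxel time course with the seed course,
#' Fisher z-transformed (\code{z = atanh(r)}). Correlations with
#' \code{|r| >= 1 - 1e-12} are clipped to the bound before \code{atanh} and
#' counted; zero-variance voxels get \code{z = 0} and are masked out rather
#' than propagating NaN.
#'
#' @param vol A preprocessed \code{volume_series}.
#' @param seed_ts Numeric seed time course of length equal to the number of
#'   volumes.
#' @param mask Optional 3D logical analysis mask (default: all voxels).
#' @return An object of class \code{connectivity_map}: list with 3D arrays
#'   \code{z} and logical \code{mask}, plus \code{n_clipped}.
#' @export
seed_map <- function(vol, seed_ts, mask = NULL) {
  stopifnot(inherits(vol, "volume_series"))
  d <- dim(vol$data)
  nt <- d[4]
  seed_ts <- as.numeric(seed_ts)
  if (length(seed_ts) != nt) {
    stop("seed_ts length must equal the number of volumes", call. = FALSE)
  }
  if (stats::sd(seed_ts) == 0) stop("seed time course has zero variance", call. = FALSE)
  m <- matrix(vol$data, nrow = prod(d[1:3]))       # v x t
  mu <- rowMeans(m)
  mc <- m - mu
  ssy <- rowSums(mc^2)
  s <- seed_ts - mean(seed_ts)
  r <- as.numeric(mc %*% s) / sqrt(ssy * sum(s^2))
  zero_var <- ssy == 0
  r[zero_var] <- 0
  clip <- 1 - 1e-12
  clipped <- abs(r) >= clip & !zero_var
  r[r >= clip] <- clip
  r[r <= -clip] <- -clip
  z <- atanh(r)
  z[zero_var] <- 0
  keep <- if (is.null(mask)) rep(TRUE, length(r)) else as.logical(mask)
  keep <- keep & !zero_var
  structure(list(z = array(z, dim = d[1:3]),
                 mask = array(keep, dim = d[1:3]),
                 n_clipped = sum(clipped)),
            class = "connectivity_map")
}

#' Write / read a 3D map (Fisher-z or statistic) as NIfTI-1
#'
#' @param z 3D numeric array (e.g. \code{map$z} of a
#'   \code{connectivity_map}, or a t map).
#' @param affine 4x4 voxel-to-world transform of the originating volume.
#' @param path Path to a \code{.nii} / \code{.nii.gz} file.
#' @return \code{write_map_nifti} returns \code{path} invisibly;
#'   \code{read_map_nifti} returns a list with \code{z} and \code{affine}.
#' @export
write_map_nifti <- function(z, affine, path) {
  stopifnot(length(dim(z)) == 3L)
  img <- RNifti::asNifti(z)
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- vox
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_map_nifti
#' @export
read_map_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  list(z = array(as.numeric(img), dim = dim(img)), affine = aff)
}
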