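#' Specification of a synthetic BOLD phantom
#'
#' A small 4D phantom with two disjoint cubic regions: a "seed" region
#' sharing a common latent time course, and a "target" region whose voxel
#' courses are built as \code{r * seed + sqrt(1 - r^2) * noise}, so the
#' seed-target Pearson correlation is \code{r} in expectation. All other
#' voxels are white noise. Optionally a spatial Gaussian pre-smoothing can be
#' applied, because cluster inference behaves differently on smooth fields.
#'
#' @param shape Integer length-3 voxel counts (default \code{c(20, 20, 12)}).
#' @param voxel_mm Isotropic voxel edge length (mm, default 2.5).
#' @param n_volumes Number of volumes (default 240; pipelines typically
#'   discard the first 5).
#' @param tr_s Repetition time (s, default 2.52).
#' @param seed_center_vox,target_center_vox 1-based voxel index triples: the
#'   low corner of each cubic region (defaults place the seed a quarter of
#'   the way into the grid and the target near the opposite corner).
#' @param region_side_vox Cube side in voxels (default 2, i.e. 8-voxel
#'   regions).
#' @param coupling_r Planted seed-target correlation, \code{|r| < 1}.
#' @param noise_sd Marginal SD of all voxel signals (signal units).
#' @param seed_voxel_noise_sd Independent per-voxel noise added to the seed
#'   region on top of the shared course (keeps seed voxels non-identical).
#' @param presmooth_fwhm_mm Optional spatial Gaussian FWHM applied to each
#'   generated volume (default NULL: no spatial autocorrelation).
#' @param seed Integer RNG seed.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(20L, 20L, 12L), voxel_mm = 2.5,
                         n_volumes = 240L, tr_s = 2.52,
                         seed_center_vox = pmax(2L, shape %/% 4L),
                         target_center_vox = shape - region_side_vox,
                         region_side_vox = 2L, coupling_r = 0.5,
                         noise_sd = 1, seed_voxel_noise_sd = 0.1,
                         presmooth_fwhm_mm = NULL, seed = 1L) {
  shape <- as.integer(shape)
  if (n_volumes < 3L) stop("n_volumes must be >= 3", call. = FALSE)
  if (abs(coupling_r) >= 1) stop("|coupling_r| must be < 1", call. = FALSE)
  spec <- structure(list(shape = shape, voxel_mm = voxel_mm,
                         n_volumes = as.integer(n_volumes), tr_s = tr_s,
                         seed_center_vox = as.integer(seed_center_vox),
                         target_center_vox = as.integer(target_center_vox),
                         region_side_vox = as.integer(region_side_vox),
                         coupling_r = coupling_r, noise_sd = noise_sd,
                         seed_voxel_noise_sd = seed_voxel_noise_sd,
                         presmooth_fwhm_mm = presmooth_fwhm_mm,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  if (length(intersect(phantom_region(spec, "seed"),
                       phantom_region(spec, "target")))) {
    stop("seed and target regions must be disjoint", call. = FALSE)
  }
  spec
}

#' Linear voxel indices of a phantom's planted regions
#'
#' Ground-truth lookup for recovery checks: the 1-based linear indices of the
#' seed or target cube on the phantom's spatial grid.
#'
#' @param phantom A [phantom_spec()].
#' @param which \code{"seed"} or \code{"target"}.
#' @return Integer vector of linear voxel indices.
#' @export
phantom_region <- function(phantom, which = c("seed", "target")) {
  which <- match.arg(which)
  c0 <- if (which == "seed") phantom$seed_center_vox else phantom$target_center_vox
  s <- phantom$region_side_vox
  d <- phantom$shape
  rng <- lapply(1:3, function(a) {
    r <- c0[a]:(c0[a] + s - 1L)
    if (any(r < 1L | r > d[a])) stop("region extends outside the grid", call. = FALSE)
    r
  })
  g <- expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]])
  g$i + (g$j - 1L) * d[1] + (g$k - 1L) * d[1] * d[2]
}

phantom_affine <- function(phantom) {
  diag(c(rep(phantom$voxel_mm, 3), 1))
}

#' Seed sphere matching a phantom's seed region
#'
#' A sphere centered on the world-space center of the seed cube with radius
#' 1.2 voxel edges, which captures exactly the cube's voxels for the default
#' 2-voxel side.
#'
#' @param phantom A [phantom_spec()].
#' @return A [seed_spec()].
#' @export
phantom_seed_spec <- function(phantom) {
  s <- phantom$region_side_vox
  ctr_vox0 <- (phantom$seed_center_vox - 1) + (s - 1) / 2   # 0-based center
  seed_spec(ctr_vox0 * phantom$voxel_mm, radius_mm = 1.2 * phantom$voxel_mm,
            name = "phantom_seed")
}

#' Generate one phantom session with a given seed-target correlation
#'
#' @param phantom A [phantom_spec()].
#' @param r Seed-target correlation for this session (defaults to the
#'   phantom's \code{coupling_r}).
#' @param seed Integer RNG seed for this session (defaults to the phantom's).
#' @return A \code{volume_series}.
#' @export
gen_session_volume <- function(phantom, r = phantom$coupling_r,
                               seed = phantom$seed) {
  stopifnot(inherits(phantom, "phantom_spec"))
  if (abs(r) >= 1) stop("|r| >= 1; use a smaller coupling shift", call. = FALSE)
  d <- phantom$shape
  nt <- phantom$n_volumes
  v <- prod(d)
  set.seed(as.integer(seed))
  u <- stats::rnorm(nt)                               # shared latent course
  m <- matrix(stats::rnorm(v * nt), nrow = v)         # v x t background
  seed_idx <- phantom_region(phantom, "seed")
  targ_idx <- phantom_region(phantom, "target")
  sv <- phantom$seed_voxel_noise_sd
  m[seed_idx, ] <- matrix(u, length(seed_idx), nt, byrow = TRUE) +
    sv * matrix(stats::rnorm(length(seed_idx) * nt), length(seed_idx))
  m[targ_idx, ] <- r * matrix(u, length(targ_idx), nt, byrow = TRUE) +
    sqrt(1 - r^2) * matrix(stats::rnorm(length(targ_idx) * nt), length(targ_idx))
  vol <- volume_series(array(phantom$noise_sd * m, dim = c(d, nt)),
                       affine = phantom_affine(phantom), tr_s = phantom$tr_s)
  if (!is.null(phantom$presmooth_fwhm_mm)) {
    vol <- smooth_gaussian(vol, phantom$presmooth_fwhm_mm)
  }
  vol
}

#' Specification of a synthetic 2x2 (Group x Time) cohort
#'
#' Ground truth for a cohort of exercise and control subjects, each scanned
#' at T0 and T1. Per subject-session, the seed-target coupling is set on the
#' Fisher-z scale as \code{atanh(coupling_r) + subject trait + session noise},
#' and exercise-group T1 sessions additionally receive the planted
#' \code{interaction_delta_z} shift plus subject-level heterogeneity;
#' the result is mapped back through \code{tanh}. In the exercise group the
#' per-subject coupling change is drawn jointly with the RMSSD change at
#' correlation \code{rho_fc_rmssd}.
#'
#' @param n_per_group Subjects per group (>= 2, default 17).
#' @param interaction_delta_z Planted Group x Time coupling change, Fisher-z
#'   units (negative = connectivity decrease after exercise).
#' @param rho_fc_rmssd Planted across-subject correlation between coupling
#'   change and RMSSD change in the exercise group (\code{|rho| <= 1}).
#' @param rmssd_change_mean_ms,rmssd_change_sd_ms Exercise-group RMSSD change
#'   distribution (ms).
#' @param delta_z_sd Across-subject SD of the coupling change (z units, both
#'   groups).
#' @param subject_sd_z SD of the stable subject coupling trait (z units).
#' @param session_sd_z SD of the session-specific coupling noise (z units).
#' @param rest_rmssd_mean_ms,rest_rmssd_sd_ms Baseline resting RMSSD
#'   distribution (ms).
#' @param seed Integer RNG seed.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_per_group = 17L, interaction_delta_z = -0.4,
                        rho_fc_rmssd = -0.7, rmssd_change_mean_ms = 10,
                        rmssd_change_sd_ms = 8, delta_z_sd = 0.35,
                        subject_sd_z = 0.2, session_sd_z = 0.03,
                        rest_rmssd_mean_ms = 45, rest_rmssd_sd_ms = 8,
                        seed = 1L) {
  if (n_per_group < 2L) stop("n_per_group must be >= 2", call. = FALSE)
  if (abs(rho_fc_rmssd) > 1) stop("|rho_fc_rmssd| must be <= 1", call. = FALSE)
  structure(list(n_per_group = as.integer(n_per_group),
                 interaction_delta_z = interaction_delta_z,
                 rho_fc_rmssd = rho_fc_rmssd,
                 rmssd_change_mean_ms = rmssd_change_mean_ms,
                 rmssd_change_sd_ms = rmssd_change_sd_ms,
                 delta_z_sd = delta_z_sd, subject_sd_z = subject_sd_z,
                 session_sd_z = session_sd_z,
                 rest_rmssd_mean_ms = rest_rmssd_mean_ms,
                 rest_rmssd_sd_ms = rest_rmssd_sd_ms,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic BOLD cohort with planted effects
#'
#' Draws the per-subject, per-session ground-truth couplings and autonomic
#' scalars and assigns each session a derived RNG seed, so session volumes
#' can be materialized lazily with [cohort_volume()] (the full cohort of 4D
#' arrays is never held in memory). The returned table records the ground
#' truth (\code{truth_*} columns).
#'
#' @param phantom A [phantom_spec()].
#' @param cohort A [cohort_spec()].
#' @return An object of class \code{bold_cohort}: list with \code{phantom},
#'   \code{spec} and the cohort \code{table} (one row per subject-session).
#' @export
gen_bold_cohort <- function(phantom, cohort) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(cohort, "cohort_spec"))
  n <- 2L * cohort$n_per_group
  set.seed(cohort$seed)
  group <- rep(c("exercise", "control"), each = cohort$n_per_group)
  b <- stats::rnorm(n, sd = cohort$subject_sd_z)
  e0 <- stats::rnorm(n, sd = cohort$session_sd_z)
  e1 <- stats::rnorm(n, sd = cohort$session_sd_z)
  z1v <- stats::rnorm(n)
  z2v <- stats::rnorm(n)
  ex <- group == "exercise"
  rho <- cohort$rho_fc_rmssd
  delta <- ifelse(ex, cohort$interaction_delta_z, 0) + cohort$delta_z_sd * z1v
  drmssd <- ifelse(ex,
                   cohort$rmssd_change_mean_ms + cohort$rmssd_change_sd_ms *
                     (rho * z1v + sqrt(1 - rho^2) * z2v),
                   cohort$rmssd_change_sd_ms * z2v)
  z0 <- atanh(phantom$coupling_r) + b + e0
  z1 <- atanh(phantom$coupling_r) + b + e1 + delta
  if (any(!is.finite(tanh(c(z0, z1)))) || any(abs(tanh(c(z0, z1))) >= 1 - 1e-12)) {
    stop("planted shifts push |r| to 1; use a smaller interaction_delta_z",
         call. = FALSE)
  }
  rmssd_t0 <- cohort$rest_rmssd_mean_ms +
    cohort$rest_rmssd_sd_ms * stats::rnorm(n)
  rmssd_t0 <- pmax(rmssd_t0, 5)
  hr_t0 <- 65 + 6 * stats::rnorm(n)
  hr_t1 <- hr_t0 + ifelse(ex, -2, 0) + 2 * stats::rnorm(n)
  vt_t0 <- 150 + 25 * stats::rnorm(n)
  vt_t1 <- vt_t0 + ifelse(ex, 17, 0) + 8 * stats::rnorm(n)
  session_seed <- sample.int(.Machine$integer.max - 1L, 2L * n)
  subj <- sprintf("S%02d", seq_len(n))
  table <- data.frame(
    subject_id = rep(subj, times = 2),
    group = rep(group, times = 2),
    session = rep(c("T0", "T1"), each = n),
    rmssd_ms = c(rmssd_t0, rmssd_t0 + drmssd),
    hr_bpm = c(hr_t0, hr_t1),
    vt_power_w = c(vt_t0, vt_t1),
    truth_z = c(z0, z1),
    truth_r = tanh(c(z0, z1)),
    truth_delta_z = rep(delta, times = 2),
    truth_drmssd_ms = rep(drmssd, times = 2),
    session_seed = session_seed,
    stringsAsFactors = FALSE)
  structure(list(phantom = phantom, spec = cohort, table = table),
            class = "bold_cohort")
}

#' Materialize one session volume of a generated cohort
#'
#' @param x A \code{bold_cohort}.
#' @param subject_id Subject identifier (e.g. \code{"S03"}).
#' @param session \code{"T0"} or \code{"T1"}.
#' @return A \code{volume_series}.
#' @export
cohort_volume <- function(x, subject_id, session) {
  stopifnot(inherits(x, "bold_cohort"))
  row <- x$table[x$table$subject_id == subject_id & x$table$session == session, ]
  if (nrow(row) != 1L) stop("no such subject-session", call. = FALSE)
  gen_session_volume(x$phantom, r = row$truth_r, seed = row$session_seed)
}

#' Compute per-session Fisher-z seed maps for a whole cohort
#'
#' Runs the seed-map pipeline (discard initial volumes, optional temporal
#' preprocessing, seed extraction through the phantom's seed sphere,
#' voxelwise Fisher-z correlation) for every subject and session, and stacks
#' the results into an \code{fc_cohort} ready for group inference.
#'
#' @param x A \code{bold_cohort}.
#' @param discard_n Initial volumes to discard (default 5).
#' @param detrend Apply [detrend_quadratic()] (default FALSE; phantom noise
#'   is stationary).
#' @param bandpass Apply [bandpass_bold()] (default FALSE).
#' @param smooth_fwhm_mm Optional spatial smoothing FWHM (mm).
#' @return An [fc_cohort()].
#' @export
cohort_zmaps <- function(x, discard_n = 5L, detrend = FALSE, bandpass = FALSE,
                         smooth_fwhm_mm = NULL) {
  stopifnot(inherits(x, "bold_cohort"))
  tab <- x$table
  subj <- unique(tab$subject_id)
  d <- x$phantom$shape
  v <- prod(d)
  sspec <- phantom_seed_spec(x$phantom)
  get_map <- function(s, ses) {
    row <- tab[tab$subject_id == s & tab$session == ses, ]
    vol <- gen_session_volume(x$phantom, r = row$truth_r, seed = row$session_seed)
    if (discard_n > 0L) vol <- discard_initial(vol, discard_n)
    if (detrend) vol <- detrend_quadratic(vol)
    if (bandpass) vol <- bandpass_bold(vol)
    if (!is.null(smooth_fwhm_mm)) vol <- smooth_gaussian(vol, smooth_fwhm_mm)
    seed_map(vol, extract_seed(vol, sspec))
  }
  z0 <- matrix(NA_real_, v, length(subj))
  z1 <- matrix(NA_real_, v, length(subj))
  msk <- rep(TRUE, v)
  for (i in seq_along(subj)) {
    m0 <- get_map(subj[i], "T0"); m1 <- get_map(subj[i], "T1")
    z0[, i] <- as.numeric(m0$z); z1[, i] <- as.numeric(m1$z)
    msk <- msk & as.numeric(m0$mask) & as.numeric(m1$mask)
  }
  grp <- tab$group[match(subj, tab$subject_id)]
  fc_cohort(z0, z1, factor(grp, levels = c("exercise", "control")), d,
            mask = array(msk, dim = d), subjects = subj)
}
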