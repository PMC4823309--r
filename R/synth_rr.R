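#' Ground-truth profile for a synthetic incremental-exercise RR series
#'
#' Encodes the generative truth behind an incremental exercise recording: the
#' mean RR interval falls linearly from \code{rr_rest_ms} to \code{rr_end_ms}
#' over \code{[0, dp_true_s]} and stays there, while the local expected RMSSD
#' falls linearly from \code{rmssd_start_ms} to \code{rmssd_floor_ms} over the
#' same span and saturates at the floor afterwards. \code{dp_true_s} is thus
#' the true time at which vagally mediated variability reaches its floor, the
#' quantity deflection-point detection tries to recover.
#'
#' @param duration_s Total duration to generate (s).
#' @param rr_rest_ms,rr_end_ms Mean RR at rest / at the end of the decline (ms).
#' @param rmssd_start_ms,rmssd_floor_ms Local expected RMSSD at start / floor (ms).
#' @param dp_true_s Time (s) at which variability reaches its floor.
#' @param seed Integer RNG seed.
#' @return An object of class \code{rr_profile}.
#' @export
rr_profile <- function(duration_s = 700, rr_rest_ms = 1000, rr_end_ms = 600,
                       rmssd_start_ms = 40, rmssd_floor_ms = 3,
                       dp_true_s = 420, seed = 1L) {
  if (!(duration_s > 0)) stop("invalid rr_profile: duration_s must be > 0", call. = FALSE)
  if (!(rmssd_start_ms > rmssd_floor_ms)) {
    stop("invalid rr_profile: rmssd_start_ms must exceed rmssd_floor_ms", call. = FALSE)
  }
  if (!(rmssd_floor_ms >= 0)) stop("invalid rr_profile: rmssd_floor_ms must be >= 0", call. = FALSE)
  if (!(dp_true_s > 0 && dp_true_s < duration_s)) {
    stop("invalid rr_profile: dp_true_s must lie strictly inside (0, duration_s)", call. = FALSE)
  }
  if (!(rr_end_ms < rr_rest_ms)) {
    stop("invalid rr_profile: rr_end_ms must be smaller than rr_rest_ms", call. = FALSE)
  }
  if (!(rr_end_ms > 0)) stop("invalid rr_profile: rr_end_ms must be > 0", call. = FALSE)
  structure(list(duration_s = duration_s, rr_rest_ms = rr_rest_ms,
                 rr_end_ms = rr_end_ms, rmssd_start_ms = rmssd_start_ms,
                 rmssd_floor_ms = rmssd_floor_ms, dp_true_s = dp_true_s,
                 seed = as.integer(seed)),
            class = "rr_profile")
}

# Deterministic trend components of the generator, shared with the analytic
# oracle used in tests: both saturate at dp_true_s.
rr_trend_ms <- function(profile, t_s) {
  f <- pmin(t_s, profile$dp_true_s) / profile$dp_true_s
  profile$rr_rest_ms + (profile$rr_end_ms - profile$rr_rest_ms) * f
}

local_rmssd_ms <- function(profile, t_s) {
  f <- pmin(t_s, profile$dp_true_s) / profile$dp_true_s
  profile$rmssd_start_ms + (profile$rmssd_floor_ms - profile$rmssd_start_ms) * f
}

#' Generate an incremental-exercise RR series with a known variability floor
#'
#' Draws RR intervals as \code{trend(t) + e}, with independent Gaussian
#' deviations of SD \code{local_rmssd(t)/sqrt(2)}, so that the local expected
#' RMSSD (the RMS of successive differences of independent deviations) equals
#' the profile's linear decline-then-floor shape. Deterministic under the
#' profile's seed.
#'
#' @param profile An [rr_profile()].
#' @return A \code{beat_series} spanning at least \code{duration_s}.
#' @export
gen_rr_exercise <- function(profile) {
  stopifnot(inherits(profile, "rr_profile"))
  set.seed(profile$seed)
  # upper bound on beat count: shortest possible interval is the trend floor
  n_max <- ceiling(profile$duration_s * 1000 / profile$rr_end_ms) + 64L
  z <- stats::rnorm(n_max)
  rr <- numeric(n_max)
  t <- 0
  i <- 0L
  while (t < profile$duration_s && i < n_max) {
    i <- i + 1L
    sd_i <- local_rmssd_ms(profile, t) / sqrt(2)
    val <- rr_trend_ms(profile, t) + sd_i * z[i]
    # physiological guard; essentially never triggered for sane profiles
    if (val < 100) val <- 100
    rr[i] <- val
    t <- t + val / 1000
  }
  beat_series_from_rr(rr[seq_len(i)])
}

#' Generate a resting RR series with a target RMSSD
#'
#' Independent Gaussian RR values around \code{rr_mean_ms} with SD
#' \code{target_rmssd_ms / sqrt(2)}; since successive differences of
#' independent variables have SD \code{sqrt(2) * sigma}, the expected RMSSD
#' equals the target.
#'
#' @param n_beats Number of beats (>= 2; yields \code{n_beats - 1} intervals).
#' @param rr_mean_ms Mean RR interval (ms).
#' @param target_rmssd_ms Target expected RMSSD (ms, >= 0).
#' @param seed Integer RNG seed.
#' @return A \code{beat_series}.
#' @examples
#' rmssd(gen_rr_rest(1e4, 1000, 30 * sqrt(2), seed = 7))  # ~42.43 ms
#' @export
gen_rr_rest <- function(n_beats, rr_mean_ms = 1000, target_rmssd_ms = 40,
                        seed = 1L) {
  if (n_beats < 2L) stop("gen_rr_rest needs n_beats >= 2", call. = FALSE)
  if (target_rmssd_ms < 0) stop("target_rmssd_ms must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  rr <- stats::rnorm(n_beats - 1L, mean = rr_mean_ms,
                     sd = target_rmssd_ms / sqrt(2))
  rr[rr <= 0] <- rr_mean_ms  # guard, untouched for realistic settings
  beat_series_from_rr(rr)
}
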