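#' Sliding-window RMSSD track over a beat series
#'
#' Computes RMSSD in a sliding window of \code{window_beats} RR intervals
#' with \code{overlap_beats} intervals of overlap (the acquisition convention
#' is 256/192, i.e. a 64-interval advance). Each window is timestamped with
#' the mean beat time of the beats it spans. The number of windows is
#' \code{floor((n - window) / (window - overlap)) + 1}.
#'
#' @param beats A \code{beat_series} with at least \code{window_beats}
#'   intervals.
#' @param window_beats Window length in RR intervals (default 256).
#' @param overlap_beats Overlap between successive windows (default 192;
#'   must be < \code{window_beats}).
#' @return An object of class \code{sliding_hrv}: a data frame with columns
#'   \code{window_center_time_s} and \code{rmssd_ms} and attributes
#'   \code{window_beats}, \code{overlap_beats}.
#' @export
sliding_rmssd <- function(beats, window_beats = 256L, overlap_beats = 192L) {
  stopifnot(inherits(beats, "beat_series"))
  window_beats <- as.integer(window_beats)
  overlap_beats <- as.integer(overlap_beats)
  if (overlap_beats < 0L || overlap_beats >= window_beats) {
    stop("overlap_beats must satisfy 0 <= overlap < window_beats", call. = FALSE)
  }
  n <- n_intervals(beats)
  if (n < window_beats) {
    stop(sprintf("sliding_rmssd needs at least window_beats = %d intervals, got %d",
                 window_beats, n), call. = FALSE)
  }
  step <- window_beats - overlap_beats
  starts <- seq.int(1L, n - window_beats + 1L, by = step)
  # cumulative sums give O(1) per-window RMSSD and mean beat time
  d2 <- c(0, cumsum(diff(beats$rr_ms)^2))        # d2[k+1] = sum of first k sq diffs
  ct <- c(0, cumsum(beats$beat_time_s))
  val <- vapply(starts, function(s) {
    e <- s + window_beats - 1L                   # intervals s..e -> diffs s..e-1
    sqrt((d2[e] - d2[s]) / (window_beats - 1L))
  }, numeric(1))
  tm <- vapply(starts, function(s) {
    e_beat <- s + window_beats                   # beats s..s+window
    (ct[e_beat + 1L] - ct[s]) / (window_beats + 1L)
  }, numeric(1))
  structure(data.frame(window_center_time_s = tm, rmssd_ms = val),
            class = c("sliding_hrv", "data.frame"),
            window_beats = window_beats, overlap_beats = overlap_beats)
}

#' Deflection point and vagal threshold from a sliding RMSSD track
#'
#' Implements the tail-threshold rule: the threshold is the mean plus
#' \code{k_sd} (default 3) sample standard deviations of the track values
#' whose window centers fall in the last 30\% of the exercise time (where the
#' variability decline is complete), and the deflection point (DP) is the
#' center time of the first window - scanning forward from exercise start -
#' whose RMSSD drops strictly below that threshold. Optionally
#' \code{sustain_windows} consecutive sub-threshold windows can be required.
#'
#' @param track A \code{sliding_hrv}.
#' @param exercise_start_s,exercise_end_s Exercise interval (s) on the
#'   window-center clock.
#' @param k_sd Threshold multiplier on the tail SD (default 3).
#' @param sustain_windows Number of consecutive sub-threshold windows
#'   required (default 1).
#' @param tail_fraction Fraction of the exercise time forming the tail
#'   (default 0.3, i.e. the last 30\%).
#' @return An object of class \code{vagal_threshold_result}: list with
#'   \code{dp_time_s}, \code{threshold_ms}, \code{tail_mean_ms},
#'   \code{tail_sd_ms}, \code{n_tail_windows}, and \code{vt_power_w} /
#'   \code{vt_hr_bpm} (NA until filled by [vt_at_dp()]).
#' @export
deflection_point <- function(track, exercise_start_s, exercise_end_s,
                             k_sd = 3.0, sustain_windows = 1L,
                             tail_fraction = 0.3) {
  stopifnot(inherits(track, "sliding_hrv"))
  if (!(exercise_end_s > exercise_start_s)) {
    stop("exercise_end_s must exceed exercise_start_s", call. = FALSE)
  }
  tm <- track$window_center_time_s
  val <- track$rmssd_ms
  in_ex <- tm >= exercise_start_s & tm <= exercise_end_s
  tail_start <- exercise_start_s + (1 - tail_fraction) * (exercise_end_s - exercise_start_s)
  in_tail <- in_ex & tm >= tail_start
  if (sum(in_tail) < 2L) {
    stop(sprintf("need at least 2 windows in the last %.0f%% of exercise time, got %d",
                 100 * tail_fraction, sum(in_tail)), call. = FALSE)
  }
  if (sum(in_ex & !in_tail) < 1L) {
    stop("need at least 1 window before the tail segment", call. = FALSE)
  }
  tail_mean <- mean(val[in_tail])
  tail_sd <- stats::sd(val[in_tail])            # n-1 denominator
  threshold <- tail_mean + k_sd * tail_sd
  idx <- which(in_ex)
  below <- val[idx] < threshold                  # strict drop below
  dp_i <- NA_integer_
  run_len <- as.integer(sustain_windows)
  for (j in seq_along(idx)) {
    if (j + run_len - 1L > length(idx)) break
    if (all(below[j:(j + run_len - 1L)])) { dp_i <- idx[j]; break }
  }
  if (is.na(dp_i)) {
    stop(structure(class = c("vagalfc_dp_not_found", "error", "condition"),
                   list(message = sprintf(
                     "no window dropped below the threshold %.3f ms within the exercise interval",
                     threshold), call = NULL)))
  }
  structure(list(dp_time_s = tm[dp_i], threshold_ms = threshold,
                 tail_mean_ms = tail_mean, tail_sd_ms = tail_sd,
                 n_tail_windows = sum(in_tail),
                 vt_power_w = NA_real_, vt_hr_bpm = NA_real_),
            class = "vagal_threshold_result")
}

#' @export
print.vagal_threshold_result <- function(x, ...) {
  cat(sprintf("<vagal_threshold_result> DP %.1f s, threshold %.2f ms (tail %.2f +/- %.2f ms, n=%d)\n",
              x$dp_time_s, x$threshold_ms, x$tail_mean_ms, x$tail_sd_ms,
              x$n_tail_windows))
  if (!is.na(x$vt_power_w)) cat(sprintf("  vagal threshold power %.0f W\n", x$vt_power_w))
  invisible(x)
}

#' Build a stepped power ramp table
#'
#' Stage-start times on the exercise clock (t = 0 at exercise start) with the
#' stepped protocol's powers: stage k (0-based) runs
#' \code{[k * stage_s, (k+1) * stage_s)} at
#' \code{start_power_w + k * increment_w}.
#'
#' @param protocol A [stage_protocol()].
#' @param n_stages Number of stages.
#' @return Data frame with \code{stage_start_s}, \code{power_w} and attribute
#'   \code{stage_s}.
#' @export
stage_ramp <- function(protocol = stage_protocol(), n_stages = 8L) {
  k <- 0:(n_stages - 1L)
  structure(data.frame(stage_start_s = k * protocol$stage_s,
                       power_w = protocol$start_power_w + k * protocol$increment_w),
            stage_s = protocol$stage_s)
}

#' Attach the stage power (and heart rate) at the deflection point
#'
#' Fills \code{vt_power_w} by piecewise-constant lookup of the stage power
#' active at \code{dp_time_s} (the stepped protocol is not interpolated), and
#' optionally \code{vt_hr_bpm} from the nearest sample of a heart-rate track.
#'
#' @param result A \code{vagal_threshold_result}.
#' @param ramp Data frame with columns \code{stage_start_s}, \code{power_w}
#'   (e.g. from [stage_ramp()]); must cover \code{dp_time_s}.
#' @param hr Optional data frame with \code{time_s}, \code{hr_bpm}.
#' @return The result with \code{vt_power_w} (and \code{vt_hr_bpm}) filled.
#' @export
vt_at_dp <- function(result, ramp, hr = NULL) {
  stopifnot(inherits(result, "vagal_threshold_result"))
  if (!all(c("stage_start_s", "power_w") %in% names(ramp))) {
    stop("ramp needs columns stage_start_s and power_w", call. = FALSE)
  }
  starts <- ramp$stage_start_s
  stage_s <- attr(ramp, "stage_s")
  if (is.null(stage_s)) {
    stage_s <- if (nrow(ramp) > 1L) stats::median(diff(starts)) else
      stop("single-stage ramp without a stage_s attribute", call. = FALSE)
  }
  dp <- result$dp_time_s
  last_end <- starts[length(starts)] + stage_s
  if (dp < starts[1] || dp >= last_end) {
    stop(sprintf("dp_time_s = %.1f s lies outside the ramp [%.1f, %.1f)",
                 dp, starts[1], last_end), call. = FALSE)
  }
  result$vt_power_w <- ramp$power_w[findInterval(dp, starts)]
  if (!is.null(hr)) {
    result$vt_hr_bpm <- hr$hr_bpm[which.min(abs(hr$time_s - dp))]
  }
  result
}
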