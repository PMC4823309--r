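#' Adaptive artifact filtering of an RR series
#'
#' Replaces ectopic beats and measurement artifacts in an RR series by a
#' robust local rule: an interval deviating from the running median of its
#' \code{window_beats} neighbours by more than \code{k_sd} local robust
#' standard deviations (1.4826 * MAD about the local median) is replaced by
#' that local median. All decisions are taken against the original series in
#' a single pass, so the filter is idempotent on typical single-artifact
#' data. Beat times are rebuilt from the corrected intervals.
#'
#' @param beats A \code{beat_series}.
#' @param window_beats Number of neighbouring intervals forming the local
#'   window (split evenly around the index, default 20).
#' @param k_sd Rejection threshold in robust SD units (default 3).
#' @return A corrected \code{beat_series} with attributes
#'   \code{n_replaced}, \code{fraction_replaced} and logical
#'   \code{quality_flag} (TRUE when more than 20\% of intervals were
#'   replaced, also signalled as a warning).
#' @examples
#' rr <- rep(800, 50); rr[25] <- 400
#' out <- adaptive_filter_rr(beat_series_from_rr(rr))
#' attr(out, "n_replaced")
#' @export
adaptive_filter_rr <- function(beats, window_beats = 20L, k_sd = 3.0) {
  stopifnot(inherits(beats, "beat_series"))
  rr <- beats$rr_ms
  n <- length(rr)
  if (n < window_beats + 1L) {
    stop(sprintf("adaptive_filter_rr needs at least window_beats + 1 = %d intervals, got %d",
                 window_beats + 1L, n), call. = FALSE)
  }
  half <- max(1L, window_beats %/% 2L)
  out <- rr
  replaced <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    nb <- rr[setdiff(lo:hi, i)]
    med <- stats::median(nb)
    rsd <- stats::mad(nb, center = med)  # 1.4826 * MAD
    if (abs(rr[i] - med) > k_sd * rsd) {
      out[i] <- med
      replaced[i] <- TRUE
    }
  }
  frac <- mean(replaced)
  res <- beat_series_from_rr(out, t0_s = beats$beat_time_s[1])
  attr(res, "n_replaced") <- sum(replaced)
  attr(res, "fraction_replaced") <- frac
  attr(res, "quality_flag") <- frac > 0.2
  if (frac > 0.2) {
    warning(sprintf("adaptive_filter_rr replaced %.1f%% of intervals; signal quality suspect",
                    100 * frac), call. = FALSE)
  }
  res
}
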