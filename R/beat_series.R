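#' Construct a beat series from beat times
#'
#' A beat series is the substrate of all heart-rate-variability computation in
#' this package: an ordered vector of beat times (s) together with the derived
#' RR intervals (ms), \code{rr_ms[i] = 1000 * (beat_time_s[i+1] - beat_time_s[i])}.
#'
#' @param beat_time_s Numeric vector of strictly increasing beat times in
#'   seconds (at least 2 beats).
#' @return An object of class \code{beat_series}: a list with elements
#'   \code{beat_time_s} and \code{rr_ms}.
#' @examples
#' b <- beat_series(c(0, 0.8, 1.62, 2.41))
#' b$rr_ms
#' @export
beat_series <- function(beat_time_s) {
  beat_time_s <- as.numeric(beat_time_s)
  if (length(beat_time_s) < 2L) {
    stop("beat_series needs at least 2 beat times", call. = FALSE)
  }
  rr <- 1000 * diff(beat_time_s)
  if (any(rr <= 0)) {
    stop("beat times must be strictly increasing (all RR intervals > 0)",
         call. = FALSE)
  }
  structure(list(beat_time_s = beat_time_s, rr_ms = rr),
            class = "beat_series")
}

#' Construct a beat series from RR intervals
#'
#' @param rr_ms Numeric vector of positive RR intervals in milliseconds.
#' @param t0_s Time of the first beat (seconds), default 0.
#' @return A \code{beat_series}.
#' @export
beat_series_from_rr <- function(rr_ms, t0_s = 0) {
  rr_ms <- as.numeric(rr_ms)
  if (length(rr_ms) < 1L || any(rr_ms <= 0)) {
    stop("rr_ms must contain at least one positive interval", call. = FALSE)
  }
  # keep the supplied intervals exactly (re-deriving them from cumulative
  # times would perturb them in the last bits)
  structure(list(beat_time_s = t0_s + c(0, cumsum(rr_ms)) / 1000,
                 rr_ms = rr_ms),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats over %.1f s, mean RR %.1f ms\n",
              length(x$beat_time_s), diff(range(x$beat_time_s)),
              mean(x$rr_ms)))
  invisible(x)
}

n_intervals <- function(beats) length(beats$rr_ms)

#' Root mean square of successive RR-interval differences (RMSSD)
#'
#' The time-domain index of vagally mediated heart rate variability:
#' \eqn{\sqrt{\mathrm{mean}((\Delta RR)^2)}} over successive RR differences,
#' in milliseconds.
#'
#' @param beats A \code{beat_series} (or a plain numeric vector of RR
#'   intervals in ms).
#' @return RMSSD in ms (scalar, >= 0).
#' @examples
#' rmssd(beat_series_from_rr(c(800, 810, 790)))  # sqrt(250)
#' @export
rmssd <- function(beats) {
  rr <- if (inherits(beats, "beat_series")) beats$rr_ms else as.numeric(beats)
  if (length(rr) < 2L) {
    stop("rmssd needs at least 2 RR intervals (3 beats)", call. = FALSE)
  }
  sqrt(mean(diff(rr)^2))
}

#' Mean heart rate from a beat series
#'
#' Uses the mean-of-intervals convention \code{60000 / mean(rr_ms)} (bpm),
#' which differs from the mean of instantaneous rates when RR varies.
#'
#' @inheritParams rmssd
#' @return Mean heart rate in beats per minute.
#' @examples
#' mean_hr(beat_series_from_rr(c(500, 1000)))  # 80 bpm
#' @export
mean_hr <- function(beats) {
  rr <- if (inherits(beats, "beat_series")) beats$rr_ms else as.numeric(beats)
  if (length(rr) < 1L) stop("mean_hr needs at least 1 RR interval", call. = FALSE)
  60000 / mean(rr)
}

#' Summarize autonomic state of a recording
#'
#' @inheritParams rmssd
#' @return A one-row data frame with \code{mean_hr_bpm}, \code{rmssd_ms},
#'   \code{n_beats}.
#' @export
autonomic_summary <- function(beats) {
  stopifnot(inherits(beats, "beat_series"))
  data.frame(mean_hr_bpm = mean_hr(beats),
             rmssd_ms = rmssd(beats),
             n_beats = length(beats$beat_time_s))
}

#' Write / read a beat series as two-column TSV
#'
#' Columns \code{beat_time_s} and \code{rr_ms}; the first row carries
#' \code{rr_ms = NA} because the first beat has no preceding interval.
#'
#' @param beats A \code{beat_series}.
#' @param path File path.
#' @return \code{write_beat_series} returns \code{path} invisibly;
#'   \code{read_beat_series} returns a \code{beat_series}.
#' @export
write_beat_series <- function(beats, path) {
  stopifnot(inherits(beats, "beat_series"))
  df <- data.frame(beat_time_s = beats$beat_time_s,
                   rr_ms = c(NA, beats$rr_ms))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_beat_series
#' @export
read_beat_series <- function(path) {
  df <- utils::read.delim(path)
  beat_series(df$beat_time_s)
}
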