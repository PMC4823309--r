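# Photoplethysmogram synthesis and pulse-to-RR conversion.

# Stereotyped pulse waveform: asymmetric gamma-like bump with unit peak
# amplitude placed so its maximum sits exactly at the beat time (fast rise
# over `rise_s`, slower decay). Only the peak timing matters downstream.
ppg_template <- function(tau_s, rise_s = 0.15, shape = 2) {
  u <- (tau_s + rise_s) / rise_s
  out <- ifelse(u > 0, u^shape * exp(shape * (1 - u)), 0)
  out[tau_s < -rise_s | tau_s > 0.8] <- 0
  out
}

#' Generate a photoplethysmogram trace from a beat series
#'
#' One stereotyped pulse wave (rise-peak-decay template, unit amplitude, peak
#' at the beat time) per beat, plus additive white Gaussian noise, sampled at
#' \code{fs_hz}.
#'
#' @param beats A \code{beat_series} giving the true beat times.
#' @param fs_hz Sampling rate (Hz, > 10; the acquisition convention is 500 Hz).
#' @param noise_sd Additive Gaussian noise SD in units of the unit pulse
#'   amplitude.
#' @param seed Integer RNG seed.
#' @param duration_s Optional trace duration; default covers the last beat
#'   plus the template tail.
#' @return Numeric trace with attributes \code{fs_hz} and \code{time_s}.
#' @export
gen_ppg <- function(beats, fs_hz = 500, noise_sd = 0, seed = 1L,
                    duration_s = NULL) {
  stopifnot(inherits(beats, "beat_series"))
  if (fs_hz <= 10) stop("gen_ppg needs fs_hz > 10", call. = FALSE)
  if (length(beats$beat_time_s) == 0L) stop("empty beat series", call. = FALSE)
  if (is.null(duration_s)) duration_s <- max(beats$beat_time_s) + 1.0
  n <- ceiling(duration_s * fs_hz)
  tgrid <- (seq_len(n) - 1L) / fs_hz
  trace <- numeric(n)
  half_support <- 0.81
  for (tb in beats$beat_time_s) {
    i0 <- max(1L, floor((tb - 0.16) * fs_hz) + 1L)
    i1 <- min(n, ceiling((tb + half_support) * fs_hz) + 1L)
    if (i0 > n || i1 < 1L) next
    idx <- i0:i1
    trace[idx] <- trace[idx] + ppg_template(tgrid[idx] - tb)
  }
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    trace <- trace + stats::rnorm(n, sd = noise_sd)
  }
  structure(trace, fs_hz = fs_hz, time_s = tgrid)
}

#' Zero-phase band-pass filter for pulse traces
#'
#' 4-pole Butterworth band-pass applied forward and backward
#' (\code{signal::filtfilt}), so the net filter is zero-phase with squared
#' magnitude response. Default band 0.5-5 Hz covers the pulse fundamental at
#' 30-300 bpm.
#'
#' @param trace Numeric sampled trace.
#' @param fs_hz Sampling rate (Hz).
#' @param low_hz,high_hz Band edges (Hz), \code{0 < low < high < fs/2}.
#' @return Filtered trace (attributes preserved).
#' @export
bandpass_pulse <- function(trace, fs_hz, low_hz = 0.5, high_hz = 5.0) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs_hz / 2)) {
    stop("band edges must satisfy 0 < low_hz < high_hz < fs_hz/2", call. = FALSE)
  }
  bf <- signal::butter(2, c(low_hz, high_hz) / (fs_hz / 2), type = "pass")
  out <- signal::filtfilt(bf, as.numeric(trace))
  attributes(out) <- attributes(trace)
  out
}

#' Detect pulse peaks in a photoplethysmogram and return the beat series
#'
#' Band-pass filters the trace (optional), finds local maxima above a
#' prominence floor and enforces a minimum inter-peak distance by greedily
#' keeping the highest peaks first. Defaults: 0.33 s minimum distance
#' (<= 180 bpm) and a floor of \code{prominence_frac} times the 95th
#' percentile amplitude of the (filtered) trace.
#'
#' @param trace Numeric sampled trace (raw or already band-passed).
#' @param fs_hz Sampling rate (Hz).
#' @param bandpass Apply [bandpass_pulse()] first (default TRUE).
#' @param min_distance_s Minimum inter-peak distance (s).
#' @param prominence_frac Fraction of the 95th-percentile amplitude used as
#'   the height floor.
#' @param low_hz,high_hz Band edges forwarded to [bandpass_pulse()].
#' @return A \code{beat_series} of detected beat times.
#' @export
detect_pulse_peaks <- function(trace, fs_hz, bandpass = TRUE,
                               min_distance_s = 0.33, prominence_frac = 0.3,
                               low_hz = 0.5, high_hz = 5.0) {
  x <- as.numeric(trace)
  if (bandpass) x <- as.numeric(bandpass_pulse(x, fs_hz, low_hz, high_hz))
  n <- length(x)
  if (n < 3L) stop("trace too short for peak detection", call. = FALSE)
  floor_h <- prominence_frac * stats::quantile(x, 0.95, names = FALSE)
  i <- 2:(n - 1L)
  cand <- i[x[i] > x[i - 1L] & x[i] >= x[i + 1L] & x[i] > floor_h & x[i] > 0]
  if (length(cand) == 0L) {
    stop("no pulse peaks found (trace flat or below prominence floor)",
         call. = FALSE)
  }
  cand <- cand[order(x[cand], decreasing = TRUE)]
  min_gap <- round(min_distance_s * fs_hz)
  keep <- integer(0)
  for (ci in cand) {
    if (all(abs(keep - ci) >= min_gap)) keep <- c(keep, ci)
  }
  keep <- sort(keep)
  if (length(keep) < 2L) {
    stop("fewer than 2 pulse peaks found; cannot form RR intervals",
         call. = FALSE)
  }
  beat_series((keep - 1L) / fs_hz)
}

#' Write / read a PPG trace as plain text
#'
#' One sample per line, preceded by a header line \code{# fs_hz <value>}.
#'
#' @param trace Trace from [gen_ppg()] (or any numeric with \code{fs_hz}
#'   attribute / explicit \code{fs_hz}).
#' @param path File path.
#' @param fs_hz Sampling rate; defaults to the trace attribute.
#' @return \code{write_ppg} returns \code{path} invisibly; \code{read_ppg}
#'   returns the trace with its \code{fs_hz} attribute set.
#' @export
write_ppg <- function(trace, path, fs_hz = attr(trace, "fs_hz")) {
  if (is.null(fs_hz)) stop("fs_hz unknown; supply it explicitly", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz %g", fs_hz), con)
  writeLines(format(as.numeric(trace), digits = 10, trim = TRUE, scientific = FALSE), con)
  invisible(path)
}

#' @rdname write_ppg
#' @export
read_ppg <- function(path) {
  hdr <- readLines(path, n = 1L)
  fs <- as.numeric(sub("^#\\s*fs_hz\\s+", "", hdr))
  if (!is.finite(fs)) stop("missing '# fs_hz' header in PPG file", call. = FALSE)
  vals <- utils::read.table(path, skip = 1L)[[1]]
  structure(as.numeric(vals), fs_hz = fs)
}
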