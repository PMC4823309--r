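test_that("rmssd follows the direct formula and its invariances", {
  expect_equal(rmssd(beat_series_from_rr(c(800, 800, 800))), 0)
  expect_equal(rmssd(beat_series_from_rr(c(800, 810, 790))), sqrt(250))
  # homogeneity: scaling RR scales RMSSD
  set.seed(4)
  rr <- stats::rnorm(50, 900, 30)
  expect_equal(rmssd(2 * rr), 2 * rmssd(rr))
  # exact agreement with an independent loop on random series
  for (i in 1:20) {
    rr <- stats::rnorm(sample(3:200, 1), 800, 50)
    expect_equal(rmssd(rr), rmssd_loop(rr), tolerance = 1e-14)
  }
  expect_error(rmssd(beat_series_from_rr(c(800))), "at least 2")
})

test_that("mean_hr uses the mean-of-intervals convention", {
  expect_equal(mean_hr(beat_series_from_rr(rep(1000, 10))), 60)
  expect_equal(mean_hr(beat_series_from_rr(rep(800, 10))), 75)
  expect_equal(mean_hr(beat_series_from_rr(c(500, 1000))), 80)
  expect_error(mean_hr(numeric(0)))
})

test_that("beat series validates and round-trips through TSV", {
  expect_error(beat_series(c(0, 0.5, 0.5)), "strictly increasing")
  expect_error(beat_series(1), "at least 2")
  b <- gen_rr_rest(50, 900, 35, seed = 8)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_beat_series(b, f)
  b2 <- read_beat_series(f)
  expect_equal(b2$beat_time_s, b$beat_time_s, tolerance = 1e-8)
  s <- autonomic_summary(b)
  expect_equal(s$n_beats, 50)
  expect_gt(s$mean_hr_bpm, 0)
})

test_that("pulse band-pass passes the band and rejects outside it", {
  fs <- 500
  t <- seq(0, 20, by = 1 / fs)
  trim <- seq(length(t) %/% 4, 3 * length(t) %/% 4)
  y2 <- bandpass_pulse(sin(2 * pi * 2 * t), fs)
  expect_lt(abs(max(abs(y2[trim])) - 1), 0.05)
  yslow <- bandpass_pulse(sin(2 * pi * 0.05 * t), fs)
  expect_lt(max(abs(yslow[trim])), 0.10)
  expect_equal(as.numeric(bandpass_pulse(numeric(1000) , fs)), numeric(1000))
  expect_error(bandpass_pulse(sin(t), fs, low_hz = 5, high_hz = 0.5), "band edges")
})

test_that("pulse peak detection recovers constructed beats exactly", {
  b <- beat_series(c(0.5, 1.5, 2.5))
  tr <- gen_ppg(b, fs_hz = 500, noise_sd = 0)
  # noiseless trace has exactly one template maximum per beat
  det <- detect_pulse_peaks(tr, 500, bandpass = FALSE)
  expect_length(det$beat_time_s, 3)
  expect_equal(det$beat_time_s, b$beat_time_s, tolerance = 1 / 500 + 1e-9)
  expect_equal(diff(det$beat_time_s), c(1, 1), tolerance = 2 / 500)
  expect_error(detect_pulse_peaks(numeric(5000), 500), "no pulse peaks|flat")
})

test_that("ppg generator: sample count, determinism and text round-trip", {
  b <- beat_series(c(0.5, 1.5, 2.5))
  tr <- gen_ppg(b, fs_hz = 500, noise_sd = 0, duration_s = 10)
  expect_length(as.numeric(tr), 5000)
  t1 <- gen_ppg(b, 500, noise_sd = 0.1, seed = 3)
  t2 <- gen_ppg(b, 500, noise_sd = 0.1, seed = 3)
  expect_identical(as.numeric(t1), as.numeric(t2))
  expect_error(gen_ppg(b, fs_hz = 5), "fs_hz > 10")
  f <- withr::local_tempfile(fileext = ".txt")
  write_ppg(t1, f)
  r <- read_ppg(f)
  expect_equal(attr(r, "fs_hz"), 500)
  expect_equal(as.numeric(r), as.numeric(t1), tolerance = 1e-7)
})

test_that("generator-to-detector round trip recovers beats under noise", {
  beats <- gen_rr_rest(1000, 900, 30, seed = 2)
  trace <- gen_ppg(beats, fs_hz = 500, noise_sd = 0.1, seed = 3)
  det <- detect_pulse_peaks(trace, 500)
  err_ms <- vapply(beats$beat_time_s,
                   function(tb) 1000 * min(abs(det$beat_time_s - tb)),
                   numeric(1))
  expect_gte(mean(err_ms <= 20), 0.99)
})

test_that("adaptive RR filter replaces ectopics and nothing else", {
  clean <- beat_series_from_rr(rep(800, 60))
  out <- adaptive_filter_rr(clean)
  expect_equal(out$rr_ms, clean$rr_ms)
  expect_equal(attr(out, "n_replaced"), 0L)

  set.seed(11)
  rr <- stats::rnorm(1000, 800, 5)
  rr[500] <- 400
  filt <- adaptive_filter_rr(beat_series_from_rr(rr))
  expect_gte(attr(filt, "n_replaced"), 1L)
  expect_true(all(filt$rr_ms > 700))
  # hand evaluation of the rule at the outlier index
  nb <- rr[c(490:499, 501:510)]
  expect_gt(abs(400 - stats::median(nb)), 3 * stats::mad(nb, center = stats::median(nb)))
  # idempotent on its own output for the single-ectopic fixture
  rr2 <- rep(800, 200); rr2[100] <- 400
  f1 <- adaptive_filter_rr(beat_series_from_rr(rr2))
  expect_equal(attr(f1, "n_replaced"), 1L)
  f2 <- adaptive_filter_rr(f1)
  expect_identical(f2$rr_ms, f1$rr_ms)
  expect_equal(attr(f2, "n_replaced"), 0L)

  expect_error(adaptive_filter_rr(beat_series_from_rr(rep(800, 20))),
               "at least window_beats")
})

test_that("adaptive RR filter flags poor-quality recordings", {
  set.seed(3)
  rr <- stats::rnorm(100, 800, 3)
  rr[seq(1, 100, by = 4)] <- 1600   # 25% spikes
  expect_warning(out <- adaptive_filter_rr(beat_series_from_rr(rr)),
                 "signal quality")
  expect_true(attr(out, "quality_flag"))
})
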