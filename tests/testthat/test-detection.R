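# Detector tests run on short scenes (a few seconds at 200 kHz); the
# filter and detector are duration-agnostic.

fs <- 200e3

test_that("band-pass filter preserves the passband and kills the stopband", {
  t <- seq(0, 0.02, by = 1 / fs)
  mid <- seq(1000, length(t) - 1000)
  gain_db <- function(f) {
    x <- sin(2 * pi * f * t)
    y <- bandpass_filter(audio_segment(x, fs))$samples
    20 * log10(sd(y[mid]) / sd(x[mid]))
  }
  expect_gt(gain_db(50e3), -1)   # in-band identity
  expect_lt(gain_db(1e3), -40)   # deep stopband
  expect_lt(gain_db(5e3), -40)   # 0.5 x low edge
  expect_lt(gain_db(99e3), -40)  # above the high edge
  expect_error(bandpass_filter(audio_segment(rnorm(100), fs), 90e3, 10e3),
               "band edges")
  expect_error(bandpass_filter(audio_segment(rnorm(100), fs), 10e3, 150e3),
               "band edges")
})

test_that("filtered white noise loses out-of-band power by 40 dB or more", {
  set.seed(1)
  x <- rnorm(2^17)
  y <- bandpass_filter(audio_segment(x, fs))$samples
  # direct periodogram oracle on the output
  p <- Mod(fft(y))^2
  freq <- (seq_along(p) - 1) / length(p) * fs
  inband <- freq > 15e3 & freq < 85e3
  outband <- freq < 4e3 | (freq > 96e3 & freq < 100e3)
  expect_gt(10 * log10(mean(p[inband]) / mean(p[outband])), 40)
})

test_that("pure noise below the boundary threshold yields no detections", {
  set.seed(2)
  # calibrated level of the energy trace ~ 80 dB (threshold 95)
  cal <- 50
  x <- rnorm(fs * 0.5, 0, 10^((80 - cal) / 20))
  audio <- audio_segment(x, fs, cal_db = cal)
  expect_equal(nrow(detect_clicks(audio)), 0)
})

test_that("audio shorter than the smoothing window yields an empty result", {
  audio <- audio_segment(rnorm(5), fs, cal_db = 120)
  expect_equal(nrow(detect_clicks(audio)), 0)
})

test_that("a planted impulse is detected at its true time", {
  set.seed(3)
  cal <- 50
  spec <- click_type_spec("T", peak_khz = 40, bandwidth_khz = 6,
                          modal_ici = 0.1)
  noise <- rnorm(fs, 0, 10^((75 - cal) / 20))
  wf <- synth_click_waveform(spec, fs, cal_db = cal, level_dbpp = 130,
                             jitter = FALSE)
  t_true <- 0.5
  at <- round(t_true * fs) + 1
  half <- (length(wf) - 1) / 2
  x <- noise
  x[(at - half):(at + half)] <- x[(at - half):(at + half)] + wf
  audio <- audio_segment(x, fs, cal_db = cal)
  dets <- detect_clicks(audio)
  expect_equal(nrow(dets), 1)
  expect_lt(abs(dets$start_time - t_true), 5e-4)
  # oracle: argmax of the 50-us moving-average energy lies inside the bounds
  e <- as.numeric(stats::filter(x^2, rep(1 / 10, 10), sides = 2))
  peak_t <- (which.max(e) - 1) / fs
  expect_gte(peak_t, dets$start_time - 1e-4)
  expect_lte(peak_t, dets$end_time + 1e-4)
  # snippet carries 20 samples of context each side
  expect_equal(length(dets$snippet[[1]]),
               dets$end_idx - dets$start_idx + 1 + 40)
})

test_that("impulses 5 ms apart produce two separate detections", {
  set.seed(4)
  cal <- 50
  spec <- click_type_spec("T", peak_khz = 40, bandwidth_khz = 6,
                          modal_ici = 0.1)
  x <- rnorm(fs %/% 10, 0, 10^((70 - cal) / 20))
  wf <- synth_click_waveform(spec, fs, cal_db = cal, level_dbpp = 132,
                             jitter = FALSE)
  half <- (length(wf) - 1) / 2
  for (tt in c(0.04, 0.045)) {
    at <- round(tt * fs) + 1
    x[(at - half):(at + half)] <- x[(at - half):(at + half)] + wf
  }
  audio <- audio_segment(x, fs, cal_db = cal)
  dets <- detect_clicks(audio)
  expect_equal(nrow(dets), 2)
  expect_lt(abs(diff(dets$start_time) - 0.005), 2e-4)
  # brute-force boundary-crossing oracle: two disjoint above-threshold runs
  e <- as.numeric(stats::filter(x^2, rep(1 / 10, 10), sides = 2))
  e_db <- 10 * log10(pmax(e, 1e-300)) + cal
  e_db[is.na(e)] <- -Inf
  runs <- rle(e_db > 95)
  expect_equal(sum(runs$values), 2)
})

test_that("detection is translation-equivariant and calibration-covariant", {
  set.seed(5)
  cal <- 50
  spec <- click_type_spec("T", peak_khz = 35, bandwidth_khz = 6,
                          modal_ici = 0.1)
  x <- rnorm(fs %/% 10, 0, 10^((70 - cal) / 20))
  wf <- synth_click_waveform(spec, fs, cal_db = cal, level_dbpp = 131,
                             jitter = FALSE)
  half <- (length(wf) - 1) / 2
  at <- round(0.05 * fs)
  x[(at - half):(at + half)] <- x[(at - half):(at + half)] + wf
  d1 <- detect_clicks(audio_segment(x, fs, cal_db = cal))
  k <- 1000
  d2 <- detect_clicks(audio_segment(c(rep(0, k), x), fs, cal_db = cal))
  expect_equal(d2$start_time, d1$start_time + k / fs, tolerance = 1 / fs)
  # +c dB calibration shifts received levels and spectra by exactly +c
  a1 <- audio_segment(x, fs, cal_db = cal)
  a2 <- audio_segment(x, fs, cal_db = cal + 7)
  m1 <- measure_clicks(detect_clicks(a1), a1)
  # same boundary threshold crossed differently under +7 dB, so measure
  # the identical snippet set under both calibrations
  dets <- detect_clicks(a1)
  m2 <- measure_clicks(dets, a2)
  expect_equal(m2$rl_pp_db, m1$rl_pp_db + 7, tolerance = 1e-10)
  expect_equal(spectrum_matrix(m2), spectrum_matrix(m1) + 7,
               tolerance = 1e-10)
})

test_that("click spectra equal a directly evaluated windowed DFT", {
  # tone snippet: spectral peak at the tone frequency within one bin
  tt <- (0:299) / fs
  tone <- sin(2 * pi * 30e3 * tt)
  spec <- compute_click_spectrum(tone, fs)
  freq <- attr(spec, "freq_hz")
  expect_lt(abs(freq[which.max(spec)] - 30e3), 501)
  # flat +6 dB transfer function adds exactly 6 dB everywhere
  tf <- data.frame(frequency_hz = c(0, 100e3), db = c(6, 6))
  spec6 <- compute_click_spectrum(tone, fs, transfer_function = tf)
  expect_equal(as.numeric(spec6), as.numeric(spec) + 6)
  # Gaussian-windowed chirp against an independent DFT oracle
  set.seed(6)
  n <- 240
  tt <- (0:(n - 1)) / fs
  x <- exp(-((tt - 6e-4)^2) / (2 * 2e-4^2)) *
    cos(2 * pi * (25e3 * tt + 2e7 * tt^2))
  got <- compute_click_spectrum(x, fs, cal_db = 12)
  hann <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  padded <- c(x * hann, rep(0, 400 - n))
  k <- 0:199
  oracle <- sapply(k, function(kk) {
    20 * log10(Mod(sum(padded * exp(-2i * pi * kk * (0:399) / 400)))) + 12
  })
  expect_equal(as.numeric(got), oracle, tolerance = 1e-6)
  expect_error(compute_click_spectrum(numeric(0), fs), "empty")
})

test_that("long snippets are truncated about the envelope peak", {
  tt <- (0:999) / fs
  x <- exp(-((tt - 3e-3)^2) / (2 * 1e-4^2)) * cos(2 * pi * 40e3 * tt)
  spec <- compute_click_spectrum(x, fs)
  expect_length(spec, 200)
  freq <- attr(spec, "freq_hz")
  expect_lt(abs(freq[which.max(spec)] - 40e3), 501)
})

test_that("quality control retains exactly the conforming clicks", {
  base <- data.frame(peak_khz = 40, rl_pp_db = 130, env_dur_s = 1e-4)
  mk <- function(n, ...) {
    df <- base[rep(1, n), ]
    over <- list(...)
    for (nm in names(over)) df[[nm]] <- over[[nm]]
    df
  }
  clicks <- rbind(mk(70), mk(10, peak_khz = 10), mk(10, rl_pp_db = 118),
                  mk(10, env_dur_s = 5e-3))
  kept <- qc_filter(clicks)
  # oracle: direct predicate evaluation
  pred <- clicks$peak_khz >= 15 & clicks$peak_khz <= 85 &
    clicks$rl_pp_db > 120 & clicks$env_dur_s < 1e-3
  expect_equal(nrow(kept), 70)
  expect_equal(nrow(kept), sum(pred))
  # subset, order preserved, idempotent
  expect_true(all(rownames(kept) %in% rownames(clicks)))
  expect_identical(qc_filter(kept), kept)
  expect_equal(nrow(qc_filter(clicks[0, ])), 0)
  # boundary cases from the retention rules
  expect_equal(nrow(qc_filter(mk(1, peak_khz = 10))), 0)
  expect_equal(nrow(qc_filter(mk(1, rl_pp_db = 118))), 0)
})
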