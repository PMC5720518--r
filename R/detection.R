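#' Detector configuration
#'
#' Defaults follow the standard wideband (200 kHz) seafloor-recorder
#' workflow: audio band-pass filtered 10-90 kHz; click boundaries where a
#' 50-us moving average of calibrated energy exceeds 95 dB re 1 uPa;
#' retained detections must have peak frequency in 15-85 kHz, received
#' level above 120 dB peak-to-peak re 1 uPa, and a high-energy Hilbert
#' envelope duration below `max_envelope_duration`.
#'
#' @param boundary_threshold_db Energy threshold (dB re 1 uPa) defining
#'   click start/end on the smoothed energy trace. Default 95.
#' @param rl_threshold_dbpp Minimum received level, dB peak-to-peak re 1 uPa.
#'   Default 120.
#' @param peak_range_khz Acceptable peak-frequency interval, kHz. Default
#'   `c(15, 85)`.
#' @param max_envelope_duration Maximum duration (s) for which the Hilbert
#'   envelope may exceed 50% of its maximum. Default 1 ms: the width of a
#'   delphinid click including surface/bottom multipath is well under this,
#'   while longer tonal or ship transients are excluded.
#' @param smooth_us Energy smoothing (moving-average) window, microseconds.
#'   Default 50.
#' @param merge_gap_us Threshold crossings separated by less than this gap
#'   (microseconds) are merged into one detection. Default 100.
#' @param band_hz Analysis band (Hz) for filtering and peak search.
#' @param n_fft DFT length for click spectra. Default 400 (500 Hz/bin at
#'   200 kHz).
#' @param context_samples Samples of context kept before and after the
#'   detected boundaries in each snippet. Default 20.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(boundary_threshold_db = 95,
                            rl_threshold_dbpp = 120,
                            peak_range_khz = c(15, 85),
                            max_envelope_duration = 1e-3,
                            smooth_us = 50,
                            merge_gap_us = 100,
                            band_hz = c(10e3, 90e3),
                            n_fft = 400,
                            context_samples = 20) {
  structure(list(
    boundary_threshold_db = boundary_threshold_db,
    rl_threshold_dbpp = rl_threshold_dbpp,
    peak_range_khz = peak_range_khz,
    max_envelope_duration = max_envelope_duration,
    smooth_us = smooth_us,
    merge_gap_us = merge_gap_us,
    band_hz = band_hz,
    n_fft = n_fft,
    context_samples = context_samples
  ), class = "detector_config")
}

#' Band-pass filter an audio segment
#'
#' Linear-phase FIR band-pass applied forward and backward (zero phase), so
#' detection times are not biased by group delay. Stopband attenuation is
#' far in excess of 40 dB one octave below the low edge and beyond the high
#' edge; passband ripple is well under 1 dB.
#'
#' @param audio An [audio_segment()].
#' @param low,high Band edges in Hz; `0 < low < high < sample_rate/2`.
#' @param order FIR order (number of taps minus one). Default 128.
#' @return A filtered [audio_segment()] of identical length and timestamps.
#' @export
bandpass_filter <- function(audio, low = 10e3, high = 90e3, order = 128) {
  stopifnot(inherits(audio, "audio_segment"))
  fs <- audio$sample_rate
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("invalid band edges: need 0 < low < high < sample_rate/2")
  }
  b <- as.numeric(signal::fir1(order, c(low, high) / (fs / 2), type = "pass"))
  y <- signal::filtfilt(b, 1, audio$samples)
  out <- audio
  out$samples <- as.numeric(y)
  out
}

# Hilbert envelope via the analytic signal (FFT method).
hilbert_envelope <- function(x) {
  n <- length(x)
  if (n == 0) return(numeric(0))
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

# Duration (s) over which the Hilbert envelope exceeds 50% of its maximum.
envelope_duration <- function(snippet, sample_rate) {
  env <- hilbert_envelope(snippet)
  if (length(env) == 0 || max(env) == 0) return(0)
  sum(env > 0.5 * max(env)) / sample_rate
}

#' Detect candidate echolocation clicks with an energy threshold
#'
#' Computes the calibrated smoothed energy trace (moving average of squared
#' pressure over `smooth_us`, in dB re 1 uPa) and marks each maximal run of
#' samples above `boundary_threshold_db` as one detection; runs separated by
#' less than `merge_gap_us` are merged. Each detection's snippet includes
#' `context_samples` samples of context on both sides.
#'
#' @param audio A band-pass filtered, calibrated [audio_segment()].
#' @param config A [detector_config()].
#' @return A data.frame with columns `start_time`, `end_time` (absolute
#'   seconds), `start_idx`, `end_idx` (sample indices of the threshold
#'   crossings) and a list column `snippet`; zero rows when the audio is
#'   shorter than the smoothing window or nothing crosses the threshold.
#' @export
detect_clicks <- function(audio, config = detector_config()) {
  stopifnot(inherits(audio, "audio_segment"))
  fs <- audio$sample_rate
  x <- audio$samples
  w <- max(1L, as.integer(round(config$smooth_us * 1e-6 * fs)))
  empty <- data.frame(start_time = numeric(0), end_time = numeric(0),
                      start_idx = integer(0), end_idx = integer(0))
  empty$snippet <- list()
  if (length(x) < w) return(empty)
  energy <- as.numeric(stats::filter(x^2, rep(1 / w, w), sides = 2))
  energy_db <- 10 * log10(pmax(energy, .Machine$double.xmin)) + audio$cal_db
  energy_db[is.na(energy)] <- -Inf
  above <- energy_db > config$boundary_threshold_db
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  if (nrow(runs) == 0) return(empty)
  merge_gap <- config$merge_gap_us * 1e-6 * fs
  if (nrow(runs) > 1) {
    keep_start <- runs[1, 1]
    merged <- list()
    cur <- runs[1, ]
    for (k in 2:nrow(runs)) {
      if (runs[k, 1] - cur[2] < merge_gap) {
        cur[2] <- runs[k, 2]
      } else {
        merged[[length(merged) + 1]] <- cur
        cur <- runs[k, ]
      }
    }
    merged[[length(merged) + 1]] <- cur
    runs <- do.call(rbind, merged)
  }
  ctx <- config$context_samples
  n <- length(x)
  snippets <- lapply(seq_len(nrow(runs)), function(k) {
    i0 <- max(1L, runs[k, 1] - ctx)
    i1 <- min(n, runs[k, 2] + ctx)
    x[i0:i1]
  })
  out <- data.frame(
    start_time = audio$start_time + (runs[, 1] - 1) / fs,
    end_time = audio$start_time + (runs[, 2] - 1) / fs,
    start_idx = as.integer(runs[, 1]),
    end_idx = as.integer(runs[, 2])
  )
  out$snippet <- snippets
  out
}

#' Compute the calibrated spectrum of a click snippet
#'
#' The snippet is Hann-weighted and zero-padded to `n_fft` points; the
#' one-sided magnitude spectrum `20*log10|DFT|` is corrected by the
#' calibration offset and the per-frequency transfer function. Snippets
#' longer than `n_fft` are truncated to `n_fft` samples centered on the
#' peak of the Hilbert envelope.
#'
#' @param snippet Numeric waveform (digital units).
#' @param sample_rate Hz.
#' @param cal_db Calibration offset (dB re 1 uPa per digital unit).
#' @param transfer_function Optional two-column (frequency_hz, db) table.
#' @param n_fft DFT length (default 400: 500 Hz/bin at 200 kHz).
#' @return Numeric vector of `n_fft/2` spectral levels (dB re 1 uPa) with
#'   attribute `freq_hz` giving bin center frequencies.
#' @export
compute_click_spectrum <- function(snippet, sample_rate, cal_db = 0,
                                   transfer_function = NULL, n_fft = 400) {
  if (length(snippet) == 0) stop("empty snippet")
  if (length(snippet) > n_fft) {
    env <- hilbert_envelope(snippet)
    pk <- which.max(env)
    i0 <- max(1L, min(pk - n_fft %/% 2, length(snippet) - n_fft + 1L))
    snippet <- snippet[i0:(i0 + n_fft - 1L)]
  }
  L <- length(snippet)
  win <- if (L > 1) 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1))) else 1
  padded <- c(snippet * win, rep(0, n_fft - L))
  mag <- Mod(fft(padded))[seq_len(n_fft %/% 2)]
  freq_hz <- (seq_len(n_fft %/% 2) - 1) * sample_rate / n_fft
  spec <- 20 * log10(pmax(mag, .Machine$double.xmin)) + cal_db +
    tf_correction(transfer_function, freq_hz)
  attr(spec, "freq_hz") <- freq_hz
  spec
}

#' Measure spectra and QC features for detected clicks
#'
#' Computes, per detection: the calibrated spectrum on the standard
#' 10-70 kHz grid, peak frequency over the analysis band, received level
#' (dB peak-to-peak re 1 uPa) and high-energy envelope duration.
#'
#' @param dets Output of [detect_clicks()] (must carry the `snippet` column).
#' @param audio The [audio_segment()] the detections came from (supplies
#'   sample rate, calibration and transfer function).
#' @param config A [detector_config()].
#' @param site_id,deployment_id Identifiers stored with each record.
#' @return A detection table: `detection_id`, `time`, `end_time`,
#'   `peak_khz`, `rl_pp_db`, `env_dur_s`, `site_id`, `deployment_id`, plus
#'   one spectrum column per 10-70 kHz grid bin.
#' @export
measure_clicks <- function(dets, audio, config = detector_config(),
                           site_id = "S1", deployment_id = "D1") {
  stopifnot(inherits(audio, "audio_segment"))
  fs <- audio$sample_rate
  amp <- 10^(audio$cal_db / 20)
  n <- nrow(dets)
  grid_khz <- spectrum_grid_khz()
  specs <- matrix(NA_real_, n, length(grid_khz))
  peak_khz <- rl <- envd <- numeric(n)
  for (k in seq_len(n)) {
    sn <- dets$snippet[[k]]
    spec <- compute_click_spectrum(sn, fs, cal_db = audio$cal_db,
                                   transfer_function = audio$transfer_function,
                                   n_fft = config$n_fft)
    freq_khz <- attr(spec, "freq_hz") / 1000
    in_band <- freq_khz >= config$band_hz[1] / 1000 &
      freq_khz <= config$band_hz[2] / 1000
    peak_khz[k] <- freq_khz[in_band][which.max(spec[in_band])]
    specs[k, ] <- approx(freq_khz, as.numeric(spec), xout = grid_khz,
                         rule = 2)$y
    p <- sn * amp
    rl[k] <- 20 * log10(max(p) - min(p))
    envd[k] <- envelope_duration(sn, fs)
  }
  out <- data.frame(
    detection_id = seq_len(n),
    time = dets$start_time,
    end_time = dets$end_time,
    peak_khz = peak_khz,
    rl_pp_db = rl,
    env_dur_s = envd,
    site_id = rep(site_id, n),
    deployment_id = rep(deployment_id, n),
    stringsAsFactors = FALSE
  )
  specs <- as.data.frame(specs)
  names(specs) <- spec_cols()
  cbind(out, specs)
}

#' Quality-control filter for detected clicks
#'
#' Retains clicks with peak frequency inside `peak_range_khz`, received
#' level above `rl_threshold_dbpp` and envelope duration below
#' `max_envelope_duration`. Order is preserved; the operation is idempotent.
#'
#' @param clicks A detection table (see [measure_clicks()]).
#' @param config A [detector_config()].
#' @return The subset of `clicks` passing all three criteria.
#' @export
qc_filter <- function(clicks, config = detector_config()) {
  if (nrow(clicks) == 0) return(clicks)
  keep <- clicks$peak_khz >= config$peak_range_khz[1] &
    clicks$peak_khz <= config$peak_range_khz[2] &
    clicks$rl_pp_db > config$rl_threshold_dbpp &
    clicks$env_dur_s < config$max_envelope_duration
  clicks[keep, , drop = FALSE]
}
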