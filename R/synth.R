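#' Specify a synthetic click type
#'
#' Parametric description of one click type: a dB spectral template over
#' the 10-70 kHz grid built from a dominant Gaussian peak, optional
#' secondary peaks and notches, and a gentle low-frequency roll-off; plus
#' a modal inter-click interval with jitter and a received-level
#' distribution.
#'
#' @param label Type label.
#' @param peak_khz Dominant peak frequency, kHz (15-85).
#' @param bandwidth_khz Gaussian sigma of the dominant peak, kHz (> 0).
#' @param peak_gain_db Height of the dominant peak above the spectral
#'   floor. Default 25.
#' @param secondary List of secondary features, each
#'   `list(khz=, gain_db=, width_khz=)`; negative `gain_db` carves a notch.
#' @param lowcut_khz Frequencies below this are rolled off (models types
#'   with minimal low-frequency energy); `NULL` for none.
#' @param modal_ici Modal inter-click interval, seconds (0.01-0.5).
#' @param ici_cv Coefficient of variation of the ICI jitter. Default 0.1.
#' @param level_mean_dbpp,level_sd_db Received-level distribution
#'   (dB peak-to-peak re 1 uPa). Defaults 130 and 4.
#' @param spectral_noise_db SD of the correlated per-click spectral
#'   perturbation, dB. Default 2.
#' @param bin_noise_db SD of the correlated per-bin spectral perturbation
#'   shared by all clicks of one bin's train, dB. Default 2.5. This
#'   emulates encounter-level effects (group orientation, range-dependent
#'   attenuation) that do not average out within a bin and give field
#'   summary spectra their bin-to-bin spread.
#' @return A list of class `click_type_spec`.
#' @export
click_type_spec <- function(label, peak_khz, bandwidth_khz = 6,
                            peak_gain_db = 25, secondary = list(),
                            lowcut_khz = NULL, modal_ici = 0.1,
                            ici_cv = 0.1, level_mean_dbpp = 130,
                            level_sd_db = 4, spectral_noise_db = 2,
                            bin_noise_db = 2.5) {
  if (bandwidth_khz <= 0) stop("infeasible template: bandwidth must be positive")
  if (!(peak_khz >= 15 && peak_khz <= 85)) {
    stop("peak frequency must lie in [15, 85] kHz")
  }
  if (!(modal_ici >= 0.01 && modal_ici < 0.5)) {
    stop("modal ICI must lie in [0.01, 0.5) s")
  }
  for (s in secondary) {
    if (s$width_khz <= 0) stop("infeasible template: secondary width must be positive")
  }
  structure(list(label = label, peak_khz = peak_khz,
                 bandwidth_khz = bandwidth_khz, peak_gain_db = peak_gain_db,
                 secondary = secondary, lowcut_khz = lowcut_khz,
                 modal_ici = modal_ici, ici_cv = ici_cv,
                 level_mean_dbpp = level_mean_dbpp,
                 level_sd_db = level_sd_db,
                 spectral_noise_db = spectral_noise_db,
                 bin_noise_db = bin_noise_db),
            class = "click_type_spec")
}

#' Spectral template of a click type (dB, 10-70 kHz grid)
#'
#' @param spec A [click_type_spec()].
#' @return Numeric vector of relative dB levels on [spectrum_grid_khz()].
#' @export
type_template_db <- function(spec) {
  f <- spectrum_grid_khz()
  shape <- spec$peak_gain_db *
    exp(-(f - spec$peak_khz)^2 / (2 * spec$bandwidth_khz^2))
  for (s in spec$secondary) {
    shape <- shape + s$gain_db * exp(-(f - s$khz)^2 / (2 * s$width_khz^2))
  }
  if (!is.null(spec$lowcut_khz)) {
    shape <- shape - 20 * pmax(0, spec$lowcut_khz - f) / spec$lowcut_khz * 2
  }
  # mild broadband tilt: high frequencies attenuate in seawater
  shape - 0.08 * (f - 10)
}

#' Synthetic presets for seven delphinid click types
#'
#' Returns seven `click_type_spec` presets spanning the peak-frequency
#' (22-42 kHz) and modal-ICI (0.035-0.165 s) ranges reported for Gulf of
#' Mexico delphinid click types, with the qualitative spectral features
#' that distinguish them in field data: a narrow low-frequency side peak
#' (type A), the multi-peaked banded structure characteristic of Risso's
#' dolphin (type B), low-frequency concentrated energy (type C), paired
#' low-frequency peaks beneath a high dominant band (type D), a clean
#' mid-band peak with suppressed low frequencies (type E), a similar peak
#' with minor 16/20 kHz side structure (type F), and a single broad
#' high-energy band (type G). These are synthetic stand-ins for trained
#' field templates, intended for ground-truthed pipeline validation.
#'
#' @return Named list of seven [click_type_spec()] objects.
#' @export
gom_click_types <- function() {
  list(
    A = click_type_spec("A", peak_khz = 27, bandwidth_khz = 5,
      secondary = list(list(khz = 12, gain_db = 10, width_khz = 1.2)),
      modal_ici = 0.155),
    B = click_type_spec("B", peak_khz = 33, bandwidth_khz = 3,
      secondary = list(list(khz = 22, gain_db = 16, width_khz = 1.3),
                       list(khz = 26, gain_db = 19, width_khz = 1.3)),
      modal_ici = 0.125),
    C = click_type_spec("C", peak_khz = 22, bandwidth_khz = 4.5,
      modal_ici = 0.165),
    D = click_type_spec("D", peak_khz = 42, bandwidth_khz = 6,
      secondary = list(list(khz = 12, gain_db = 9, width_khz = 1.2),
                       list(khz = 18, gain_db = 11, width_khz = 1.4)),
      modal_ici = 0.035),
    E = click_type_spec("E", peak_khz = 32.5, bandwidth_khz = 4.5,
      lowcut_khz = 20, modal_ici = 0.065),
    F = click_type_spec("F", peak_khz = 29.5, bandwidth_khz = 7,
      secondary = list(list(khz = 20, gain_db = 13, width_khz = 1.8),
                       list(khz = 16, gain_db = 8, width_khz = 1.2)),
      modal_ici = 0.065),
    G = click_type_spec("G", peak_khz = 36.5, bandwidth_khz = 8,
      secondary = list(list(khz = 25, gain_db = 21, width_khz = 4),
                       list(khz = 48, gain_db = 18, width_khz = 4)),
      modal_ici = 0.035)
  )
}

#' Synthesize one click waveform
#'
#' Gaussian-enveloped cosine (tone burst) at the type's dominant peak
#' frequency, plus one tone burst per secondary peak, scaled to a target
#' calibrated peak-to-peak received level. The burst is shorter than 400
#' samples at 200 kHz, consistent with the impulsive-click assumptions of
#' the detector.
#'
#' @param spec A [click_type_spec()].
#' @param sample_rate Hz. Default 200 kHz.
#' @param cal_db Calibration offset the waveform will be interpreted
#'   under (digital amplitude -> dB re 1 uPa).
#' @param level_dbpp Target received level (dB pp re 1 uPa); `NULL` draws
#'   from the spec's level distribution.
#' @param jitter Apply within-type spectral jitter to component
#'   amplitudes (disable for deterministic output).
#' @return Numeric waveform (digital units) of odd length < 400.
#' @export
synth_click_waveform <- function(spec, sample_rate = 200e3, cal_db = 0,
                                 level_dbpp = NULL, jitter = TRUE) {
  sigma_t <- 1 / (2 * pi * spec$bandwidth_khz * 1000)
  half <- min(180L, max(30L, ceiling(4 * sigma_t * sample_rate)))
  t <- (-half:half) / sample_rate
  x <- exp(-t^2 / (2 * sigma_t^2)) * cos(2 * pi * spec$peak_khz * 1000 * t)
  for (s in spec$secondary) {
    if (s$gain_db <= 0) next  # notches are spectral-domain features
    rel <- 10^((s$gain_db - spec$peak_gain_db) / 20)
    if (jitter) rel <- rel * 10^(rnorm(1, 0, spec$spectral_noise_db) / 20)
    st <- 1 / (2 * pi * s$width_khz * 1000)
    st <- min(st, half / sample_rate / 3)
    x <- x + rel * exp(-t^2 / (2 * st^2)) * cos(2 * pi * s$khz * 1000 * t)
  }
  if (is.null(level_dbpp)) {
    level_dbpp <- rnorm(1, spec$level_mean_dbpp, spec$level_sd_db)
  }
  target_pp <- 10^((level_dbpp - cal_db) / 20)
  x * target_pp / (max(x) - min(x))
}

#' Synthesize a calibrated audio scene with ground truth
#'
#' Places jittered click trains for each supplied type on a Gaussian
#' noise background, optionally adds snapping-shrimp-like false-positive
#' transients (very short impulses with energy concentrated above
#' 70 kHz), and returns the audio together with a truth table of every
#' planted signal.
#'
#' @param specs List of [click_type_spec()] (one click train per spec).
#' @param duration Seconds. Default 10 (a full five-minute bin at 200 kHz
#'   is 60 million samples; shorter scenes are ample for detector
#'   validation).
#' @param sample_rate Hz. Default 200 kHz.
#' @param cal_db Calibration offset carried by the audio. Default 50.
#' @param noise_floor_db Broadband noise level such that the smoothed
#'   energy trace sits near this calibrated level (dB re 1 uPa). Default
#'   75.
#' @param shrimp_rate False-positive transients per second. Default 0.
#' @param start_time Absolute start time (epoch seconds).
#' @return List: `audio` (an [audio_segment()]) and `truth` (data.frame
#'   `time`, `type`, `level_dbpp`; shrimp transients have type
#'   `"shrimp"`).
#' @export
synth_audio_bin <- function(specs, duration = 10, sample_rate = 200e3,
                            cal_db = 50, noise_floor_db = 75,
                            shrimp_rate = 0, start_time = 0) {
  n <- round(duration * sample_rate)
  noise_sd <- 10^((noise_floor_db - cal_db) / 20)
  x <- rnorm(n, 0, noise_sd)
  truth <- list()
  place <- function(x, wf, at_idx) {
    half <- (length(wf) - 1) %/% 2
    i0 <- at_idx - half
    i1 <- at_idx + half
    w0 <- max(1L, i0)
    w1 <- min(n, i1)
    if (w1 < w0) return(x)
    x[w0:w1] <- x[w0:w1] + wf[(w0 - i0 + 1):(w1 - i0 + 1)]
    x
  }
  for (spec in specs) {
    t0 <- runif(1, 0.05, max(0.06, min(1, duration / 10)))
    tt <- t0
    while (tt < duration - 0.05) {
      lvl <- rnorm(1, spec$level_mean_dbpp, spec$level_sd_db)
      wf <- synth_click_waveform(spec, sample_rate, cal_db, level_dbpp = lvl)
      idx <- round(tt * sample_rate) + 1L
      x <- place(x, wf, idx)
      truth[[length(truth) + 1]] <-
        data.frame(time = start_time + tt, type = spec$label,
                   level_dbpp = lvl)
      tt <- tt + max(0.011, rnorm(1, spec$modal_ici,
                                  spec$ici_cv * spec$modal_ici))
    }
  }
  if (shrimp_rate > 0) {
    n_shrimp <- max(0L, round(shrimp_rate * duration))
    shrimp_t <- sort(runif(n_shrimp, 0.01, duration - 0.01))
    for (tt in shrimp_t) {
      # < 50 us transient with energy concentrated above the 70 kHz
      # band edge, so the in-band spectral peak falls above 85 kHz
      st <- 15e-6
      half <- ceiling(4 * st * sample_rate)
      tvec <- (-half:half) / sample_rate
      lvl <- rnorm(1, 135, 4)
      wf <- exp(-tvec^2 / (2 * st^2)) * cos(2 * pi * 93e3 * tvec)
      wf <- wf * 10^((lvl - cal_db) / 20) / (max(wf) - min(wf))
      x <- place(x, wf, round(tt * sample_rate) + 1L)
      truth[[length(truth) + 1]] <-
        data.frame(time = start_time + tt, type = "shrimp", level_dbpp = lvl)
    }
  }
  truth <- if (length(truth) > 0) {
    tr <- do.call(rbind, truth)
    tr[order(tr$time), , drop = FALSE]
  } else {
    data.frame(time = numeric(0), type = character(0),
               level_dbpp = numeric(0))
  }
  rownames(truth) <- NULL
  list(audio = audio_segment(x, sample_rate, start_time = start_time,
                             cal_db = cal_db),
       truth = truth)
}

#' Specify a synthetic detection-level dataset
#'
#' @param types List of [click_type_spec()] (e.g. [gom_click_types()]).
#' @param sites Site identifiers. Default `c("MC","GC","DT","DC","MP")`,
#'   the five-site monitoring layout the generator emulates.
#' @param bins_per_type_per_site Five-minute bins generated per type per
#'   site. Default 10.
#' @param clicks_per_bin Range (min, max) of clicks per bin. Default
#'   `c(150, 400)`.
#' @param mixture_fraction Fraction of bins containing two types (half
#'   the clicks each). Default 0.
#' @param rng_seed Seed; all output is fully determined by it.
#' @return A list of class `synthetic_dataset_spec`.
#' @export
synthetic_dataset_spec <- function(types = gom_click_types(),
                                   sites = c("MC", "GC", "DT", "DC", "MP"),
                                   bins_per_type_per_site = 10,
                                   clicks_per_bin = c(150, 400),
                                   mixture_fraction = 0,
                                   rng_seed = 1) {
  stopifnot(length(types) >= 1, length(sites) >= 1,
            clicks_per_bin[1] >= 2, clicks_per_bin[2] >= clicks_per_bin[1],
            mixture_fraction >= 0, mixture_fraction <= 1)
  structure(list(types = types, sites = sites,
                 bins_per_type_per_site = bins_per_type_per_site,
                 clicks_per_bin = clicks_per_bin,
                 mixture_fraction = mixture_fraction,
                 rng_seed = rng_seed),
            class = "synthetic_dataset_spec")
}

# Spectrally smooth perturbation draw (dB) on the grid: Gaussian knots
# every 6 kHz, linearly interpolated.
smooth_noise_draw <- function(sd_db) {
  f <- spectrum_grid_khz()
  knots <- seq(10, 70, by = 6)
  approx(knots, rnorm(length(knots), 0, sd_db), xout = f)$y
}

# Per-click perturbation: smooth component plus white per-bin noise (the
# white part averages out in bin mean spectra, as it does in field data).
spectral_noise_draw <- function(sd_db) {
  smooth_noise_draw(sd_db) + rnorm(length(SPEC_GRID_KHZ), 0, sd_db / 2)
}

# Click times for one bin: a single jittered train, wrapping to a new
# offset if it outruns the bin.
synth_train_times <- function(spec, n, bin_start, bin_s = 300) {
  times <- numeric(n)
  tt <- runif(1, 0, 2)
  for (k in seq_len(n)) {
    if (tt >= bin_s - 0.01) tt <- runif(1, 0, 1)
    times[k] <- tt
    tt <- tt + max(0.011, rnorm(1, spec$modal_ici,
                                spec$ici_cv * spec$modal_ici))
  }
  bin_start + sort(times)
}

#' Generate a ground-truthed detection-level dataset
#'
#' Emits click-level spectra (type template + correlated within-type
#' noise), timestamps forming jittered click trains at each type's modal
#' ICI, and per-click / per-bin truth labels - without audio synthesis,
#' so datasets of 10^4-10^5 clicks generate in seconds. This is the
#' primary test path for the clustering and classification stages.
#'
#' @param spec A [synthetic_dataset_spec()].
#' @return List: `detections` (a detection table as produced by
#'   [measure_clicks()]), `truth_clicks` (`detection_id`, `true_type`),
#'   `truth_bins` (`site_id`, `bin_start`, `types`).
#' @export
synth_detection_dataset <- function(spec = synthetic_dataset_spec()) {
  stopifnot(inherits(spec, "synthetic_dataset_spec"))
  with_seed(spec$rng_seed, {
    grid <- spectrum_grid_khz()
    templates <- lapply(spec$types, type_template_db)
    type_labels <- unname(vapply(spec$types, `[[`, "", "label"))
    day0 <- 1600000200  # arbitrary epoch origin, aligned to 300 s bins
    rows <- list()
    bin_rows <- list()
    bin_counter <- 0
    for (si in seq_along(spec$sites)) {
      site <- spec$sites[si]
      # interleave types across consecutive bins within the site
      layout <- rep(seq_along(spec$types),
                    each = spec$bins_per_type_per_site)
      for (bi in seq_along(layout)) {
        ti <- layout[bi]
        bin_counter <- bin_counter + 1
        bin_start <- day0 + (bin_counter - 1) * 300
        cr <- spec$clicks_per_bin
        n <- if (cr[1] == cr[2]) cr[1] else {
          sample(seq(cr[1], cr[2]), 1)
        }
        mix <- runif(1) < spec$mixture_fraction && length(spec$types) > 1
        parts <- if (mix) {
          others <- setdiff(seq_along(spec$types), ti)
          other <- if (length(others) == 1) others else sample(others, 1)
          list(list(ti = ti, n = ceiling(n / 2)),
               list(ti = other, n = floor(n / 2)))
        } else {
          list(list(ti = ti, n = n))
        }
        for (p in parts) {
          tspec <- spec$types[[p$ti]]
          times <- synth_train_times(tspec, p$n, bin_start)
          base <- templates[[p$ti]] +
            smooth_noise_draw(tspec$bin_noise_db)
          specs <- t(vapply(seq_len(p$n), function(k) {
            base + spectral_noise_draw(tspec$spectral_noise_db)
          }, numeric(length(grid))))
          rl <- rnorm(p$n, tspec$level_mean_dbpp, tspec$level_sd_db)
          df <- data.frame(
            time = times,
            end_time = times + 1e-4,
            peak_khz = grid[max.col(specs)],
            rl_pp_db = rl,
            env_dur_s = 5e-5,
            site_id = site,
            deployment_id = paste0(site, "01"),
            true_type = type_labels[p$ti],
            stringsAsFactors = FALSE
          )
          df[spec_cols()] <- as.data.frame(specs + rl - max(base))
          rows[[length(rows) + 1]] <- df
        }
        bin_rows[[length(bin_rows) + 1]] <- data.frame(
          site_id = site, bin_start = bin_start,
          types = paste(type_labels[vapply(parts, `[[`, 0L, "ti")],
                        collapse = "+"),
          stringsAsFactors = FALSE)
      }
    }
    det <- do.call(rbind, rows)
    det <- det[order(det$time), , drop = FALSE]
    det$detection_id <- seq_len(nrow(det))
    truth_clicks <- det[, c("detection_id", "true_type")]
    det$true_type <- NULL
    det <- det[, c("detection_id",
                   setdiff(names(det), "detection_id")), drop = FALSE]
    rownames(det) <- rownames(truth_clicks) <- NULL
    list(detections = det, truth_clicks = truth_clicks,
         truth_bins = do.call(rbind, bin_rows))
  })
}
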