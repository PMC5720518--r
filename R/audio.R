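#' Construct a calibrated audio segment
#'
#' Container for single-channel wideband audio. Calibration maps digital
#' amplitude to absolute sound pressure: a sample of digital amplitude `x`
#' corresponds to a level of `20*log10(|x|) + cal_db` dB re 1 uPa. An
#' optional transfer function supplies a per-frequency correction (dB added
#' to computed spectra).
#'
#' @param samples Numeric vector, finite, single channel.
#' @param sample_rate Sampling rate in Hz. Spectral analysis up to 90 kHz
#'   requires at least 180 kHz; the nominal rate is 200 kHz.
#' @param start_time Absolute start time, seconds since epoch (UTC) or
#'   `POSIXct`.
#' @param cal_db Calibration offset in dB mapping digital amplitude to
#'   dB re 1 uPa.
#' @param transfer_function Optional two-column matrix/data.frame
#'   (`frequency_hz`, `db`) of per-frequency corrections; must cover the
#'   10-90 kHz analysis band when supplied.
#' @return An object of class `audio_segment`.
#' @export
audio_segment <- function(samples, sample_rate, start_time = 0, cal_db = 0,
                          transfer_function = NULL) {
  if (!is.numeric(samples) || anyNA(samples) || any(!is.finite(samples))) {
    stop("samples must be finite numeric values")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    stop("sample_rate must be a positive scalar (Hz)")
  }
  if (inherits(start_time, "POSIXct")) start_time <- as.numeric(start_time)
  tf <- NULL
  if (!is.null(transfer_function)) {
    tf <- as.data.frame(transfer_function)
    if (ncol(tf) < 2) stop("transfer_function needs columns frequency_hz, db")
    names(tf)[1:2] <- c("frequency_hz", "db")
    tf <- tf[order(tf$frequency_hz), 1:2]
  }
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         start_time = start_time, cal_db = cal_db, transfer_function = tf),
    class = "audio_segment"
  )
}

#' @export
print.audio_segment <- function(x, ...) {
  cat(sprintf("<audio_segment> %d samples @ %g kHz (%.3f s), cal %.1f dB%s\n",
              length(x$samples), x$sample_rate / 1000,
              length(x$samples) / x$sample_rate, x$cal_db,
              if (is.null(x$transfer_function)) "" else ", transfer function"))
  invisible(x)
}

#' @export
length.audio_segment <- function(x) length(x$samples)

# Evaluate the transfer function (dB correction) at frequencies in Hz.
# Linear interpolation, flat extrapolation at the ends; zero when absent.
tf_correction <- function(audio_or_tf, freq_hz) {
  tf <- if (inherits(audio_or_tf, "audio_segment")) {
    audio_or_tf$transfer_function
  } else {
    audio_or_tf
  }
  if (is.null(tf)) return(rep(0, length(freq_hz)))
  tf <- as.data.frame(tf)
  approx(tf[[1]], tf[[2]], xout = freq_hz, rule = 2)$y
}

#' Read a single-channel WAV file
#'
#' Minimal RIFF/WAVE reader supporting single-channel PCM (16- or 24-bit)
#' and IEEE float (32-bit) encodings. Integer samples are scaled to
#' \[-1, 1) by the full-scale value of the encoding.
#'
#' @param path Path to a `.wav` file.
#' @param start_time,cal_db,transfer_function Passed to [audio_segment()].
#' @return An [audio_segment()].
#' @export
read_wav <- function(path, start_time = 0, cal_db = 0, transfer_function = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      )
      extra <- size - 16
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      if (fmt$channels != 1) {
        stop("unsupported WAV: ", fmt$channels, " channels (single channel required)")
      }
      if (fmt$format == 1 && fmt$bits == 16) {
        n <- size %/% 2
        raw <- readBin(con, "integer", n, 2, signed = TRUE, endian = "little")
        samples <- raw / 32768
      } else if (fmt$format == 1 && fmt$bits == 24) {
        bytes <- readBin(con, "raw", size)
        n <- length(bytes) %/% 3
        b <- matrix(as.integer(bytes[seq_len(n * 3)]), nrow = 3)
        v <- b[1, ] + b[2, ] * 256L + b[3, ] * 65536L
        v <- ifelse(v >= 8388608, v - 16777216, v)
        samples <- v / 8388608
      } else if (fmt$format == 3 && fmt$bits == 32) {
        n <- size %/% 4
        samples <- readBin(con, "numeric", n, 4, endian = "little")
      } else {
        stop("unsupported WAV encoding: format ", fmt$format, ", ",
             fmt$bits, " bits")
      }
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  audio_segment(samples, fmt$sample_rate, start_time = start_time,
                cal_db = cal_db, transfer_function = transfer_function)
}

#' Write a single-channel WAV file
#'
#' @param audio An [audio_segment()] (or numeric vector with `sample_rate`).
#' @param path Output path.
#' @param bits Encoding: 16 (PCM) or 32 (IEEE float).
#' @param sample_rate Required when `audio` is a bare numeric vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path, bits = 16, sample_rate = NULL) {
  if (inherits(audio, "audio_segment")) {
    samples <- audio$samples
    sample_rate <- audio$sample_rate
  } else {
    samples <- as.numeric(audio)
    if (is.null(sample_rate)) stop("sample_rate required for bare vectors")
  }
  if (!bits %in% c(16, 32)) stop("bits must be 16 (PCM) or 32 (float)")
  n <- length(samples)
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(as.integer(if (bits == 16) 1 else 3), con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(sample_rate), con, 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16) {
    v <- as.integer(round(pmax(pmin(samples, 32767 / 32768), -1) * 32768))
    writeBin(v, con, 2, endian = "little")
  } else {
    writeBin(samples, con, 4, endian = "little")
  }
  invisible(path)
}

#' Read audio with its calibration sidecar
#'
#' Loads a WAV file together with a plain-text calibration sidecar. The
#' sidecar (default: the WAV path with extension `.cal`) contains a line
#' `calibration_db <value>` and, optionally, subsequent two-column lines
#' `<frequency_hz> <db>` giving the hydrophone transfer-function correction
#' curve. Lines starting with `#` are ignored.
#'
#' @param path Path to a single-channel WAV file.
#' @param cal_path Path to the calibration sidecar; defaults to `path` with
#'   a `.cal` extension.
#' @param start_time Absolute start time of the recording (seconds or POSIXct).
#' @return An [audio_segment()] carrying calibration and transfer function.
#' @export
read_audio <- function(path, cal_path = NULL, start_time = 0) {
  if (is.null(cal_path)) cal_path <- sub("\\.wav$", ".cal", path, ignore.case = TRUE)
  if (!file.exists(cal_path)) {
    stop("missing calibration sidecar for ", path, " (expected ", cal_path, ")")
  }
  lines <- readLines(cal_path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cal_line <- grep("^calibration_db\\b", lines, value = TRUE)
  if (length(cal_line) != 1) {
    stop("calibration sidecar ", cal_path, " must contain one 'calibration_db' line")
  }
  cal_db <- as.numeric(strsplit(cal_line, "[[:space:]]+")[[1]][2])
  tf_lines <- lines[!startsWith(lines, "calibration_db")]
  tf <- NULL
  if (length(tf_lines) > 0) {
    parts <- do.call(rbind, lapply(strsplit(tf_lines, "[[:space:]]+"), function(p) {
      as.numeric(p[1:2])
    }))
    tf <- data.frame(frequency_hz = parts[, 1], db = parts[, 2])
  }
  read_wav(path, start_time = start_time, cal_db = cal_db,
           transfer_function = tf)
}

#' Write a calibration sidecar file
#'
#' @param path Output path (conventionally the WAV path with `.cal`).
#' @param cal_db Calibration offset in dB.
#' @param transfer_function Optional two-column (frequency_hz, db) table.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(path, cal_db, transfer_function = NULL) {
  lines <- c("# clicknet calibration sidecar v1",
             sprintf("calibration_db %.6g", cal_db))
  if (!is.null(transfer_function)) {
    tf <- as.data.frame(transfer_function)
    lines <- c(lines, sprintf("%.6g %.6g", tf[[1]], tf[[2]]))
  }
  writeLines(lines, path)
  invisible(path)
}
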