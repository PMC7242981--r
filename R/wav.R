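# Minimal RIFF/WAVE I/O for mono stimuli.
#
# Supports the formats used for speech stimuli in the lab: PCM 16- and
# 24-bit integer and IEEE 32-bit float, single channel. Samples are scaled
# to [-1, 1] on read.

#' Audio signal container
#'
#' A mono audio signal: a finite real sample vector plus its sample rate.
#'
#' @param samples numeric vector of dimensionless amplitudes.
#' @param rate sample rate in Hz.
#' @return object of class `audio_signal` with elements `samples` and `rate`.
#' @export
#' @examples
#' audio_signal(sin(2 * pi * 440 * seq(0, 0.1, by = 1/8000)), 8000)
audio_signal <- function(samples, rate) {
  if (!is.numeric(samples) || any(!is.finite(samples))) {
    stop_domain("samples must be finite numeric values")
  }
  if (!is_scalar_num(rate) || rate <= 0) stop_domain("rate must be positive")
  structure(list(samples = as.numeric(samples), rate = rate),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("audio_signal: %d samples @ %g Hz (%.3f s), peak %.3f\n",
              length(x$samples), x$rate, length(x$samples) / x$rate,
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' Read a mono WAV file
#'
#' @param path path to a RIFF/WAVE file, mono, PCM 16/24-bit or 32-bit float.
#' @return an [audio_signal()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_domain("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")  # total size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop_domain("not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        format = readBin(raw[1:2], "integer", 1, 2, endian = "little",
                         signed = FALSE),
        channels = readBin(raw[3:4], "integer", 1, 2, endian = "little",
                           signed = FALSE),
        rate = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little",
                       signed = FALSE))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size)
    }
    if (size %% 2 == 1) readBin(con, "raw", 1)  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop_domain("missing fmt or data chunk in ", path)
  }
  if (fmt$channels != 1) stop_domain("only mono WAV is supported")
  samples <- switch(as.character(fmt$bits),
    "16" = readBin(data_raw, "integer", length(data_raw) %/% 2, 2,
                   signed = TRUE, endian = "little") / 32768,
    "24" = {
      n <- length(data_raw) %/% 3
      b <- matrix(as.integer(data_raw[seq_len(3 * n)]), nrow = 3)
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    "32" = {
      if (fmt$format != 3) stop_domain("32-bit WAV must be IEEE float")
      readBin(data_raw, "double", length(data_raw) %/% 4, 4,
              endian = "little")
    },
    stop_domain("unsupported bit depth: ", fmt$bits))
  audio_signal(samples, fmt$rate)
}

#' Write a mono WAV file
#'
#' @param signal an [audio_signal()].
#' @param path output file path.
#' @param bits 16 or 24 (PCM integer) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, bits = 16) {
  stopifnot(inherits(signal, "audio_signal"))
  bits <- as.integer(bits)
  if (!bits %in% c(16L, 24L, 32L)) stop_domain("bits must be 16, 24 or 32")
  x <- signal$samples
  n <- length(x)
  bytes_per <- bits %/% 8L
  data_size <- n * bytes_per
  fmt_code <- if (bits == 32L) 3L else 1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(signal$rate), con, 4, endian = "little")
  writeBin(as.integer(signal$rate * bytes_per), con, 4, endian = "little")
  writeBin(bytes_per, con, 2, endian = "little")
  writeBin(bits, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16L) {
    v <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
    writeBin(v, con, 2, endian = "little")
  } else if (bits == 24L) {
    v <- pmax(-8388608, pmin(8388607, round(x * 8388608)))
    v <- ifelse(v < 0, v + 16777216, v)
    b <- rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256)
    writeBin(as.raw(as.vector(b)), con)
  } else {
    writeBin(x, con, 4, endian = "little")
  }
  invisible(path)
}
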