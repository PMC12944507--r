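#' Read a mono RIFF WAV file
#'
#' Minimal reader for the formats the package writes: uncompressed PCM
#' (8/16/24/32 bit integer) and IEEE float32/float64, single channel.
#'
#' @param path file path.
#' @return a list with `samples` (numeric vector, float data as stored,
#'   integer PCM rescaled to `[-1, 1)`), `fs` (sampling rate, Hz),
#'   `bits` and `format` (`"pcm"` or `"float"`).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stopf("not a RIFF file: %s", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stopf("not a WAVE file: %s", path)

  fmt <- NULL
  samples <- NULL
  repeat {
    id_raw <- readBin(con, "raw", 4)
    if (length(id_raw) < 4) break
    id <- rawToChar(id_raw)
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      audio_format <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      n_channels <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      fs <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))  # byte rate
      invisible(readBin(con, "integer", 1, 2, endian = "little"))  # block align
      bits <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      if (size > 16) invisible(readBin(con, "raw", size - 16))
      fmt <- list(format = audio_format, channels = n_channels, fs = fs, bits = bits)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stopf("malformed WAV: data chunk before fmt chunk")
      if (fmt$channels != 1L) stopf("only mono WAV supported (got %d channels)", fmt$channels)
      bytes <- fmt$bits / 8
      n <- size / bytes
      if (fmt$format == 3L) {
        samples <- readBin(con, "double", n, bytes, endian = "little")
      } else if (fmt$format == 1L) {
        if (fmt$bits == 8) {
          raw8 <- readBin(con, "integer", n, 1, signed = FALSE)
          samples <- (raw8 - 128) / 128
        } else if (fmt$bits == 16) {
          samples <- readBin(con, "integer", n, 2, endian = "little") / 32768
        } else if (fmt$bits == 24) {
          raw <- readBin(con, "raw", size)
          b <- matrix(as.integer(raw), nrow = 3)
          v <- b[1, ] + b[2, ] * 256L + b[3, ] * 65536L
          v <- ifelse(v >= 8388608, v - 16777216, v)
          samples <- v / 8388608
        } else if (fmt$bits == 32) {
          samples <- readBin(con, "integer", n, 4, endian = "little") / 2147483648
        } else stopf("unsupported PCM bit depth: %d", fmt$bits)
      } else stopf("unsupported WAV format code: %d", fmt$format)
      if (size %% 2 == 1) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(samples)) stopf("no data chunk found in %s", path)
  list(samples = samples, fs = fmt$fs, bits = fmt$bits,
       format = if (fmt$format == 3L) "float" else "pcm")
}

#' Write a mono WAV file
#'
#' @param samples numeric vector.
#' @param fs sampling rate in Hz.
#' @param path output path.
#' @param bits 16 (integer PCM, clipped to `[-1, 1)`) or 32 (IEEE float,
#'   lossless round-trip; the default).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, fs, path, bits = 32L) {
  stopifnot(bits %in% c(16L, 32L))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  bytes <- bits / 8
  data_size <- n * bytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(if (bits == 32L) 3L else 1L, con, 2, endian = "little")  # float / PCM
  writeBin(1L, con, 2, endian = "little")                            # mono
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * bytes), con, 4, endian = "little")
  writeBin(as.integer(bytes), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 32L) {
    writeBin(samples, con, 4, endian = "little")
  } else {
    x <- pmin(pmax(samples, -1), 32767 / 32768)
    writeBin(as.integer(round(x * 32768)), con, 2, endian = "little")
  }
  invisible(path)
}
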