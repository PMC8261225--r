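# Minimal RIFF/WAVE (16-bit PCM, mono) reader and writer.  Stimuli are
# written at a common RMS well below full scale, so 16-bit quantisation is
# ample for playback and for all acoustic measurements in this package.

#' Write a mono waveform to a 16-bit PCM WAV file
#'
#' @param wave Numeric vector in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, sample_rate, path) {
  stopifnot(is.numeric(wave), length(wave) > 0, sample_rate > 0)
  if (max(abs(wave)) > 1 + 1e-9) stop("waveform exceeds [-1, 1]; normalize first")
  pcm <- as.integer(round(pmax(-1, pmin(1, wave)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")           # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate) * 2L, con, size = 4, endian = "little") # byte rate
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path File path.
#' @return A list with `wave` (numeric in `[-1, 1]`) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) stop("only mono PCM supported")
      sample_rate <- readBin(con, "integer", size = 4, endian = "little")
      invisible(readBin(con, "integer", size = 4, endian = "little"))
      ba <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (ba[2] != 16L) stop("only 16-bit PCM supported")
      if (size > 16) invisible(readBin(con, "raw", n = size - 16L))
    } else if (id == "data") {
      pcm <- readBin(con, "integer", n = size / 2L, size = 2,
                     signed = TRUE, endian = "little")
      return(list(wave = pcm / 32767, sample_rate = sample_rate))
    } else {
      invisible(readBin(con, "raw", n = size))
    }
  }
}
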