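#' Write a mono waveform to a PCM16 WAV file
#'
#' Minimal RIFF/WAVE writer for single-channel 16-bit PCM audio. Samples are
#' expected in `[-1, 1]` and are clipped before quantization.
#'
#' @param x Numeric vector of samples in `[-1, 1]`.
#' @param fs Sample rate in Hz.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_wav()]
#' @export
write_wav <- function(x, fs, path) {
  stopifnot(is.numeric(x), length(x) >= 1, fs > 0)
  pcm <- as.integer(round(pmax(-1, pmin(1, x)) * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + n_bytes, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono PCM16 WAV file
#'
#' @param path WAV file path (mono, 16-bit PCM).
#' @return A list with elements `x` (samples in `[-1, 1]`) and `fs` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file: ", path)
  fs <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) stop("only mono PCM supported")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      ba <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (ba[2] != 16L) stop("only 16-bit PCM supported")
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", sz / 2, size = 2, endian = "little",
                     signed = TRUE)
      if (is.null(fs)) stop("data chunk before fmt chunk")
      return(list(x = pcm / 32767, fs = fs))
    } else {
      readBin(con, "raw", sz)
    }
  }
}
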