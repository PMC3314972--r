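## Minimal mono RIFF/WAVE I/O (PCM 16-bit and IEEE float32). The package
## only ever deals with mono signals, so multi-channel files are refused.

#' Write a mono signal to a WAV file
#'
#' @param x Numeric vector, nominally in `[-1, 1]`.
#' @param path Output file path.
#' @param sample_rate Sample rate in Hz.
#' @param bits Either `16` (PCM) or `32` (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, sample_rate, bits = 16L) {
  stopifnot(is.numeric(x), sample_rate > 0, bits %in% c(16L, 32L))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(x)
  bytes_per <- bits / 8L
  data_size <- n * bytes_per
  fmt_code <- if (bits == 16L) 1L else 3L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16L) {
    q <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(as.double(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' @param path WAV file path.
#' @return A list with elements `signal` (numeric vector scaled to
#'   `[-1, 1]` for PCM input) and `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) abort("not a RIFF/WAVE file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) abort("not a RIFF/WAVE file")
  fmt_code <- NA_integer_; n_chan <- NA_integer_
  sample_rate <- NA_integer_; bits <- NA_integer_
  signal <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_code <- readBin(con, integer(), size = 2, endian = "little")
      n_chan <- readBin(con, integer(), size = 2, endian = "little")
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      extra <- size - 16L
      if (extra > 0) invisible(readBin(con, raw(), n = extra))
    } else if (identical(id, "data")) {
      if (n_chan != 1L) abort("only mono WAV files are supported")
      if (fmt_code == 1L && bits == 16L) {
        signal <- readBin(con, integer(), n = size / 2L, size = 2,
                          signed = TRUE, endian = "little") / 32767
      } else if (fmt_code == 3L && bits == 32L) {
        signal <- readBin(con, double(), n = size / 4L, size = 4,
                          endian = "little")
      } else {
        abort("unsupported WAV encoding (need PCM16 or float32)")
      }
      break
    } else {
      invisible(readBin(con, raw(), n = size))
    }
  }
  if (is.null(signal)) abort("no data chunk found in WAV file")
  list(signal = signal, sample_rate = sample_rate)
}
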