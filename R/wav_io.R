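# Minimal mono RIFF/WAVE I/O: 16-bit PCM (format 1) and 32-bit IEEE float
# (format 3). Covers exactly what the stimulus bank and trace fixtures need.

#' Write a mono WAV file
#'
#' @param samples Numeric vector in [-1, 1] (clipped for PCM).
#' @param fs Sampling rate in Hz.
#' @param path Output file path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return Invisibly, `path`.
#' @export
write_wav <- function(samples, fs, path, bits = 16) {
  if (!bits %in% c(16L, 32L)) stop("bits must be 16 (PCM) or 32 (float)")
  fs <- as.integer(round(fs))
  n <- length(samples)
  bytes_per_sample <- bits / 8L
  data_size <- n * bytes_per_sample
  fmt_code <- if (bits == 16L) 1L else 3L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes_per_sample), con, size = 4,
           endian = "little")                              # byte rate
  writeBin(as.integer(bytes_per_sample), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16L) {
    x <- pmin(pmax(samples, -1), 1)
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' @param path File path.
#' @return List with `samples` (numeric, PCM rescaled to [-1, 1]), `fs`,
#'   and `bits`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop(sprintf("'%s' is not a RIFF file", path))
  readBin(con, "integer", size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop(sprintf("'%s' is not a WAVE file", path))
  fmt_code <- NA_integer_; fs <- NA_integer_; bits <- NA_integer_
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, "integer", size = 2, endian = "little")
      n_chan <- readBin(con, "integer", size = 2, endian = "little")
      if (n_chan != 1L) stop("only mono WAV files are supported")
      fs <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      extra <- size - 16L
      if (extra > 0) readBin(con, "raw", n = extra)
    } else if (id == "data") {
      if (fmt_code == 1L && bits == 16L) {
        samples <- readBin(con, "integer", n = size / 2, size = 2,
                           signed = TRUE, endian = "little") / 32767
      } else if (fmt_code == 3L && bits == 32L) {
        samples <- readBin(con, "numeric", n = size / 4, size = 4,
                           endian = "little")
      } else {
        stop(sprintf("unsupported WAV format (code %d, %d bits)",
                     fmt_code, bits))
      }
      break
    } else {
      readBin(con, "raw", n = size)
    }
  }
  if (is.null(samples)) stop(sprintf("no data chunk found in '%s'", path))
  list(samples = samples, fs = fs, bits = bits)
}
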