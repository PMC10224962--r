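# Minimal RIFF/WAVE reader and writer (16-bit PCM, mono or stereo).

#' Read a WAV file
#'
#' Supports uncompressed PCM (8/16/32-bit integer) and 32-bit IEEE float.
#' Samples are returned on \[-1, 1\] as a matrix (samples x channels).
#'
#' @param path Path to a `.wav` file.
#' @return List: `samples` (numeric matrix), `sample_rate`, `bits`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz + sz %% 2)
      fmt <- list(
        audio_format = sum(as.integer(body[1:2]) * c(1, 256)),
        n_channels   = sum(as.integer(body[3:4]) * c(1, 256)),
        sample_rate  = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(body[15:16]) * c(1, 256)))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", sz + sz %% 2)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk: ", path)
  x <- switch(as.character(fmt$bits),
    "8"  = (as.integer(data_raw) - 128) / 128,
    "16" = readBin(data_raw, "integer", length(data_raw) / 2, 2,
                   signed = TRUE, endian = "little") / 32768,
    "32" = if (fmt$audio_format == 3)
             readBin(data_raw, "double", length(data_raw) / 4, 4,
                     endian = "little")
           else readBin(data_raw, "integer", length(data_raw) / 4, 4,
                        endian = "little") / 2147483648,
    stop("unsupported bit depth: ", fmt$bits))
  m <- matrix(x, ncol = fmt$n_channels, byrow = TRUE)
  list(samples = m, sample_rate = fmt$sample_rate, bits = fmt$bits)
}

#' Write a mono or stereo WAV file (16-bit PCM)
#'
#' @param samples Numeric vector (mono) or matrix (samples x channels) on
#'   \[-1, 1\]; values outside are clipped.
#' @param sample_rate Sample rate, Hz.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_wav <- function(samples, sample_rate, path) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  n_ch <- ncol(samples)
  x <- as.vector(t(samples))                 # interleave channels
  x <- pmax(pmin(x, 1), -1)
  pcm <- as.integer(round(x * 32767))
  data_size <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")                   # PCM
  writeBin(as.integer(n_ch), con, 2, endian = "little")
  writeBin(as.integer(sample_rate), con, 4, endian = "little")
  writeBin(as.integer(sample_rate * n_ch * 2L), con, 4, endian = "little")
  writeBin(as.integer(n_ch * 2L), con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
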