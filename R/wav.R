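# Minimal RIFF/WAVE reader and writer (16-bit PCM and 32-bit IEEE float).
# No WAV codec is available in the supporting packages, so the container is
# implemented here directly with readBin/writeBin (little-endian throughout).

#' Write a multi-channel WAV file
#'
#' @param samples Numeric matrix (rows = frames, columns = channels) or a
#'   numeric vector (one channel), values nominally in \[-1, 1\].
#' @param rate_hz Sampling rate in Hz.
#' @param path Output file path.
#' @param format `"float32"` (default; lossless for this package's signals)
#'   or `"pcm16"` (values clipped to \[-1, 1\] and quantised to 16 bits).
#' @return `path`, invisibly.
#' @seealso [read_wav()]
#' @export
write_wav <- function(samples, rate_hz, path, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  assert_that(is.matrix(samples) && is.numeric(samples) &&
                all(is.finite(samples)), "samples must be a finite numeric matrix")
  nch <- ncol(samples); nfr <- nrow(samples)
  interleaved <- as.numeric(t(samples))
  bits <- if (format == "float32") 32L else 16L
  block <- nch * bits %/% 8L
  data_size <- nfr * block
  con <- file(path, "wb")
  on.exit(close(con))
  wch <- function(s) writeChar(s, con, eos = NULL)
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  fmt_size <- if (format == "float32") 18L else 16L
  fact <- if (format == "float32") 12L else 0L  # fact chunk required for float
  wch("RIFF"); w32(4L + (8L + fmt_size) + fact + 8L + data_size); wch("WAVE")
  wch("fmt "); w32(fmt_size)
  w16(if (format == "float32") 3L else 1L)  # 3 = IEEE float, 1 = PCM
  w16(nch); w32(rate_hz); w32(rate_hz * block); w16(block); w16(bits)
  if (format == "float32") {
    w16(0L)                                  # cbSize
    wch("fact"); w32(4L); w32(nfr)
  }
  wch("data"); w32(data_size)
  if (format == "float32") {
    writeBin(interleaved, con, size = 4, endian = "little")
  } else {
    q <- pmin(pmax(interleaved, -1), 1)
    w16(as.integer(round(q * 32767)))
  }
  invisible(path)
}

#' Read a WAV file
#'
#' Supports the formats written by [write_wav()]: uncompressed 16-bit PCM and
#' 32-bit IEEE float, any channel count. Unknown RIFF chunks are skipped.
#'
#' @param path WAV file path.
#' @return List with `samples` (numeric matrix, rows = frames, columns =
#'   channels; PCM rescaled to \[-1, 1\] by 1/32767), `rate_hz` and `format`.
#' @export
read_wav <- function(path) {
  assert_that(file.exists(path), paste("no such file:", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rch <- function(k) readChar(con, k, useBytes = TRUE)
  r32 <- function() readBin(con, "integer", size = 4, endian = "little")
  r16 <- function() readBin(con, "integer", size = 2, endian = "little")
  assert_that(rch(4) == "RIFF", paste(path, "is not a RIFF file"))
  r32()
  assert_that(rch(4) == "WAVE", paste(path, "is not a WAVE file"))
  fmt <- NULL; raw_data <- NULL
  repeat {
    id <- rch(4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- r32()
    if (id == "fmt ") {
      fmt <- list(audio_format = r16(), n_channels = r16(), rate_hz = r32())
      r32(); r16()  # byte rate, block align
      fmt$bits <- r16()
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (id == "data") {
      raw_data <- readBin(con, "raw", size)
      if (size %% 2 == 1) readBin(con, "raw", 1)  # chunk padding
    } else {
      readBin(con, "raw", size + size %% 2)
    }
    if (!is.null(fmt) && !is.null(raw_data)) break
  }
  assert_that(!is.null(fmt) && !is.null(raw_data),
              paste(path, "is missing fmt/data chunks"))
  if (fmt$audio_format == 3 && fmt$bits == 32) {
    x <- readBin(raw_data, "numeric", n = length(raw_data) / 4, size = 4,
                 endian = "little")
    format <- "float32"
  } else if (fmt$audio_format == 1 && fmt$bits == 16) {
    x <- readBin(raw_data, "integer", n = length(raw_data) / 2, size = 2,
                 signed = TRUE, endian = "little") / 32767
    format <- "pcm16"
  } else {
    stop_pleura(sprintf("unsupported WAV encoding in %s (format %d, %d bits)",
                        path, fmt$audio_format, fmt$bits))
  }
  list(samples = matrix(x, ncol = fmt$n_channels, byrow = TRUE),
       rate_hz = fmt$rate_hz, format = format)
}
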