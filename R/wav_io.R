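# Minimal RIFF/WAVE reader and writer: PCM16 and IEEE float32, the two
# encodings passive acoustic recorders produce. Multichannel files are
# downmixed to mono by averaging on read; all internal processing is mono.

#' Read a WAV file
#'
#' Supports PCM16 and IEEE float32 RIFF/WAVE (including the WAVE_FORMAT_
#' EXTENSIBLE wrapper around either). Multichannel audio is averaged to a
#' single channel; PCM16 samples are scaled by 1/32768 to the -1..1 range.
#'
#' @param path path to a `.wav` file.
#' @return a [waveform()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        format   = readBin(raw[1:2], "integer", 1, 2, signed = FALSE,
                           endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, 2, signed = FALSE,
                           endian = "little"),
        rate     = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits     = readBin(raw[15:16], "integer", 1, 2, signed = FALSE,
                           endian = "little"))
      if (fmt$format == 65534L && sz >= 40)  # extensible: subformat GUID
        fmt$format <- readBin(raw[25:26], "integer", 1, 2, signed = FALSE,
                              endian = "little")
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("malformed WAV (missing fmt or data chunk): ", path)

  if (fmt$format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2, 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "double", length(data_raw) / 4, 4,
                 endian = "little")
  } else {
    stop("unsupported WAV encoding (format ", fmt$format, ", ",
         fmt$bits, " bits); only PCM16 and float32 are supported")
  }
  if (fmt$channels > 1L) {
    nfrm <- length(x) %/% fmt$channels
    x <- colMeans(matrix(x[seq_len(nfrm * fmt$channels)],
                         nrow = fmt$channels))
  }
  waveform(x, fmt$rate)
}

#' Write a WAV file
#'
#' @param w a [waveform()].
#' @param path output path.
#' @param bits 32 writes IEEE float32 (the default; lossless for internal
#'   float storage), 16 writes PCM16 with clipping at full scale.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, bits = 32) {
  stopifnot_waveform(w)
  if (!bits %in% c(16, 32)) stop("bits must be 16 or 32")
  x <- w$samples
  n <- length(x)
  bytes_per <- bits / 8
  data_sz <- n * bytes_per
  fmt_code <- if (bits == 32) 3L else 1L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_sz), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")                       # mono
  writeBin(as.integer(round(w$rate)), con, 4, endian = "little")
  writeBin(as.integer(round(w$rate) * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")    # block align
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, 4, endian = "little")
  if (bits == 32) {
    writeBin(x, con, 4, endian = "little")
  } else {
    xi <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
    writeBin(xi, con, 2, endian = "little")
  }
  invisible(path)
}
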