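#' Read a WAV file
#'
#' Minimal RIFF/WAVE reader covering the formats the pipeline writes and
#' consumes: 16- and 24-bit integer PCM and 32-bit IEEE float, mono or
#' stereo (mono files are duplicated onto both channels). Integer samples
#' are scaled to `[-1, 1)`.
#'
#' @param path Path to a `.wav` file.
#' @param resample_to Optional target sample rate in Hz; if given and
#'   different from the file's rate, channels are resampled with a
#'   polyphase filter ([signal::resample()]).
#' @return A [stereo_signal()].
#' @export
read_wav <- function(path, resample_to = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop(path, " is not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop(path, " is not a WAVE file")

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = raw_uint(body, 1, 2),
        n_channels = raw_uint(body, 3, 2),
        sample_rate = raw_uint(body, 5, 4),
        bits = raw_uint(body, 15, 2)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk in ", path)

  nch <- fmt$n_channels
  if (!nch %in% c(1L, 2L)) stop("only mono/stereo WAV supported")
  samples <- switch(
    as.character(fmt$audio_format),
    "1" = {  # integer PCM
      if (fmt$bits == 16) {
        readBin(data_raw, "integer", length(data_raw) / 2, 2,
                signed = TRUE, endian = "little") / 32768
      } else if (fmt$bits == 24) {
        decode_pcm24(data_raw)
      } else stop("unsupported PCM bit depth: ", fmt$bits)
    },
    "3" = {  # IEEE float
      if (fmt$bits != 32) stop("only 32-bit float WAV supported")
      readBin(data_raw, "numeric", length(data_raw) / 4, 4, endian = "little")
    },
    stop("unsupported WAV audio format code: ", fmt$audio_format)
  )
  if (nch == 1L) {
    left <- right <- samples
  } else {
    left <- samples[seq(1, length(samples), by = 2)]
    right <- samples[seq(2, length(samples), by = 2)]
  }
  fs <- fmt$sample_rate
  if (!is.null(resample_to) && resample_to != fs) {
    frac <- rational_approx(resample_to / fs)
    left <- signal::resample(left, frac[1], frac[2])
    right <- signal::resample(right, frac[1], frac[2])
    fs <- resample_to
  }
  stereo_signal(left, right, fs)
}

raw_uint <- function(raw, at, nbytes) {
  sum(as.integer(raw[at:(at + nbytes - 1)]) * 256^(0:(nbytes - 1)))
}

decode_pcm24 <- function(raw) {
  n <- length(raw) / 3
  b <- matrix(as.integer(raw), nrow = 3)
  v <- b[1, ] + b[2, ] * 256 + b[3, ] * 65536
  v <- ifelse(v >= 2^23, v - 2^24, v)
  v / 2^23
}

rational_approx <- function(r, max_den = 1000L) {
  # best small-denominator rational for a resampling ratio
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    if (p < 1) next
    e <- abs(r - p / q)
    if (e < err - 1e-15) { best <- c(p, q); err <- e }
    if (err < 1e-12) break
  }
  best
}

#' Write a stereo signal to a WAV file
#'
#' @param x A [stereo_signal()].
#' @param path Output path.
#' @param format One of `"pcm16"`, `"pcm24"`, `"float32"`.
#' @param normalize If `TRUE` and the peak exceeds 1, rescale to 0.99 peak
#'   before integer quantization (float32 is never rescaled).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, format = c("float32", "pcm16", "pcm24"),
                      normalize = TRUE) {
  stopifnot(inherits(x, "stereo_signal"))
  format <- match.arg(format)
  inter <- as.vector(rbind(x$left, x$right))
  peak <- max(abs(inter), 0)
  if (format != "float32" && normalize && peak > 1) {
    inter <- inter * 0.99 / peak
  }
  fs <- as.integer(round(x$sample_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  nch <- 2L
  if (format == "float32") {
    fmt_code <- 3L; bits <- 32L
    payload_size <- length(inter) * 4L
  } else if (format == "pcm16") {
    fmt_code <- 1L; bits <- 16L
    payload_size <- length(inter) * 2L
  } else {
    fmt_code <- 1L; bits <- 24L
    payload_size <- length(inter) * 3L
  }
  block <- nch * bits / 8L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + payload_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(nch, con, 2, endian = "little")
  writeBin(fs, con, 4, endian = "little")
  writeBin(as.integer(fs * block), con, 4, endian = "little")
  writeBin(as.integer(block), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(payload_size), con, 4, endian = "little")
  if (format == "float32") {
    writeBin(inter, con, 4, endian = "little")
  } else if (format == "pcm16") {
    q <- as.integer(pmax(-32768, pmin(32767, round(inter * 32768))))
    writeBin(q, con, 2, endian = "little")
  } else {
    q <- round(pmax(-1, pmin(1 - 2^-23, inter)) * 2^23)
    q <- ifelse(q < 0, q + 2^24, q)
    b <- rbind(q %% 256, (q %/% 256) %% 256, (q %/% 65536) %% 256)
    writeBin(as.raw(as.vector(b)), con)
  }
  invisible(path)
}
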