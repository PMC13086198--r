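#' Time-frequency analysis grid
#'
#' Describes the STFT lattice shared by all spectrograms, clouds, models and
#' masks: one-sided bin centers `k * sample_rate / window_len` for
#' `k = 0 .. window_len/2`, frame centers in seconds, and the analysis
#' parameters needed for exact inversion. At the default 40-ms window and
#' 32.1-kHz rate the window is 1284 samples and the bin spacing exactly
#' 25 Hz.
#'
#' @param window_len Window length in samples (even).
#' @param hop Hop in samples; must divide `window_len`.
#' @param sample_rate Sample rate in Hz.
#' @param n_frames Number of frames.
#' @param orig_len Original signal length in samples (for inversion).
#' @param pad Reflect-padding applied at each end, in samples.
#' @return A `tf_grid` with `frequencies_hz`, `frame_times_s`, and the
#'   parameters above.
#' @export
tf_grid <- function(window_len, hop, sample_rate, n_frames, orig_len, pad) {
  if (window_len %% 2 != 0) stop("window_len must be even")
  if (window_len %% hop != 0) stop("hop must divide window_len")
  starts <- (seq_len(n_frames) - 1L) * hop   # 0-based starts in padded signal
  structure(list(
    frequencies_hz = (0:(window_len / 2)) * sample_rate / window_len,
    frame_times_s = (starts - pad + window_len / 2) / sample_rate,
    window_len = window_len,
    hop = hop,
    sample_rate = sample_rate,
    n_frames = n_frames,
    orig_len = orig_len,
    pad = pad
  ), class = "tf_grid")
}

#' @export
print.tf_grid <- function(x, ...) {
  cat(sprintf(paste0("<tf_grid> %d bins x %d frames, window %d samples ",
                     "(hop %d) @ %g Hz, bin spacing %g Hz\n"),
              length(x$frequencies_hz), x$n_frames, x$window_len, x$hop,
              x$sample_rate, x$frequencies_hz[2]))
  invisible(x)
}

# Periodic Hann window: shifted copies at 50% overlap sum exactly to 1,
# which is what makes plain overlap-add inversion exact.
hann_periodic <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
}

#' Short-time Fourier transform of a stereo signal
#'
#' Windowed one-sided DFT frames (periodic Hann, 50% hop) computed
#' separately for the left and right channels on a shared grid. The signal
#' is reflect-padded by one window at each end so that every original
#' sample is fully covered by the overlap-add partition of unity, making
#' [istft()] an exact inverse.
#'
#' @param signal A [stereo_signal()] at least one window long.
#' @param window_ms Analysis window length in milliseconds (default 40, the
#'   working choice that yields 25-Hz bins at 32.1 kHz).
#' @return A `stereo_spectrogram`: complex matrices `X_L`, `X_R`
#'   (frequency x frame) plus the `tf_grid` in `$grid`.
#' @export
stft <- function(signal, window_ms = 40) {
  stopifnot(inherits(signal, "stereo_signal"))
  fs <- signal$sample_rate
  win <- round(fs * window_ms / 1000)
  if (win %% 2 == 1) win <- win + 1
  n <- n_samples(signal)
  if (n < win) {
    stop("signal (", n, " samples) is shorter than one analysis window (",
         win, " samples)")
  }
  hop <- win %/% 2L
  pad <- win
  w <- hann_periodic(win)

  frame_channel <- function(x) {
    xp <- c(rev(x[seq_len(pad)]), x, rev(x[seq(n - pad + 1L, n)]))
    # extend so the last frames cover the padded tail completely
    n_fr <- ceiling((length(xp) - win) / hop) + 1L
    need <- (n_fr - 1L) * hop + win
    xp <- c(xp, numeric(need - length(xp)))
    idx <- outer(seq_len(win), (seq_len(n_fr) - 1L) * hop, "+")
    frames <- matrix(xp[idx], nrow = win) * w
    X <- stats::mvfft(frames)
    X[seq_len(win / 2 + 1L), , drop = FALSE]
  }
  XL <- frame_channel(signal$left)
  XR <- frame_channel(signal$right)
  grid <- tf_grid(win, hop, fs, ncol(XL), n, pad)
  structure(list(X_L = XL, X_R = XR, grid = grid),
            class = "stereo_spectrogram")
}

#' @export
print.stereo_spectrogram <- function(x, ...) {
  cat("<stereo_spectrogram>\n")
  print(x$grid)
  invisible(x)
}

#' Inverse STFT (overlap-add synthesis)
#'
#' Reconstructs the time-domain stereo signal by inverse-DFT of each frame
#' and plain overlap-add. Because analysis used a periodic Hann at 50%
#' overlap (a partition of unity) and the edges were reflect-padded, the
#' round trip `istft(stft(x))` reproduces `x` exactly (to floating-point
#' rounding) over the whole original extent.
#'
#' @param spec A `stereo_spectrogram` from [stft()] (possibly masked).
#' @return A [stereo_signal()] of the original length.
#' @export
istft <- function(spec) {
  stopifnot(inherits(spec, "stereo_spectrogram"))
  g <- spec$grid
  win <- g$window_len
  hop <- g$hop

  synth_channel <- function(X) {
    full <- rbind(X, Conj(X[seq(win / 2, 2), , drop = FALSE]))
    frames <- Re(stats::mvfft(full, inverse = TRUE)) / win
    out <- numeric((ncol(X) - 1L) * hop + win)
    for (j in seq_len(ncol(X))) {
      at <- (j - 1L) * hop
      out[(at + 1L):(at + win)] <- out[(at + 1L):(at + win)] + frames[, j]
    }
    out[(g$pad + 1L):(g$pad + g$orig_len)]
  }
  stereo_signal(synth_channel(spec$X_L), synth_channel(spec$X_R),
                g$sample_rate)
}

#' Total spectral energy of a spectrogram
#'
#' Sum of `|X_L|^2 + |X_R|^2` over all bins; the quantity conserved (up to
#' the window partition) through masking diagnostics.
#'
#' @param spec A `stereo_spectrogram`.
#' @return Scalar energy.
#' @export
spec_energy <- function(spec) {
  sum(Mod(spec$X_L)^2) + sum(Mod(spec$X_R)^2)
}
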