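#' Two-channel sampled waveform
#'
#' The unit of audio exchange in spiralsep: a left/right pair of sample
#' vectors at a common sample rate. Amplitudes are dimensionless; absolute
#' sound level is never modelled, only level *ratios* between sources.
#'
#' @param left,right Numeric sample vectors of equal length, finite.
#' @param sample_rate Sampling frequency in Hz (> 0).
#' @return An object of class `stereo_signal` with elements `left`, `right`
#'   and `sample_rate`.
#' @examples
#' s <- stereo_signal(sin(2 * pi * 440 * (0:999) / 32100),
#'                    cos(2 * pi * 440 * (0:999) / 32100), 32100)
#' n_samples(s)
#' @export
stereo_signal <- function(left, right, sample_rate) {
  left <- as.numeric(left)
  right <- as.numeric(right)
  if (length(left) != length(right)) {
    stop("left and right channels must have equal length (got ",
         length(left), " and ", length(right), ")")
  }
  if (!all(is.finite(left)) || !all(is.finite(right))) {
    stop("channel samples must be finite")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      !is.finite(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be a single positive number (Hz)")
  }
  structure(list(left = left, right = right, sample_rate = sample_rate),
            class = "stereo_signal")
}

#' @export
print.stereo_signal <- function(x, ...) {
  cat(sprintf("<stereo_signal> %d samples @ %g Hz (%.3f s), peak %.4g\n",
              length(x$left), x$sample_rate,
              length(x$left) / x$sample_rate,
              max(abs(c(x$left, x$right, 0)))))
  invisible(x)
}

#' Number of samples per channel
#' @param x A `stereo_signal`.
#' @return Integer sample count.
#' @export
n_samples <- function(x) {
  stopifnot(inherits(x, "stereo_signal"))
  length(x$left)
}

#' Root-mean-square amplitude of a signal
#'
#' For a stereo signal the RMS is taken jointly over both channels, so that
#' level equalization between sources is a whole-signal (not per-channel,
#' not per-frame) operation.
#'
#' @param x Numeric vector or `stereo_signal`.
#' @return RMS amplitude (dimensionless).
#' @export
rms <- function(x) {
  if (inherits(x, "stereo_signal")) x <- c(x$left, x$right)
  sqrt(mean(as.numeric(x)^2))
}

#' Time-reverse a sample sequence
#'
#' Reversal preserves the long-term spectrum and energy of speech while
#' destroying its intelligibility, which is why reversed sentences serve as
#' the interfering stream in the virtual-scene experiments.
#'
#' @param x Numeric sample vector.
#' @return `x` reversed: `out[k] = x[N + 1 - k]`.
#' @examples
#' time_reverse(c(1, 2, 3))
#' @export
time_reverse <- function(x) {
  rev(as.numeric(x))
}

#' Linear gain applied to the interferer for a given SNR
#'
#' The mixing convention references both sources at equal RMS (0 dB SNR);
#' raising the SNR scales the interferer down by `10^(-snr_db/20)`. A 3 dB
#' SNR therefore scales the interferer by 0.707.
#'
#' @param snr_db Target signal-to-noise ratio in decibels.
#' @return Linear amplitude factor applied to the RMS-equalized interferer.
#' @export
snr_gain <- function(snr_db) {
  10^(-snr_db / 20)
}

#' Mix a target and an interferer at a controlled SNR
#'
#' Both stereo sources are first equalized to a common whole-signal RMS
#' (the target's), then the interferer is scaled by [snr_gain()] and the two
#' are summed sample-wise per channel, zero-padding the shorter source.
#'
#' @param target,interferer `stereo_signal` objects at the same sample rate.
#' @param snr_db Signal-to-noise ratio in dB (target re interferer).
#' @return A `stereo_signal` mixture. Attribute `interferer_gain` records
#'   the total linear gain applied to the interferer.
#' @export
mix_scene <- function(target, interferer, snr_db = 0) {
  stopifnot(inherits(target, "stereo_signal"),
            inherits(interferer, "stereo_signal"))
  if (target$sample_rate != interferer$sample_rate) {
    stop("sample-rate mismatch: target ", target$sample_rate,
         " Hz vs interferer ", interferer$sample_rate, " Hz")
  }
  rt <- rms(target)
  ri <- rms(interferer)
  if (rt == 0) stop("target is silent (all zero): RMS undefined for mixing")
  if (ri == 0) stop("interferer is silent (all zero): RMS undefined for mixing")
  g <- (rt / ri) * snr_gain(snr_db)
  n <- max(n_samples(target), n_samples(interferer))
  pad <- function(v) c(v, numeric(n - length(v)))
  out <- stereo_signal(pad(target$left) + g * pad(interferer$left),
                       pad(target$right) + g * pad(interferer$right),
                       target$sample_rate)
  attr(out, "interferer_gain") <- g
  out
}

#' Spatialize a monaural source through an HRIR pair
#'
#' Convolves the input with the left- and right-ear impulse responses,
#' producing the binaural virtual-acoustic-space rendering of the source at
#' the HRIR's azimuth. The full (open) convolution is returned, length
#' `length(mono) + n_taps - 1`.
#'
#' @param mono Numeric sample vector (non-empty).
#' @param hrir An `hrir_pair` from [synth_hrir()], or any list with numeric
#'   `left`, `right` and `sample_rate`.
#' @param sample_rate Sample rate of `mono` in Hz; must match the HRIR's.
#' @return A `stereo_signal`.
#' @export
spatialize <- function(mono, hrir, sample_rate) {
  mono <- as.numeric(mono)
  if (length(mono) == 0L) stop("mono input must be non-empty")
  if (!is.null(hrir$sample_rate) && hrir$sample_rate != sample_rate) {
    stop("sample-rate mismatch: signal ", sample_rate,
         " Hz vs HRIR ", hrir$sample_rate, " Hz")
  }
  stereo_signal(conv_full(mono, hrir$left),
                conv_full(mono, hrir$right),
                sample_rate)
}

# FFT-based full linear convolution (length n + m - 1).
conv_full <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nf <- stats::nextn(n, 2L)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nf - length(x)))) *
                     stats::fft(c(h, numeric(nf - length(h)))),
                     inverse = TRUE)) / nf
  y[seq_len(n)]
}

#' Generate a sparse tone-burst source
#'
#' Builds a test source that embodies the sparseness (W-disjoint
#' orthogonality) assumption: a sum of amplitude-gated tone bursts confined
#' to the requested frequency bands, with randomized onset times and a low
#' duty cycle, so two sources built from disjoint band sets have essentially
#' non-overlapping time-frequency supports at the 40-ms/25-Hz analysis
#' resolution. Deterministic given `seed`; the global RNG state is restored
#' on exit.
#'
#' @param seed Integer seed.
#' @param band_set List of `c(lo, hi)` frequency bands in Hz; an empty list
#'   yields an all-zero signal.
#' @param duration_s Duration in seconds.
#' @param sample_rate Sample rate in Hz (default the 32.1 kHz working rate).
#' @param tones_per_band Number of distinct tone frequencies drawn per band.
#' @param duty Approximate fraction of time each tone is active.
#' @return Numeric sample vector of length `round(duration_s * sample_rate)`.
#' @export
generate_sparse_source <- function(seed, band_set, duration_s,
                                   sample_rate = 32100,
                                   tones_per_band = 3L, duty = 0.35) {
  stopifnot(duration_s > 0, sample_rate > 0)
  n <- round(duration_s * sample_rate)
  out <- numeric(n)
  if (length(band_set) == 0L) return(out)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  t <- (seq_len(n) - 1) / sample_rate
  bin_hz <- 25  # analysis-grid spacing of the 40-ms window
  ramp_s <- 0.02
  for (band in band_set) {
    lo <- band[1]; hi <- band[2]
    stopifnot(hi > lo, lo > 0)
    # tones sit on analysis bin centers, kept 50 Hz inside the band edges so
    # Hann mainlobe leakage stays within the band
    kmin <- ceiling((lo + 50) / bin_hz)
    kmax <- floor((hi - 50) / bin_hz)
    if (kmax < kmin) { kmin <- round(mean(c(lo, hi)) / bin_hz); kmax <- kmin }
    ks <- sample(seq(kmin, kmax), min(tones_per_band, kmax - kmin + 1L))
    for (k in ks) {
      f <- k * bin_hz
      tone <- sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
      env <- burst_envelope(n, sample_rate, duty, ramp_s)
      out <- out + env * tone * stats::runif(1, 0.6, 1)
    }
  }
  out
}

# Random raised-cosine gated on/off envelope with the requested duty cycle.
burst_envelope <- function(n, fs, duty, ramp_s) {
  env <- numeric(n)
  ramp <- round(ramp_s * fs)
  dur_s <- n / fs
  n_bursts <- max(1L, round(duty * dur_s / 0.25))
  for (b in seq_len(n_bursts)) {
    len <- round(stats::runif(1, 0.15, 0.35) * fs)
    start <- 1L + floor(stats::runif(1, 0, max(1, n - len)))
    stop_ <- min(n, start + len - 1L)
    seg <- numeric(stop_ - start + 1L)
    seg[] <- 1
    r <- min(ramp, floor(length(seg) / 2))
    if (r > 0) {
      up <- 0.5 * (1 - cos(pi * seq_len(r) / r))
      seg[seq_len(r)] <- seg[seq_len(r)] * up
      seg[length(seg) - r + seq_len(r)] <- seg[length(seg) - r + seq_len(r)] * rev(up)
    }
    env[start:stop_] <- pmax(env[start:stop_], seg)
  }
  env
}

#' Time-frequency energy overlap between two sources
#'
#' Cosine similarity of the per-bin STFT energy maps of two monaural
#' signals; 0 means disjoint supports, 1 identical supports. Used to verify
#' the sparseness of generated fixtures.
#'
#' @param x,y Numeric sample vectors at the same rate.
#' @param sample_rate Sample rate in Hz.
#' @param window_ms Analysis window in milliseconds.
#' @return Overlap ratio in `[0, 1]`.
#' @export
tf_overlap <- function(x, y, sample_rate = 32100, window_ms = 40) {
  ex <- bin_energy(x, sample_rate, window_ms)
  ey <- bin_energy(y, sample_rate, window_ms)
  sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
}

bin_energy <- function(x, sample_rate, window_ms) {
  s <- stereo_signal(x, x, sample_rate)
  sp <- stft(s, window_ms = window_ms)
  Mod(sp$X_L)^2
}

# Seed helpers: run reproducibly without clobbering the caller's RNG stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
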