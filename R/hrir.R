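#' Synthesize a spherical-head HRIR pair for one azimuth
#'
#' Generates a left/right head-related impulse-response pair from a
#' spherical-head model, emulating the two cues the localization model
#' exploits:
#'
#' * **ITD** — a fractional interaural delay following the Woodworth law
#'   `tau(theta) = (a/c) * (theta + sin(theta))` for the lateral angle
#'   `theta`, split symmetrically across the two ears. It is zero at 0° and
#'   at +/-180°, maximal near +/-90°, and the leading ear is the one the
#'   source is on.
#' * **ILD** — a frequency-dependent head-shadow low-pass on the far ear,
#'   exactly 0 dB at 0° and monotonically stronger toward +/-90° at any
#'   fixed frequency.
#'
#' Rear azimuths (|azimuth| > 90°) additionally receive a +2 dB high-shelf
#' above 6 kHz on both ears, a small spectral perturbation that keeps
#' front/back mirror pairs acoustically distinguishable (real pinnae do the
#' same job; a perfectly symmetric sphere would put them on a degenerate
#' confusion cone).
#'
#' @param azimuth_deg Azimuth in degrees: 0 front, negative left, positive
#'   right, +/-180 back; elevation is fixed at 0.
#' @param head_radius_m Head radius `a` in meters.
#' @param n_taps FIR length in samples; must hold the maximum interaural
#'   delay (about 26 samples at 32.1 kHz) plus filter tails.
#' @param sample_rate Sample rate in Hz.
#' @param speed_of_sound Speed of sound `c` in m/s.
#' @return An `hrir_pair`: list with `left`, `right` (numeric, `n_taps`
#'   long), `sample_rate`, `azimuth_deg` and `itd_s` (the signed Woodworth
#'   ITD in seconds, positive when the right ear leads).
#' @examples
#' h <- synth_hrir(60)
#' h$itd_s * 1e3  # ITD in ms
#' @export
synth_hrir <- function(azimuth_deg, head_radius_m = 0.0875, n_taps = 256L,
                       sample_rate = 32100, speed_of_sound = 343) {
  if (!is.numeric(azimuth_deg) || length(azimuth_deg) != 1L ||
      !is.finite(azimuth_deg)) {
    stop("azimuth must be a single finite number in degrees")
  }
  if (abs(azimuth_deg) > 180) {
    stop("azimuth ", azimuth_deg, " out of range: |azimuth| must be <= 180")
  }
  itd <- woodworth_itd(azimuth_deg, head_radius_m, speed_of_sound)
  max_itd <- woodworth_itd(90, head_radius_m, speed_of_sound)
  if (n_taps < 4 * ceiling(max_itd * sample_rate)) {
    stop("n_taps too small to hold the maximum interaural delay")
  }
  lat <- lateral_angle_deg(azimuth_deg)
  s <- sin(abs(lat) * pi / 180)           # lateral displacement, 0..1
  rear <- abs(azimuth_deg) > 90

  half <- itd * sample_rate / 2           # signed, samples
  base <- n_taps / 2                      # common causal delay
  # right ear leads (arrives earlier) for positive azimuth
  d_right <- base - half
  d_left <- base + half

  k <- 0:(n_taps / 2)
  f <- k * sample_rate / n_taps
  shadow <- 1 / sqrt(1 + (f * s * 5 / 12000)^2)  # far-ear head shadow
  shelf <- if (rear) rear_shelf(f) else rep(1, length(f))
  g_left <- if (azimuth_deg >= 0) shadow else rep(1, length(f))
  g_right <- if (azimuth_deg >= 0) rep(1, length(f)) else shadow

  list_ir <- function(gain, delay) {
    H <- gain * shelf * exp(-2i * pi * k * delay / n_taps)
    H[1] <- Re(H[1])
    H[length(H)] <- Re(H[length(H)])
    full <- c(H, Conj(H[seq(n_taps / 2, 2)]))
    Re(stats::fft(full, inverse = TRUE)) / n_taps
  }
  structure(list(left = list_ir(g_left, d_left),
                 right = list_ir(g_right, d_right),
                 sample_rate = sample_rate,
                 azimuth_deg = azimuth_deg,
                 itd_s = itd),
            class = "hrir_pair")
}

#' Woodworth spherical-head interaural time difference
#'
#' `tau = (a/c) * (theta + sin(theta))` with the lateral angle folded into
#' the front quadrant, so the ITD is 0 at 0° and +/-180° and maximal at
#' +/-90°. Positive values mean the right ear leads.
#'
#' @param azimuth_deg Azimuth in degrees, |azimuth| <= 180.
#' @param head_radius_m Head radius in meters.
#' @param speed_of_sound Speed of sound in m/s.
#' @return Signed ITD in seconds.
#' @export
woodworth_itd <- function(azimuth_deg, head_radius_m = 0.0875,
                          speed_of_sound = 343) {
  lat <- lateral_angle_deg(azimuth_deg)
  th <- abs(lat) * pi / 180
  sign(lat) * head_radius_m / speed_of_sound * (th + sin(th))
}

# Fold an azimuth into the signed lateral angle in [-90, 90]:
# 0 at front and back, +/-90 at the sides.
lateral_angle_deg <- function(az) {
  if (az > 90) 180 - az else if (az < -90) -180 - az else az
}

# +2 dB high-shelf above 6 kHz (raised-cosine transition 6-8 kHz).
rear_shelf <- function(f) {
  g <- 10^(2 / 20)
  w <- pmin(1, pmax(0, (f - 6000) / 2000))
  1 + (g - 1) * 0.5 * (1 - cos(pi * w))
}

#' @export
print.hrir_pair <- function(x, ...) {
  cat(sprintf("<hrir_pair> azimuth %+g deg, %d taps @ %g Hz, ITD %+.3f ms\n",
              x$azimuth_deg, length(x$left), x$sample_rate, x$itd_s * 1e3))
  invisible(x)
}

#' Construct an HRIR set over an azimuth grid
#'
#' @param azimuths_deg Strictly increasing azimuths in degrees within
#'   `(-180, 180]`.
#' @param impulse_responses List of `hrir_pair`s (or left/right lists), one
#'   per azimuth, all the same length.
#' @param sample_rate Sample rate in Hz.
#' @param source Free-text identifier of where the set came from.
#' @return An `hrir_set`.
#' @export
hrir_set <- function(azimuths_deg, impulse_responses, sample_rate,
                     source = "unspecified") {
  azimuths_deg <- as.numeric(azimuths_deg)
  if (length(azimuths_deg) == 0L) stop("azimuth grid must be non-empty")
  if (any(azimuths_deg <= -180 | azimuths_deg > 180)) {
    stop("azimuths must lie in (-180, 180]")
  }
  if (is.unsorted(azimuths_deg, strictly = TRUE)) {
    stop("azimuths must be strictly increasing")
  }
  if (length(impulse_responses) != length(azimuths_deg)) {
    stop("one impulse-response pair required per azimuth")
  }
  lens <- vapply(impulse_responses,
                 function(p) length(p$left), integer(1))
  if (length(unique(lens)) != 1L) stop("all IR pairs must share one length")
  if (sample_rate <= 0) stop("sample_rate must be > 0")
  structure(list(azimuths_deg = azimuths_deg,
                 impulse_responses = impulse_responses,
                 sample_rate = sample_rate,
                 source = source),
            class = "hrir_set")
}

#' Synthesize a full spherical-head HRIR set
#'
#' @param azimuths_deg Azimuth grid in degrees (default -90..90 in 10°
#'   steps, the frontal calibration sweep).
#' @inheritParams synth_hrir
#' @return An `hrir_set` with `source = "synthetic-spherical-head"`.
#' @export
synth_hrir_set <- function(azimuths_deg = seq(-90, 90, by = 10),
                           head_radius_m = 0.0875, n_taps = 256L,
                           sample_rate = 32100) {
  azimuths_deg <- sort(as.numeric(azimuths_deg))
  irs <- lapply(azimuths_deg, synth_hrir, head_radius_m = head_radius_m,
                n_taps = n_taps, sample_rate = sample_rate)
  hrir_set(azimuths_deg, irs, sample_rate, source = "synthetic-spherical-head")
}

#' @export
print.hrir_set <- function(x, ...) {
  cat(sprintf("<hrir_set> %d azimuths [%g .. %g deg], %d taps @ %g Hz (%s)\n",
              length(x$azimuths_deg), min(x$azimuths_deg),
              max(x$azimuths_deg),
              length(x$impulse_responses[[1]]$left), x$sample_rate,
              x$source))
  invisible(x)
}

#' Look up the HRIR pair for an azimuth
#'
#' @param hrirs An `hrir_set`.
#' @param azimuth_deg Requested azimuth; must be on the set's grid (within
#'   `tol` degrees).
#' @param tol Matching tolerance in degrees.
#' @return The stored `hrir_pair`.
#' @export
get_hrir <- function(hrirs, azimuth_deg, tol = 1e-6) {
  stopifnot(inherits(hrirs, "hrir_set"))
  i <- which(abs(hrirs$azimuths_deg - azimuth_deg) <= tol)
  if (length(i) == 0L) {
    stop("azimuth ", azimuth_deg, " deg is not in the HRIR set")
  }
  hrirs$impulse_responses[[i[1]]]
}

#' Write an HRIR set to disk as per-azimuth stereo WAVs
#'
#' One stereo WAV per azimuth, named `az{+ddd}.wav`, plus a plain-text
#' `manifest.txt` giving the sample rate and azimuth list.
#'
#' @param hrirs An `hrir_set`.
#' @param dir Output directory (created if needed).
#' @param format WAV sample format passed to [write_wav()].
#' @return `dir`, invisibly.
#' @export
write_hrir_set <- function(hrirs, dir, format = "float32") {
  stopifnot(inherits(hrirs, "hrir_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(hrirs$azimuths_deg))
  for (i in seq_along(hrirs$azimuths_deg)) {
    az <- hrirs$azimuths_deg[i]
    files[i] <- sprintf("az%+04d.wav", round(az))
    p <- hrirs$impulse_responses[[i]]
    write_wav(stereo_signal(p$left, p$right, hrirs$sample_rate),
              file.path(dir, files[i]), format = format)
  }
  manifest <- c(sprintf("sample_rate %g", hrirs$sample_rate),
                sprintf("source %s", hrirs$source),
                sprintf("%g %s", hrirs$azimuths_deg, files))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Read an HRIR set written by [write_hrir_set()]
#'
#' @param dir Directory containing `manifest.txt` and the per-azimuth WAVs.
#' @return An `hrir_set`.
#' @export
read_hrir_set <- function(dir) {
  mf <- file.path(dir, "manifest.txt")
  if (!file.exists(mf)) stop("no manifest.txt in ", dir)
  lines <- readLines(mf)
  fs <- as.numeric(strsplit(lines[1], " ")[[1]][2])
  src <- sub("^source ", "", lines[2])
  entries <- strsplit(lines[-(1:2)], " ")
  az <- vapply(entries, function(e) as.numeric(e[1]), numeric(1))
  irs <- lapply(entries, function(e) {
    w <- read_wav(file.path(dir, e[2]))
    list(left = w$left, right = w$right, sample_rate = w$sample_rate)
  })
  o <- order(az)
  hrir_set(az[o], irs[o], fs, source = src)
}
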