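#' Calibrate the per-frequency spiral model from broadband noise
#'
#' For every azimuth on the grid, seeded Gaussian white noise is rendered in
#' virtual acoustic space through that azimuth's HRIR pair, analysed with
#' [stft()] and [disk_normalize()], and the energy-weighted complex mean of
#' the non-void points at each frequency is stored as that
#' (frequency, azimuth) cluster center. Traced over azimuth at a fixed
#' frequency, the centers spiral outward counterclockwise (for the
#' leading-ear direction): the interaural delay advances the phase - with
#' more turns at higher frequencies, since the phase is `2*pi*f*ITD` -
#' while the head-shadow level difference moves the modulus between origin
#' and unit circle.
#'
#' Broadband noise is used deliberately: it excites every analysis bin. It
#' is the one signal class the *segregation* stage cannot handle (it
#' violates sparseness), but calibration only ever presents one source at a
#' time.
#'
#' @param hrirs An `hrir_set`; the calibration grid must be a subset of its
#'   azimuths.
#' @param azimuth_grid Azimuths (degrees) to calibrate; default the set's
#'   full grid.
#' @param noise_duration_s Duration of the calibration noise in seconds
#'   (default 5).
#' @param seed Integer seed for the noise.
#' @param variant Normalization variant, `"eq4"` or `"eq3"`.
#' @param window_ms STFT window in milliseconds.
#' @param energy_floor_db Void threshold passed to [disk_normalize()].
#' @return A `spiral_model`: `frequencies_hz`, `azimuths_deg`, complex
#'   `centers` matrix (frequency x azimuth), `variant`, and calibration
#'   `metadata`.
#' @export
calibrate_spiral <- function(hrirs, azimuth_grid = hrirs$azimuths_deg,
                             noise_duration_s = 5, seed = 1L,
                             variant = c("eq4", "eq3"), window_ms = 40,
                             energy_floor_db = -60) {
  stopifnot(inherits(hrirs, "hrir_set"))
  variant <- match.arg(variant)
  for (az in azimuth_grid) {
    if (!any(abs(hrirs$azimuths_deg - az) <= 1e-6)) {
      stop("azimuth ", az, " deg is not in the HRIR set; cannot calibrate")
    }
  }
  fs <- hrirs$sample_rate
  old <- local_seed(seed)
  noise <- stats::rnorm(round(noise_duration_s * fs))
  restore_seed(old)

  centers <- NULL
  freqs <- NULL
  for (j in seq_along(azimuth_grid)) {
    s <- spatialize(noise, get_hrir(hrirs, azimuth_grid[j]), fs)
    cloud <- disk_normalize(stft(s, window_ms = window_ms), variant,
                            energy_floor_db)
    if (is.null(centers)) {
      freqs <- cloud$grid$frequencies_hz
      centers <- matrix(NA_complex_, nrow = length(freqs),
                        ncol = length(azimuth_grid))
    }
    w <- cloud$energies
    w[cloud$void] <- 0
    p <- cloud$points
    p[cloud$void] <- 0
    centers[, j] <- rowSums(p * w) / pmax(rowSums(w), .Machine$double.xmin)
  }
  structure(list(frequencies_hz = freqs,
                 azimuths_deg = as.numeric(azimuth_grid),
                 centers = centers,
                 variant = variant,
                 metadata = list(noise_duration_s = noise_duration_s,
                                 seed = as.integer(seed),
                                 window_ms = window_ms,
                                 energy_floor_db = energy_floor_db,
                                 sample_rate = fs,
                                 hrir_source = hrirs$source)),
            class = "spiral_model")
}

#' @export
print.spiral_model <- function(x, ...) {
  cat(sprintf(paste0("<spiral_model> variant %s: %d frequencies ",
                     "[%g .. %g Hz] x %d azimuths [%g .. %g deg]\n"),
              x$variant, length(x$frequencies_hz), min(x$frequencies_hz),
              max(x$frequencies_hz), length(x$azimuths_deg),
              min(x$azimuths_deg), max(x$azimuths_deg)))
  cat(sprintf("  calibrated from %s (%g s noise, seed %d)\n",
              x$metadata$hrir_source, x$metadata$noise_duration_s,
              x$metadata$seed))
  invisible(x)
}

#' Look up a calibrated cluster center
#'
#' Exact stored value when the requested (frequency, azimuth) lies on the
#' calibration grid; otherwise the nearest grid azimuth (circular distance)
#' and nearest frequency bin are used - no interpolation across the disk,
#' since the spiral wraps and a chord between grid points can leave the
#' cluster locus entirely.
#'
#' @param model A `spiral_model`.
#' @param azimuth_deg Requested azimuth in degrees.
#' @param frequency_hz Requested frequency; must lie within the model's
#'   calibrated range.
#' @return A single complex center.
#' @export
model_point <- function(model, azimuth_deg, frequency_hz) {
  stopifnot(inherits(model, "spiral_model"))
  fr <- range(model$frequencies_hz)
  if (frequency_hz < fr[1] || frequency_hz > fr[2]) {
    stop("frequency ", frequency_hz, " Hz outside the model range [",
         fr[1], ", ", fr[2], "] Hz")
  }
  i <- which.min(abs(model$frequencies_hz - frequency_hz))
  j <- which.min(circ_dist_deg(model$azimuths_deg, azimuth_deg))
  model$centers[i, j]
}

# Circular azimuth distance in degrees.
circ_dist_deg <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Write a spiral model to a portable JSON file
#'
#' Versioned, self-describing plain-text serialization (complex centers are
#' stored as separate real/imaginary arrays).
#'
#' @param model A `spiral_model`.
#' @param path Output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
write_spiral_model <- function(model, path) {
  stopifnot(inherits(model, "spiral_model"))
  payload <- list(
    format = "spiralsep-model",
    version = 1L,
    variant = model$variant,
    frequencies_hz = model$frequencies_hz,
    azimuths_deg = model$azimuths_deg,
    n_frequencies = nrow(model$centers),
    n_azimuths = ncol(model$centers),
    centers_re = as.vector(Re(model$centers)),   # column-major
    centers_im = as.vector(Im(model$centers)),
    metadata = model$metadata
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a spiral model written by [write_spiral_model()]
#'
#' @param path Path to the JSON model file.
#' @return A `spiral_model`.
#' @export
read_spiral_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "spiralsep-model")) {
    stop(path, " is not a spiralsep model file")
  }
  structure(list(frequencies_hz = as.numeric(p$frequencies_hz),
                 azimuths_deg = as.numeric(p$azimuths_deg),
                 centers = matrix(complex(real = as.numeric(p$centers_re),
                                          imaginary = as.numeric(p$centers_im)),
                                  nrow = p$n_frequencies),
                 variant = p$variant,
                 metadata = p$metadata),
            class = "spiral_model")
}

#' Plot the spiral loci at selected frequencies
#'
#' One unit-disk panel per frequency showing the calibrated cluster centers
#' as azimuth sweeps across the grid, colored from left (blue) to right
#' (red).
#'
#' @param model A `spiral_model`.
#' @param frequencies_hz Frequencies to display (nearest bins are used).
#' @param ... Passed to [graphics::plot()].
#' @return The model, invisibly.
#' @export
plot_spiral <- function(model, frequencies_hz = c(200, 500, 1000, 2000),
                        ...) {
  stopifnot(inherits(model, "spiral_model"))
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(frequencies_hz)),
                       mar = c(2.5, 2.5, 2, 0.5), mgp = c(1.5, 0.5, 0))
  on.exit(graphics::par(old))
  th <- seq(0, 2 * pi, length.out = 181)
  cols <- grDevices::colorRampPalette(c("navy", "grey70", "firebrick"))(
    length(model$azimuths_deg))
  for (f in frequencies_hz) {
    i <- which.min(abs(model$frequencies_hz - f))
    z <- model$centers[i, ]
    graphics::plot(cos(th), sin(th), type = "l", col = "grey60", asp = 1,
                   xlab = "Real", ylab = "Imag",
                   main = sprintf("%g Hz", model$frequencies_hz[i]), ...)
    graphics::lines(Re(z), Im(z), col = "grey85")
    graphics::points(Re(z), Im(z), pch = 19, col = cols)
  }
  invisible(model)
}
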