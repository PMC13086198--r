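#' Map a stereo spectrogram into the closed unit disk
#'
#' The core feature transform: each time-frequency bin `(X_L, X_R)` becomes
#' one complex point
#'
#' * right-referenced variant (`"eq3"`):
#'   `X_R * exp(-i * phase(X_L)) / sqrt(|X_L|^2 + |X_R|^2)`
#' * left-referenced variant (`"eq4"`): the same with L and R swapped.
#'
#' The denominator confines every point to the closed unit disk. The phase
#' of the point equals the interaural phase difference (R minus L for
#' `"eq3"`, L minus R for `"eq4"`), so an interaural delay turns the point
#' counterclockwise; the modulus encodes the interaural level difference:
#' under `"eq3"` a left-louder bin lies near the origin and a right-louder
#' bin approaches the unit circle (roles swapped under `"eq4"`). With a
#' single active source per bin the source waveform cancels exactly and the
#' point depends only on the head filter at that frequency - this is what
#' makes the clusters tight and the spiral model possible.
#'
#' Bins whose energy `|X_L|^2 + |X_R|^2` falls below `energy_floor_db`
#' relative to the loudest bin are marked *void* (NA point): they carry
#' negligible energy and are exempted from clustering and masking.
#'
#' @param spec A `stereo_spectrogram` from [stft()].
#' @param variant `"eq3"` (right-referenced) or `"eq4"` (left-referenced).
#' @param energy_floor_db Void threshold in dB relative to the maximum bin
#'   energy (default -60).
#' @return A `normalized_cloud`: complex matrix `points` (NA where void),
#'   logical matrix `void`, numeric matrix `energies`, plus `variant` and
#'   the `tf_grid`.
#' @export
disk_normalize <- function(spec, variant = c("eq4", "eq3"),
                           energy_floor_db = -60) {
  stopifnot(inherits(spec, "stereo_spectrogram"))
  variant <- match.arg(variant)
  if (!all(is.finite(Re(spec$X_L))) || !all(is.finite(Re(spec$X_R)))) {
    stop("spectrogram contains non-finite values")
  }
  E <- Mod(spec$X_L)^2 + Mod(spec$X_R)^2
  floor_lin <- max(E) * 10^(energy_floor_db / 10)
  void <- E <= floor_lin | E == 0
  denom <- sqrt(E)
  denom[void] <- 1  # never divide by ~zero; points are voided anyway
  if (variant == "eq3") {
    ref_phase <- Arg(spec$X_L)   # Arg(0+0i) is 0 by definition here
    pts <- spec$X_R * exp(-1i * ref_phase) / denom
  } else {
    ref_phase <- Arg(spec$X_R)
    pts <- spec$X_L * exp(-1i * ref_phase) / denom
  }
  pts[void] <- NA_complex_
  structure(list(points = pts, void = void, energies = E,
                 variant = variant, grid = spec$grid),
            class = "normalized_cloud")
}

#' @export
print.normalized_cloud <- function(x, ...) {
  cat(sprintf("<normalized_cloud> variant %s, %d bins x %d frames, %.1f%% void\n",
              x$variant, nrow(x$points), ncol(x$points),
              100 * mean(x$void)))
  invisible(x)
}

#' Choose the normalization variant from the scene geometry
#'
#' The interferer's cluster must sit in the *compact* half of the disk to be
#' removable; that is the left-referenced variant (`"eq4"`) when the
#' interferer is to the right of the target and the right-referenced
#' variant (`"eq3"`) otherwise.
#'
#' @param target_azimuth_deg,interferer_azimuth_deg Azimuths in degrees.
#' @return `"eq4"` or `"eq3"`.
#' @export
choose_variant <- function(target_azimuth_deg, interferer_azimuth_deg) {
  if (interferer_azimuth_deg > target_azimuth_deg) "eq4" else "eq3"
}
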