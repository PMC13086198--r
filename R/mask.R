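#' Mask parameters
#'
#' @param radius Circle radius in disk distance around the interferer's
#'   model point (default 0.2).
#' @param mode `"hard"` (inside gain 0) or `"soft"` (inside gain
#'   `soft_gain`).
#' @param soft_gain Linear amplitude factor for soft masking, in (0, 1);
#'   the default 0.2 is about a 14-dB attenuation.
#' @param safeguard `"on"` or `"off"`: when on, frequencies whose clusters
#'   are judged single-cluster by [check_separability()] are left unmasked,
#'   because removing the only cluster removes target and interferer alike.
#' @param max_frequency_hz Ceiling for mask logic; bins above it always get
#'   gain 1. The default 16 kHz covers the full analysis range; 4 kHz is a
#'   practical choice since speech energy is mostly below 4 kHz.
#' @param outside_threshold Energy fraction threshold for the safeguard's
#'   outside-the-circle criterion.
#' @return A `mask_spec` list.
#' @export
mask_spec <- function(radius = 0.2, mode = c("hard", "soft"),
                      soft_gain = 0.2, safeguard = c("on", "off"),
                      max_frequency_hz = 16000, outside_threshold = 0.10) {
  mode <- match.arg(mode)
  safeguard <- match.arg(safeguard)
  if (!(radius > 0 && radius < 1)) stop("radius must be in (0, 1)")
  if (mode == "soft" && !(soft_gain > 0 && soft_gain < 1)) {
    stop("soft_gain must be in (0, 1)")
  }
  structure(list(radius = radius, mode = mode,
                 soft_gain = if (mode == "hard") 0 else soft_gain,
                 safeguard = safeguard,
                 max_frequency_hz = max_frequency_hz,
                 outside_threshold = outside_threshold),
            class = "mask_spec")
}

#' Build a time-frequency mask around the interferer's model points
#'
#' For every analysis frequency up to the ceiling, the interferer's
#' calibrated cluster center `c(f)` is looked up with [model_point()]; a
#' bin whose normalized point lies strictly inside the circle of the given
#' radius around `c(f)` receives the inside gain (0 for a hard mask,
#' `soft_gain` for a soft one), every other bin gain 1. Membership is
#' strict (`<`), so boundary points are kept. Void bins always get gain 1:
#' they carry negligible energy and zeroing them only risks musical noise.
#'
#' With the safeguard on, each frequency is first clustered (k = 2,
#' energy-weighted) and checked with [check_separability()]; single-cluster
#' frequencies are left fully unmasked and recorded in
#' `per_frequency_active`.
#'
#' @param cloud A `normalized_cloud` of the mixture.
#' @param model A `spiral_model` with the same variant.
#' @param interferer_azimuth_deg Azimuth of the source to remove (degrees,
#'   on or near the model grid).
#' @param spec A [mask_spec()].
#' @param seed Seed for the safeguard's clustering.
#' @return A `tf_mask`: `gains` matrix over the grid,
#'   `per_frequency_active` logical vector (FALSE where the safeguard
#'   disabled masking), the `mask_spec`, and the grid.
#' @export
build_mask <- function(cloud, model, interferer_azimuth_deg,
                       spec = mask_spec(), seed = 1L) {
  stopifnot(inherits(cloud, "normalized_cloud"),
            inherits(model, "spiral_model"),
            inherits(spec, "mask_spec"))
  if (!identical(cloud$variant, model$variant)) {
    stop("variant mismatch: cloud is ", cloud$variant, ", model is ",
         model$variant)
  }
  freqs <- cloud$grid$frequencies_hz
  gains <- matrix(1, nrow = nrow(cloud$points), ncol = ncol(cloud$points))
  active <- rep(NA, length(freqs))
  inside_gain <- if (spec$mode == "hard") 0 else spec$soft_gain
  fidx <- which(freqs >= 25 & freqs <= min(spec$max_frequency_hz, 16000) &
                freqs >= min(model$frequencies_hz) &
                freqs <= max(model$frequencies_hz))
  for (i in fidx) {
    sel <- !cloud$void[i, ]
    if (!any(sel)) { active[i] <- TRUE; next }  # nothing energetic to mask
    cf <- model_point(model, interferer_azimuth_deg, freqs[i])
    z <- cloud$points[i, sel]
    w <- cloud$energies[i, sel]
    inside <- Mod(z - cf) < spec$radius
    if (spec$safeguard == "on") {
      flag <- if (sum(sel) >= 4) {
        km <- wkmeans(z, w, 2L, seed = (seed + i) %% .Machine$integer.max,
                      restarts = 5L)
        out_frac <- sum(w[Mod(z - cf) >= spec$radius]) / sum(w)
        check_separability(km$centers_z, spec$radius, out_frac,
                           spec$outside_threshold)
      } else "single_cluster"
      if (flag == "single_cluster") { active[i] <- FALSE; next }
    }
    active[i] <- TRUE
    row <- rep(1, ncol(gains))
    row[which(sel)[inside]] <- inside_gain
    gains[i, ] <- row
  }
  structure(list(gains = gains, spec = spec,
                 per_frequency_active = active,
                 frequencies_hz = freqs, grid = cloud$grid),
            class = "tf_mask")
}

#' @export
print.tf_mask <- function(x, ...) {
  n_act <- sum(x$per_frequency_active, na.rm = TRUE)
  n_saf <- sum(!x$per_frequency_active, na.rm = TRUE)
  cat(sprintf(paste0("<tf_mask> %s mask (radius %g, inside gain %g): ",
                     "%.1f%% of bins attenuated; %d frequencies masked, ",
                     "%d left unmasked\n"),
              x$spec$mode, x$spec$radius, x$spec$soft_gain,
              100 * mean(x$gains < 1), n_act, n_saf))
  invisible(x)
}

#' Apply a time-frequency mask to a mixture spectrogram
#'
#' Element-wise multiplication of both channels' *original* (un-normalized)
#' STFT matrices by the gain matrix. The normalized cloud is only ever used
#' to decide which bins to touch; no "inverse normalization" exists or is
#' needed - reconstruction goes straight through [istft()] on the masked
#' mixture STFT.
#'
#' @param mixture A `stereo_spectrogram`.
#' @param mask A `tf_mask` on the same grid.
#' @return The masked `stereo_spectrogram`.
#' @export
apply_mask <- function(mixture, mask) {
  stopifnot(inherits(mixture, "stereo_spectrogram"),
            inherits(mask, "tf_mask"))
  if (!all(dim(mixture$X_L) == dim(mask$gains))) {
    stop("mask and spectrogram shapes differ")
  }
  mixture$X_L <- mixture$X_L * mask$gains
  mixture$X_R <- mixture$X_R * mask$gains
  mixture
}

#' End-to-end segregation of a binaural scene
#'
#' The full pipeline: [stft()] of the mixture, [disk_normalize()] with the
#' model's variant, [build_mask()] around the interferer's azimuth,
#' [apply_mask()] on the original mixture STFT, and [istft()] back to the
#' time domain. The mono output (left + right sum) mirrors the convention
#' that downstream recognition consumes a monophonic stream.
#'
#' @param scene A [stereo_signal()] mixture.
#' @param model A `spiral_model`.
#' @param interferer_azimuth_deg Azimuth of the source to remove.
#' @param spec A [mask_spec()].
#' @param energy_floor_db Void threshold for [disk_normalize()].
#' @param window_ms STFT window in milliseconds.
#' @param seed Seed for the safeguard clustering.
#' @return A `segregation_result`: `audio` (masked [stereo_signal()]),
#'   `mono` (numeric vector), `mask` (`tf_mask`), `mixture_spec`,
#'   `masked_spec`, and `diagnostics` (per-frequency masked-bin counts,
#'   fraction of total energy removed, safeguard activations).
#' @export
segregate <- function(scene, model, interferer_azimuth_deg,
                      spec = mask_spec(), energy_floor_db = -60,
                      window_ms = 40, seed = 1L) {
  stopifnot(inherits(scene, "stereo_signal"),
            inherits(model, "spiral_model"))
  mix_spec <- stft(scene, window_ms = window_ms)
  cloud <- disk_normalize(mix_spec, model$variant, energy_floor_db)
  mask <- build_mask(cloud, model, interferer_azimuth_deg, spec, seed)
  masked <- apply_mask(mix_spec, mask)
  audio <- istft(masked)
  e_in <- spec_energy(mix_spec)
  e_out <- spec_energy(masked)
  diagnostics <- list(
    masked_bins_per_frequency = rowSums(mask$gains < 1),
    energy_removed_fraction = 1 - e_out / e_in,
    safeguard_unmasked_frequencies =
      sum(!mask$per_frequency_active, na.rm = TRUE),
    analyzed_frequencies = sum(!is.na(mask$per_frequency_active)),
    variant = model$variant,
    interferer_azimuth_deg = interferer_azimuth_deg
  )
  structure(list(audio = audio, mono = audio$left + audio$right,
                 mask = mask, mixture_spec = mix_spec,
                 masked_spec = masked, diagnostics = diagnostics),
            class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(paste0("<segregation_result> interferer %+g deg (%s): ",
                     "%.1f%% of energy removed; safeguard unmasked %d/%d ",
                     "frequencies\n"),
              d$interferer_azimuth_deg, x$mask$spec$mode,
              100 * d$energy_removed_fraction,
              d$safeguard_unmasked_frequencies, d$analyzed_frequencies))
  invisible(x)
}
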