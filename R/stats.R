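#' Normal-approximation confidence interval for a proportion
#'
#' Half-width `coefficient * sqrt(a_hat * (1 - a_hat) / n)`. With the
#' default coefficient 1.960 this is the 95% interval (two-sided normal
#' tail probability .05). Because open-set sentence recognition has no
#' nonzero chance level, a score is "significantly above zero" exactly
#' when the interval's lower boundary is above zero.
#'
#' @param a_hat Proportion correct in `[0, 1]`.
#' @param n Number of scored items (e.g. 100 key words per sentence group).
#' @param coefficient Normal critical value (default 1.960).
#' @return A `score_stats` list: `a_hat`, `n`, `ci_half_width`,
#'   `coefficient`, `alpha` (the two-sided tail probability implied by the
#'   coefficient), and `above_zero`.
#' @examples
#' proportion_ci(0.5, 100)$ci_half_width  # 0.098
#' @export
proportion_ci <- function(a_hat, n, coefficient = 1.960) {
  stopifnot(a_hat >= 0, a_hat <= 1, n >= 1, coefficient >= 0)
  half <- coefficient * sqrt(a_hat * (1 - a_hat) / n)
  structure(list(a_hat = a_hat, n = n, ci_half_width = half,
                 coefficient = coefficient,
                 alpha = 2 * stats::pnorm(-coefficient),
                 above_zero = (a_hat - half) > 0),
            class = "score_stats")
}

#' @export
print.score_stats <- function(x, ...) {
  cat(sprintf("<score_stats> %.1f%% +/- %.1f (n = %d)%s\n",
              100 * x$a_hat, 100 * x$ci_half_width, x$n,
              if (x$above_zero) ", significantly above zero" else ""))
  invisible(x)
}

#' Two-proportion z test
#'
#' Tests `H0: a1 = a2` for two recognition scores observed on the same
#' number of items, with the unpooled variance
#' `z = (a1 - a2) / sqrt(a1 (1 - a1)/n + a2 (1 - a2)/n)` and a two-sided
#' normal p value. When both proportions are degenerate (0 or 1) the
#' unpooled denominator vanishes; the pooled-variance form is then used
#' and flagged.
#'
#' @param a1,a2 Proportions in `[0, 1]`.
#' @param n Per-group item count.
#' @param alpha_adjusted Significance level after any multiple-comparison
#'   correction (see [bonferroni_alpha()]).
#' @param pooled Force the pooled-variance denominator.
#' @return A `z_test_result`: `a1`, `a2`, `n`, `z`, `p_two_sided`,
#'   `alpha_adjusted`, `significant`, `pooled_fallback`.
#' @examples
#' two_proportion_z(0.64, 0.45, 100)$p_two_sided  # ~= .006
#' @export
two_proportion_z <- function(a1, a2, n, alpha_adjusted = 0.05,
                             pooled = FALSE) {
  stopifnot(a1 >= 0, a1 <= 1, a2 >= 0, a2 <= 1, n >= 1)
  se_unpooled <- sqrt(a1 * (1 - a1) / n + a2 * (1 - a2) / n)
  fallback <- FALSE
  if (pooled || se_unpooled == 0) {
    p_bar <- (a1 + a2) / 2
    se <- sqrt(p_bar * (1 - p_bar) * 2 / n)
    fallback <- !pooled
  } else {
    se <- se_unpooled
  }
  z <- if (a1 == a2) 0 else (a1 - a2) / se
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(a1 = a1, a2 = a2, n = n, z = z, p_two_sided = p,
                 alpha_adjusted = alpha_adjusted,
                 significant = p < alpha_adjusted,
                 pooled_fallback = fallback),
            class = "z_test_result")
}

#' @export
print.z_test_result <- function(x, ...) {
  cat(sprintf("<z_test_result> a1 = %.3f vs a2 = %.3f (n = %d): z = %.3f, p = %.4g%s%s\n",
              x$a1, x$a2, x$n, x$z, x$p_two_sided,
              if (x$significant) sprintf(" < %.4g *", x$alpha_adjusted) else "",
              if (x$pooled_fallback) " [pooled fallback]" else ""))
  invisible(x)
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha Family-wise level (default 0.05).
#' @param m Number of comparisons sharing the same control (e.g. 6
#'   processed-versus-control geometries).
#' @return `alpha / m`.
#' @examples
#' bonferroni_alpha(0.05, 6)
#' @export
bonferroni_alpha <- function(alpha = 0.05, m) {
  stopifnot(alpha > 0, alpha <= 1, m >= 1)
  alpha / m
}

#' Score a transcript against a key-word list
#'
#' Case-insensitive, punctuation-stripped, order-free greedy matching:
#' every key word is consumed at most once, and each transcript word can
#' satisfy at most one key word. The score is matches divided by the
#' number of key words.
#'
#' @param transcript Character string (the recognizer output).
#' @param key_words Character vector of key words (order-free).
#' @param ignore_plural_s If `TRUE`, a trailing "s" mismatch between a key
#'   word and a transcript word is forgiven. Default is exact word match.
#' @param n Item count used for the confidence interval; defaults to the
#'   number of key words.
#' @return A `score_stats` (see [proportion_ci()]) whose `a_hat` is the
#'   fraction of key words found.
#' @examples
#' keyword_score("the park opens in eleven months",
#'               c("PARK", "OPENS", "ELEVEN", "MONTHS"))$a_hat
#' @export
keyword_score <- function(transcript, key_words, ignore_plural_s = FALSE,
                          n = length(key_words)) {
  stopifnot(length(key_words) >= 1)
  clean <- function(x) {
    x <- tolower(x)
    x <- gsub("[^a-z0-9' ]+", " ", x)
    strsplit(trimws(gsub(" +", " ", x)), " ")[[1]]
  }
  tw <- clean(paste(transcript, collapse = " "))
  kw <- clean(paste(key_words, collapse = " "))
  matches <- 0L
  for (k in kw) {
    hit <- which(tw == k)
    if (length(hit) == 0L && ignore_plural_s) {
      hit <- which(tw == paste0(k, "s") | paste0(tw, "s") == k)
    }
    if (length(hit) > 0L) {
      matches <- matches + 1L
      tw <- tw[-hit[1]]
    }
  }
  proportion_ci(matches / length(kw), n)
}

#' Oracle ideal binary mask from reference sources
#'
#' Keeps exactly the bins where the target's mono energy meets or exceeds
#' the interferer's - the ceiling reference for mask-based separation.
#'
#' @param target_spec,interferer_spec `stereo_spectrogram`s of the
#'   references on the same grid.
#' @return Logical matrix, `TRUE` where the target dominates.
#' @export
ideal_binary_mask <- function(target_spec, interferer_spec) {
  et <- Mod(target_spec$X_L + target_spec$X_R)^2
  ei <- Mod(interferer_spec$X_L + interferer_spec$X_R)^2
  et >= ei
}

#' Objective separation metrics against reference sources
#'
#' Replaces recognition scoring with energy bookkeeping computed from the
#' clean references (which a simulation, unlike a hearing aid, has).
#' All energies are computed on the mono (left + right) sum, mirroring the
#' monophonic recognition convention.
#'
#' @param mask A `tf_mask` produced for the mixture.
#' @param target_ref,interferer_ref Clean [stereo_signal()] references
#'   (spatialized, *as mixed*: include any SNR gain).
#' @param window_ms STFT window in milliseconds.
#' @param energy_floor_db Bins within this many dB of the loudest reference
#'   bin count as energetic for the mask-agreement metric.
#' @return A `separation_metrics` list:
#'   `interferer_residual_db` (energy of the masked interferer passthrough
#'   re the original interferer, dB), `target_preservation` (retained
#'   target energy fraction), `mask_agreement` (fraction of energetic bins
#'   classified identically to the ideal binary mask),
#'   `snr_improvement_db` (broadband output SNR minus input SNR).
#' @export
separation_metrics <- function(mask, target_ref, interferer_ref,
                               window_ms = 40, energy_floor_db = -60) {
  stopifnot(inherits(mask, "tf_mask"))
  st <- stft(target_ref, window_ms = window_ms)
  si <- stft(interferer_ref, window_ms = window_ms)
  nf <- min(ncol(st$X_L), ncol(si$X_L), ncol(mask$gains))
  g <- mask$gains[, seq_len(nf), drop = FALSE]
  et <- Mod(st$X_L + st$X_R)[, seq_len(nf), drop = FALSE]^2
  ei <- Mod(si$X_L + si$X_R)[, seq_len(nf), drop = FALSE]^2
  res_db <- 10 * log10(sum(g^2 * ei) / sum(ei))
  preserve <- sum(g^2 * et) / sum(et)
  ibm_keep <- et >= ei
  mask_keep <- g >= 1
  energetic <- (et + ei) > max(et + ei) * 10^(energy_floor_db / 10)
  agreement <- mean(mask_keep[energetic] == ibm_keep[energetic])
  snr_in <- 10 * log10(sum(et) / sum(ei))
  snr_out <- 10 * log10(sum(g^2 * et) / sum(g^2 * ei))
  structure(list(interferer_residual_db = res_db,
                 target_preservation = preserve,
                 mask_agreement = agreement,
                 snr_improvement_db = snr_out - snr_in),
            class = "separation_metrics")
}

#' @export
print.separation_metrics <- function(x, ...) {
  cat(sprintf(paste0("<separation_metrics> interferer residual %.1f dB, ",
                     "target preserved %.1f%%, mask agreement %.1f%%, ",
                     "SNR improvement %+.1f dB\n"),
              x$interferer_residual_db, 100 * x$target_preservation,
              100 * x$mask_agreement, x$snr_improvement_db))
  invisible(x)
}
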