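# Energy-weighted k-means on 2-D points with seeded k-means++ restarts.
# stats::kmeans has no observation weights, and the clustering here must be
# energy-weighted so a handful of loud bins dominates diffuse leakage.
# Returns centers ordered lexicographically by (Re, Im) so that, at equal
# inertia, labels are deterministic.
wkmeans <- function(z, w, k, seed = 1L, restarts = 10L, iter_max = 30L) {
  n <- length(z)
  stopifnot(n >= k, length(w) == n, all(w >= 0))
  X <- cbind(Re(z), Im(z))
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- kmeanspp_init(X, w, k)
    for (it in seq_len(iter_max)) {
      d2 <- dist2_to_centers(X, centers)
      lab <- max.col(-d2, ties.method = "first")
      new_centers <- centers
      for (j in seq_len(k)) {
        in_j <- lab == j
        wj <- sum(w[in_j])
        if (wj > 0) {
          new_centers[j, ] <- colSums(X[in_j, , drop = FALSE] * w[in_j]) / wj
        } else {
          # empty cluster: reseed at the point farthest from its center
          far <- which.max(d2[cbind(seq_len(n), lab)] * w)
          new_centers[j, ] <- X[far, ]
        }
      }
      if (max(abs(new_centers - centers)) < 1e-12) { centers <- new_centers; break }
      centers <- new_centers
    }
    d2 <- dist2_to_centers(X, centers)
    lab <- max.col(-d2, ties.method = "first")
    inertia <- sum(w * d2[cbind(seq_len(n), lab)])
    if (is.null(best) || inertia < best$inertia - 1e-15) {
      best <- list(centers = centers, labels = lab, inertia = inertia)
    }
  }
  ord <- order(best$centers[, 1], best$centers[, 2])
  best$centers <- best$centers[ord, , drop = FALSE]
  best$labels <- match(best$labels, ord)
  best$centers_z <- complex(real = best$centers[, 1],
                            imaginary = best$centers[, 2])
  best
}

kmeanspp_init <- function(X, w, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L, prob = w + .Machine$double.xmin)
  if (k > 1) {
    for (j in 2:k) {
      d2 <- dist2_to_centers(X, X[idx[seq_len(j - 1)], , drop = FALSE])
      mind2 <- apply(d2, 1, min)
      p <- w * mind2
      if (sum(p) <= 0) p <- rep(1, n)
      idx[j] <- sample.int(n, 1L, prob = p)
    }
  }
  X[idx, , drop = FALSE]
}

dist2_to_centers <- function(X, C) {
  outer(X[, 1], C[, 1], "-")^2 + outer(X[, 2], C[, 2], "-")^2
}

#' Judge whether two cluster centers are separable
#'
#' The safeguard test: a frequency is flagged `"single_cluster"` when the
#' two candidate centers are closer than one circle diameter
#' (`2 * radius`), or when only a small fraction of the bin energy lies
#' outside the candidate interferer circle (so "removing the cluster" would
#' remove essentially everything). A single-cluster frequency must not be
#' masked.
#'
#' @param cluster_centers Complex vector of (typically two) cluster
#'   centers.
#' @param radius Mask circle radius in disk distance (default 0.2).
#' @param outside_fraction Measured fraction of energy outside the
#'   candidate interferer circle; pass `NA` to skip this criterion.
#' @param outside_threshold Minimum outside-energy fraction required to
#'   call the geometry separable (default 0.10).
#' @return `"separable"` or `"single_cluster"`.
#' @examples
#' check_separability(c(0.1 + 0i, 0.15 + 0i), radius = 0.2,
#'                    outside_fraction = 0.4)
#' @export
check_separability <- function(cluster_centers, radius = 0.2,
                               outside_fraction = NA,
                               outside_threshold = 0.10) {
  cc <- as.complex(cluster_centers)
  if (length(cc) >= 2) {
    dmin <- min(Mod(outer(cc, cc, "-"))[lower.tri(diag(length(cc)))])
    if (dmin < 2 * radius) return("single_cluster")
  }
  if (!is.na(outside_fraction) && outside_fraction < outside_threshold) {
    return("single_cluster")
  }
  "separable"
}

#' Localize concurrent sources from a normalized cloud
#'
#' Per analysis frequency, the non-void disk points are clustered with
#' energy-weighted k-means (`k` clusters, seeded k-means++ with
#' `restarts` restarts); each cluster center is matched to the nearest
#' model azimuth at that frequency, casting a vote weighted by the
#' cluster's energy. The per-source azimuth estimates are the `k` azimuths
#' with the largest total vote energy (an energy-weighted mode across
#' frequencies; `aggregate = "median"` takes the weighted median of the
#' votes instead). Each frequency also receives a separability flag from
#' [check_separability()].
#'
#' @param cloud A `normalized_cloud`.
#' @param model A `spiral_model` with the same variant.
#' @param k Number of sources to localize (>= 1).
#' @param seed Integer seed for the k-means restarts.
#' @param restarts k-means++ restarts per frequency.
#' @param min_bins Minimum non-void bins for a frequency to participate.
#' @param radius Circle radius used by the separability flag.
#' @param aggregate `"mode"` (default) or `"median"`.
#' @return A `localization_result`: `azimuth_estimates_deg` (sorted,
#'   length `k`), `votes` (data frame of per-frequency matches),
#'   `separability` (named character vector per analyzed frequency),
#'   `per_frequency_assignments`, `cluster_centers`.
#' @export
locate_sources <- function(cloud, model, k = 2L, seed = 1L, restarts = 10L,
                           min_bins = max(2L * k, 6L), radius = 0.2,
                           aggregate = c("mode", "median")) {
  stopifnot(inherits(cloud, "normalized_cloud"),
            inherits(model, "spiral_model"), k >= 1)
  aggregate <- match.arg(aggregate)
  if (!identical(cloud$variant, model$variant)) {
    stop("variant mismatch: cloud is ", cloud$variant, ", model is ",
         model$variant)
  }
  freqs <- cloud$grid$frequencies_hz
  fidx <- which(freqs >= 25 & freqs <= max(model$frequencies_hz) &
                freqs <= 16000)
  counts <- rowSums(!cloud$void)
  fidx <- fidx[counts[fidx] >= max(min_bins, k)]
  if (length(fidx) == 0L) {
    stop("no frequency has at least ", max(min_bins, k),
         " non-void bins; cannot cluster")
  }
  votes_az <- numeric(0); votes_w <- numeric(0); votes_f <- numeric(0)
  separability <- character(length(fidx))
  assignments <- vector("list", length(fidx))
  centers_out <- vector("list", length(fidx))
  for (ii in seq_along(fidx)) {
    i <- fidx[ii]
    sel <- !cloud$void[i, ]
    z <- cloud$points[i, sel]
    w <- cloud$energies[i, sel]
    km <- wkmeans(z, w, k, seed = (seed + i) %% .Machine$integer.max,
                  restarts = restarts)
    mi <- which.min(abs(model$frequencies_hz - freqs[i]))
    az_match <- vapply(km$centers_z, function(cz) {
      model$azimuths_deg[which.min(Mod(model$centers[mi, ] - cz))]
    }, numeric(1))
    cl_energy <- vapply(seq_len(k), function(j) sum(w[km$labels == j]),
                        numeric(1))
    votes_az <- c(votes_az, az_match)
    votes_w <- c(votes_w, cl_energy)
    votes_f <- c(votes_f, rep(freqs[i], k))
    out_frac <- if (k >= 2) {
      # energy outside the circle around the weaker cluster's center
      weak <- km$centers_z[which.min(cl_energy)]
      sum(w[Mod(z - weak) >= radius]) / sum(w)
    } else NA
    separability[ii] <- check_separability(km$centers_z, radius, out_frac)
    assignments[[ii]] <- km$labels
    centers_out[[ii]] <- km$centers_z
  }
  names(separability) <- names(assignments) <- names(centers_out) <-
    sprintf("%g", freqs[fidx])
  tab <- tapply(votes_w, votes_az, sum)
  az_lv <- as.numeric(names(tab))
  est <- if (aggregate == "mode") {
    sort(az_lv[order(tab, decreasing = TRUE)][seq_len(min(k, length(tab)))])
  } else {
    o <- order(votes_az)
    cw <- cumsum(votes_w[o]) / sum(votes_w)
    sort(vapply(seq_len(k), function(j) {
      votes_az[o][which(cw >= (j - 0.5) / k)[1]]
    }, numeric(1)))
  }
  if (length(est) < k) est <- c(est, rep(est[length(est)], k - length(est)))
  structure(list(azimuth_estimates_deg = est,
                 votes = data.frame(frequency_hz = votes_f,
                                    azimuth_deg = votes_az,
                                    energy = votes_w),
                 separability = separability,
                 per_frequency_assignments = assignments,
                 cluster_centers = centers_out),
            class = "localization_result")
}

#' @export
print.localization_result <- function(x, ...) {
  cat(sprintf("<localization_result> %d source(s): %s deg; %d/%d frequencies single-cluster\n",
              length(x$azimuth_estimates_deg),
              paste(sprintf("%+g", x$azimuth_estimates_deg), collapse = ", "),
              sum(x$separability == "single_cluster"),
              length(x$separability)))
  invisible(x)
}
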