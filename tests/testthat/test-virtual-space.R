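test_that("synthetic HRIRs have the spherical-head cue structure", {
  fs <- 32100
  # frontal source: both ears identical, zero ITD/ILD
  h0 <- synth_hrir(0, sample_rate = fs)
  expect_equal(h0$left, h0$right, tolerance = 1e-14)
  expect_identical(h0$itd_s, 0)

  # left/right mirror pairs swap ears exactly, for every azimuth
  for (az in c(10, 35, 60, 90, 120, 175)) {
    hp <- synth_hrir(az, sample_rate = fs)
    hm <- synth_hrir(-az, sample_rate = fs)
    expect_identical(hp$left, hm$right)
    expect_identical(hp$right, hm$left)
  }

  # broadband cross-correlation lag matches the Woodworth ITD within one
  # sample over the whole frontal sweep
  for (az in seq(-90, 90, by = 10)) {
    h <- synth_hrir(az, sample_rate = fs)
    cc <- stats::ccf(h$right, h$left, lag.max = 40, plot = FALSE)
    lag <- cc$lag[which.max(cc$acf)]
    expect_lte(abs(-lag - woodworth_itd(az) * fs), 1)
  }

  # ILD: far-ear shadow grows monotonically toward the side at fixed
  # frequency above 500 Hz; zero at the front
  gain_at <- function(az, f) {
    h <- synth_hrir(az, sample_rate = fs)
    k <- length(h$left)
    i <- round(f / fs * k) + 1
    HL <- fft(h$left)[i]; HR <- fft(h$right)[i]
    20 * log10(Mod(HR) / Mod(HL))
  }
  for (f in c(1000, 2000, 8000)) {
    ilds <- vapply(c(0, 20, 40, 60, 90), gain_at, numeric(1), f = f)
    expect_equal(ilds[1], 0, tolerance = 1e-8)
    expect_true(all(diff(ilds) > 0))
  }

  # front/back pairs on the same confusion cone are distinguishable
  h60 <- synth_hrir(60, sample_rate = fs)
  h120 <- synth_hrir(120, sample_rate = fs)
  expect_equal(h60$itd_s, h120$itd_s)
  expect_gt(max(abs(h60$left - h120$left)), 1e-4)

  expect_error(synth_hrir(200), "180")
  expect_error(synth_hrir(NaN), "finite")
})

test_that("spatialization is exact convolution and linear", {
  fs <- 32100
  set.seed(4)
  x <- rnorm(500)
  # identity kernel
  delta <- c(1, numeric(31))
  s <- spatialize(x, list(left = delta, right = delta, sample_rate = fs), fs)
  expect_equal(s$left[seq_along(x)], x, tolerance = 1e-12)
  expect_equal(s$right, s$left)
  expect_equal(n_samples(s), length(x) + length(delta) - 1L)

  # shift kernel: right delayed by d samples relative to left
  d <- 7L
  s2 <- spatialize(x, list(left = delta,
                           right = c(numeric(d), 1, numeric(31 - d)),
                           sample_rate = fs), fs)
  expect_equal(s2$right[(d + 1):(d + length(x))], x, tolerance = 1e-12)

  # linearity
  y <- rnorm(500)
  h <- synth_hrir(40, sample_rate = fs)
  sx <- spatialize(x, h, fs); sy <- spatialize(y, h, fs)
  sxy <- spatialize(2 * x - 3 * y, h, fs)
  expect_equal(sxy$left, 2 * sx$left - 3 * sy$left, tolerance = 1e-10)

  # interaural cross-correlation of spatialized noise peaks at the
  # Woodworth lag
  set.seed(5)
  n <- rnorm(fs / 2)
  s3 <- spatialize(n, synth_hrir(60, sample_rate = fs), fs)
  cc <- stats::ccf(s3$right, s3$left, lag.max = 40, plot = FALSE)
  expect_lte(abs(-cc$lag[which.max(cc$acf)] - woodworth_itd(60) * fs), 1)

  expect_error(spatialize(x, synth_hrir(0, sample_rate = 44100), fs),
               "mismatch")
  expect_error(spatialize(numeric(0), h, fs), "non-empty")
})

test_that("time reversal is an energy-preserving involution", {
  expect_equal(time_reverse(c(1, 2, 3)), c(3, 2, 1))
  set.seed(9)
  x <- rnorm(1000)
  expect_identical(time_reverse(time_reverse(x)), x)
  expect_identical(sum(time_reverse(x)^2), sum(x^2))
})

test_that("scene mixing controls SNR through RMS equalization", {
  fs <- 32100
  set.seed(2)
  t <- stereo_signal(rnorm(4000, sd = 2), rnorm(4000, sd = 2), fs)
  i <- stereo_signal(rnorm(5000, sd = 0.3), rnorm(5000, sd = 0.3), fs)

  # 0 dB: both sources enter at equal RMS
  m0 <- mix_scene(t, i, 0)
  g0 <- attr(m0, "interferer_gain")
  expect_equal(g0 * rms(i), rms(t), tolerance = 1e-12)

  # 3 dB: interferer scaled to 0.707 of the equalized level (printed
  # precision: 10^(-3/20) = 0.70795, one unit in the last printed digit)
  expect_lt(abs(snr_gain(3) - 0.707), 1e-3)
  m3 <- mix_scene(t, i, 3)
  expect_equal(attr(m3, "interferer_gain") / g0, snr_gain(3),
               tolerance = 1e-12)

  # rescaling the interferer contribution by 10^(-d/20) shifts the SNR by d
  for (d in c(3, 10)) {
    md <- mix_scene(t, i, d)
    tpad <- c(t$left, numeric(1000))
    expect_equal(md$left - tpad, snr_gain(d) * (m0$left - tpad),
                 tolerance = 1e-12)
  }

  # zero-gain interferer leaves the target untouched
  minf <- mix_scene(t, i, Inf)
  expect_equal(minf$left[1:4000], t$left, tolerance = 1e-12)

  z <- stereo_signal(numeric(100), numeric(100), fs)
  expect_error(mix_scene(t, z, 0), "silent")
  expect_error(mix_scene(z, i, 0), "silent")
  expect_error(mix_scene(t, stereo_signal(1:10, 1:10, 48000), 0),
               "mismatch")
})

test_that("sparse fixtures are deterministic, band-limited and disjoint", {
  a <- generate_sparse_source(3, list(c(300, 900)), 1.0)
  b <- generate_sparse_source(3, list(c(300, 900)), 1.0)
  expect_identical(a, b)
  expect_gt(rms(a), 0)

  expect_identical(generate_sparse_source(3, list(), 0.5), numeric(16050))

  # disjoint band sets have essentially non-overlapping TF supports
  x <- generate_sparse_source(10, disjoint_bands_target, 1.5)
  y <- generate_sparse_source(11, disjoint_bands_interferer, 1.5)
  expect_lt(tf_overlap(x, y), 0.01)

  # the generator does not disturb the caller's RNG stream
  set.seed(123); r1 <- runif(1)
  set.seed(123); invisible(generate_sparse_source(3, list(c(300, 900)), 0.2))
  r2 <- runif(1)
  expect_identical(r1, r2)
})
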