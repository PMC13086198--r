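# Build a tiny spectrogram shell around given complex matrices so the
# normalization can be exercised on hand-constructed bins.
spec_from <- function(XL, XR, fs = 32100) {
  n <- (nrow(XL) - 1) * 2
  structure(list(X_L = XL, X_R = XR,
                 grid = tf_grid(n, n / 2, fs, ncol(XL),
                                orig_len = n * ncol(XL), pad = n)),
            class = "stereo_spectrogram")
}

test_that("normalization reproduces the worked bin examples", {
  XL <- matrix(complex(real = 1), 3, 2)
  XR <- matrix(complex(real = 1), 3, 2)
  cl <- disk_normalize(spec_from(XL, XR), "eq3", energy_floor_db = -300)
  expect_equal(cl$points[1, 1], complex(real = 1 / sqrt(2)),
               tolerance = 1e-12)

  # one-sided energy sits exactly on the unit circle
  XL2 <- matrix(0 + 0i, 3, 2); XR2 <- matrix(1 + 0i, 3, 2)
  cl2 <- disk_normalize(spec_from(XL2, XR2), "eq3", energy_floor_db = -300)
  expect_equal(Mod(cl2$points[2, 2]), 1, tolerance = 1e-12)

  # direct complex-arithmetic oracle: X_L = 2 e^{0.3i}, X_R = 1 e^{0.5i}
  XL3 <- matrix(2 * exp(0.3i), 3, 2); XR3 <- matrix(exp(0.5i), 3, 2)
  cl3 <- disk_normalize(spec_from(XL3, XR3), "eq3", energy_floor_db = -300)
  expect_equal(Mod(cl3$points[1, 1]), 1 / sqrt(5), tolerance = 1e-12)
  expect_equal(Arg(cl3$points[1, 1]), 0.2, tolerance = 1e-12)
})

test_that("every normalized point stays in the closed unit disk with IPD phase", {
  set.seed(17)
  n <- 200
  XL <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n)
  XR <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n)
  sp <- spec_from(XL, XR)
  cl3 <- disk_normalize(sp, "eq3", energy_floor_db = -300)
  cl4 <- disk_normalize(sp, "eq4", energy_floor_db = -300)
  expect_lte(max(Mod(cl3$points), na.rm = TRUE), 1 + 1e-12)
  expect_lte(max(Mod(cl4$points), na.rm = TRUE), 1 + 1e-12)
  ipd <- Arg(XR) - Arg(XL)
  expect_lt(max(abs(wrap_angle(Arg(cl3$points) - ipd))), 1e-10)
  # the two variants carry opposite phases: their sum is 0 mod 2*pi
  expect_lt(max(abs(wrap_angle(Arg(cl3$points) + Arg(cl4$points)))), 1e-10)
})

test_that("normalization is scale invariant and voids low-energy bins", {
  set.seed(18)
  fs <- 32100
  x <- generate_sparse_source(6, list(c(400, 1200)), 1, fs)
  s <- spatialize(x, synth_hrir(30, sample_rate = fs), fs)
  sp <- stft(s)
  cl <- disk_normalize(sp, "eq4")
  sp_scaled <- sp
  sp_scaled$X_L <- sp$X_L * -3.7
  sp_scaled$X_R <- sp$X_R * -3.7
  cl_s <- disk_normalize(sp_scaled, "eq4")
  expect_identical(cl$void, cl_s$void)
  expect_equal(cl$points[!cl$void], cl_s$points[!cl$void], tolerance = 1e-12)

  # void iff below the energy floor; a sparse signal has many void bins
  E <- cl$energies
  expect_identical(cl$void, E <= max(E) * 10^(-60 / 10) | E == 0)
  expect_gt(mean(cl$void), 0.3)
  expect_true(all(is.na(cl$points[cl$void])))
})

test_that("a pure interaural delay turns the point counterclockwise by 2*pi*f*tau", {
  fs <- 32100
  t <- (0:(fs - 1)) / fs
  for (tau_samp in c(3, 8)) {
    f0 <- 1000
    x <- sin(2 * pi * f0 * t)
    # right channel leads the left by tau -> positive eq3 phase at f0
    s <- stereo_signal(c(numeric(tau_samp), x),
                       c(x, numeric(tau_samp)), fs)
    cl <- disk_normalize(stft(s), "eq3")
    i <- which(cl$grid$frequencies_hz == f0)
    frames <- which(!cl$void[i, ])
    frames <- frames[frames > 3 & frames < max(frames) - 3]
    ph <- Arg(cl$points[i, frames])
    expected <- 2 * pi * f0 * tau_samp / fs
    expect_lt(max(abs(wrap_angle(ph - expected))), 0.02)
  }
})

test_that("the variant auto-selection follows the interferer side", {
  expect_equal(choose_variant(-60, 60), "eq4")
  expect_equal(choose_variant(0, 5), "eq4")
  expect_equal(choose_variant(180, 175), "eq3")
  expect_equal(choose_variant(60, -60), "eq3")
})
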