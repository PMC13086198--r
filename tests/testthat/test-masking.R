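test_that("mask gains are two-valued and follow strict circle membership", {
  hr <- front_hrirs()
  mdl <- front_model("eq4")
  sc <- disjoint_scene(hr, -60, 60, seed = 11)
  cloud <- disk_normalize(stft(sc$mixture), "eq4")

  hard <- build_mask(cloud, mdl, 60, mask_spec(mode = "hard",
                                               safeguard = "off"))
  expect_true(all(hard$gains %in% c(0, 1)))
  expect_gt(sum(hard$gains == 0), 0)

  soft <- build_mask(cloud, mdl, 60, mask_spec(mode = "soft",
                                               safeguard = "off"))
  expect_true(all(soft$gains %in% c(0.2, 1)))
  # soft attenuation in dB: 20*log10(0.2) is about -14 dB
  expect_equal(20 * log10(soft$spec$soft_gain), -13.98, tolerance = 0.005)
  # the two masks select the same bins
  expect_identical(hard$gains == 0, soft$gains == 0.2)

  # membership is strict and centered on the interferer's model point
  i <- which(cloud$grid$frequencies_hz == 1200)
  cf <- model_point(mdl, 60, 1200)
  sel <- which(!cloud$void[i, ])
  d <- Mod(cloud$points[i, sel] - cf)
  expect_identical(unname(hard$gains[i, sel] == 0), d < 0.2)
  # void bins always pass through
  expect_true(all(hard$gains[cloud$void] == 1))
})

test_that("applying a mask scales magnitudes bin-wise", {
  fs <- 32100
  set.seed(41)
  s <- stereo_signal(rnorm(fs), rnorm(fs), fs)
  sp <- stft(s)
  cloud <- disk_normalize(sp, "eq4")
  mdl <- front_model("eq4")
  mask <- build_mask(cloud, mdl, 60, mask_spec(mode = "soft",
                                               safeguard = "off"))
  out <- apply_mask(sp, mask)
  expect_equal(Mod(out$X_L), mask$gains * Mod(sp$X_L), tolerance = 1e-12)
  expect_equal(Mod(out$X_R), mask$gains * Mod(sp$X_R), tolerance = 1e-12)

  # identity and annihilator masks
  ones <- mask; ones$gains[] <- 1
  expect_equal(apply_mask(sp, ones)$X_L, sp$X_L)
  zeros <- mask; zeros$gains[] <- 0
  expect_true(all(apply_mask(sp, zeros)$X_L == 0))

  cloud3 <- disk_normalize(sp, "eq3")
  expect_error(build_mask(cloud3, mdl, 60), "variant mismatch")
})

test_that("segregation removes the interferer and keeps the target", {
  hr <- front_hrirs()
  mdl <- front_model("eq4")
  sc <- disjoint_scene(hr, -60, 60, seed = 11)

  seg_h <- segregate(sc$mixture, mdl, 60,
                     mask_spec(mode = "hard", safeguard = "off"))
  mh <- separation_metrics(seg_h$mask, sc$target_ref, sc$interferer_ref)
  expect_lt(mh$interferer_residual_db, -30)
  expect_gt(mh$target_preservation, 0.9)

  seg_s <- segregate(sc$mixture, mdl, 60,
                     mask_spec(mode = "soft", safeguard = "off"))
  ms <- separation_metrics(seg_s$mask, sc$target_ref, sc$interferer_ref)
  # soft residual: the circle covers the interferer's bins, so the
  # passthrough energy is the inside-gain squared
  expect_equal(ms$interferer_residual_db, 20 * log10(0.2), tolerance = 1)
  expect_gte(ms$target_preservation, mh$target_preservation - 1e-9)

  # energy monotonicity: masked output never gains energy, soft keeps at
  # least as much as hard
  e_in <- spec_energy(seg_h$mixture_spec)
  expect_lte(spec_energy(seg_h$masked_spec), e_in)
  expect_gte(spec_energy(seg_s$masked_spec), spec_energy(seg_h$masked_spec))

  # the mono output is the L+R sum of the masked audio
  expect_equal(seg_h$mono, seg_h$audio$left + seg_h$audio$right)
})

test_that("the single-cluster safeguard turns masking off where clusters merge", {
  hr <- front_hrirs()
  mdl <- front_model("eq4")
  fs <- hr$sample_rate
  # one source only: every frequency is single-cluster, so a safeguarded
  # mask must leave the signal untouched (round-trip identity)
  src <- generate_sparse_source(8, list(c(400, 1000), c(1600, 2400)), 1.5, fs)
  s <- spatialize(src, get_hrir(hr, 60), fs)
  seg <- segregate(s, mdl, 60, mask_spec(mode = "hard", safeguard = "on"))
  expect_true(all(seg$mask$gains == 1))
  expect_equal(seg$diagnostics$energy_removed_fraction, 0, tolerance = 1e-12)
  expect_equal_signal(seg$audio, istft(stft(s)))
  expect_lt(max(abs(seg$audio$left - s$left[seq_along(seg$audio$left)])),
            1e-9 * max(abs(s$left)))

  # with the safeguard off the same scene is masked
  seg_off <- segregate(s, mdl, 60, mask_spec(mode = "hard",
                                             safeguard = "off"))
  expect_gt(sum(seg_off$mask$gains == 0), 0)
  expect_gt(seg_off$diagnostics$energy_removed_fraction, 0.5)
})

test_that("mask parameters are validated", {
  expect_error(mask_spec(radius = 1.2), "radius")
  expect_error(mask_spec(mode = "soft", soft_gain = 0), "soft_gain")
  expect_identical(mask_spec(mode = "hard")$soft_gain, 0)
})
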