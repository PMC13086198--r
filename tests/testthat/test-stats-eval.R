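test_that("the proportion CI matches its closed form", {
  expect_equal(proportion_ci(0.5, 100)$ci_half_width, 0.098,
               tolerance = 5e-4)
  # degenerate proportion: zero width, not above zero
  p0 <- proportion_ci(0, 50)
  expect_identical(p0$ci_half_width, 0)
  expect_false(p0$above_zero)
  # the 1.960 coefficient corresponds to a two-sided tail of .05
  expect_equal(round(proportion_ci(0.5, 100)$alpha, 2), 0.05)
  # half-width maximal at 0.5 and shrinking as 1/sqrt(n)
  widths <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
                   function(a) proportion_ci(a, 100)$ci_half_width,
                   numeric(1))
  expect_equal(which.max(widths), 3L)
  expect_equal(proportion_ci(0.5, 400)$ci_half_width,
               proportion_ci(0.5, 100)$ci_half_width / 2)
})

test_that("the two-proportion z test reproduces its worked examples", {
  # null exactly
  z0 <- two_proportion_z(0.5, 0.5, 100)
  expect_identical(z0$z, 0)
  expect_identical(z0$p_two_sided, 1)

  # the reversed-vs-nonreversed interference comparison: p = .006
  z1 <- two_proportion_z(0.64, 0.45, 100)
  expect_equal(round(z1$p_two_sided, 3), 0.006)
  expect_true(z1$significant)

  # direct arithmetic oracle
  z2 <- two_proportion_z(0.97, 0.31, 100)
  expect_equal(round(z2$z, 2), 13.39)

  # antisymmetry
  z3 <- two_proportion_z(0.45, 0.64, 100)
  expect_equal(z3$z, -z1$z)
  expect_equal(z3$p_two_sided, z1$p_two_sided)

  # degenerate proportions fall back to the pooled variance
  zd <- two_proportion_z(1, 0, 20)
  expect_true(zd$pooled_fallback)
  expect_true(is.finite(zd$z))
  zp <- two_proportion_z(0.64, 0.45, 100, pooled = TRUE)
  expect_false(zp$pooled_fallback)
  expect_false(isTRUE(all.equal(zp$z, z1$z)))
})

test_that("Bonferroni adjustment divides the level by the comparison count", {
  expect_equal(bonferroni_alpha(0.05, 6), 0.05 / 6)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 2), 0.025)
  sig <- two_proportion_z(0.97, 0.31, 100,
                          alpha_adjusted = bonferroni_alpha(0.05, 6))
  expect_true(sig$significant)
})

test_that("keyword scoring is case/punctuation/order insensitive and greedy", {
  kw <- c("PARK", "OPENS", "ELEVEN", "MONTHS")
  expect_equal(keyword_score("the park opens in eleven months", kw)$a_hat, 1)
  expect_equal(keyword_score("", kw)$a_hat, 0)
  expect_equal(keyword_score("Months! eleven... OPENS park?", kw)$a_hat, 1)
  # each transcript word satisfies at most one key word
  expect_equal(keyword_score("park park", c("PARK", "PARK"))$a_hat, 1)
  expect_equal(keyword_score("park", c("PARK", "PARK"))$a_hat, 0.5)
  # partial
  expect_equal(keyword_score("the thirsty kid sleeps",
                             c("THIRSTY", "KID", "DRINKS", "JUICE"))$a_hat,
               0.5)
  # plural forgiveness only on request
  expect_equal(keyword_score("month eleven", c("MONTHS", "ELEVEN"))$a_hat,
               0.5)
  expect_equal(keyword_score("month eleven", c("MONTHS", "ELEVEN"),
                             ignore_plural_s = TRUE)$a_hat, 1)
  expect_true(all(vapply(
    c("a b c", "c b a", "A, b; C"),
    function(tr) keyword_score(tr, c("b", "c"))$a_hat, numeric(1)) == 1))
})

test_that("separation metrics honour their closed-form identities", {
  hr <- front_hrirs()
  sc <- disjoint_scene(hr, -60, 60, seed = 13, duration_s = 1)
  sp <- stft(sc$mixture)
  cloud <- disk_normalize(sp, "eq4")
  mask <- build_mask(cloud, front_model("eq4"), 60,
                     mask_spec(mode = "soft", safeguard = "off"))

  # identity mask: nothing removed, nothing improved
  ones <- mask; ones$gains[] <- 1
  m1 <- separation_metrics(ones, sc$target_ref, sc$interferer_ref)
  expect_equal(m1$interferer_residual_db, 0)
  expect_equal(m1$target_preservation, 1)
  expect_equal(m1$snr_improvement_db, 0)

  # a mask equal to the oracle ideal binary mask agrees with it fully
  st <- stft(sc$target_ref); si <- stft(sc$interferer_ref)
  ibm <- ideal_binary_mask(st, si)
  oracle <- mask
  oracle$gains <- matrix(1, nrow(ibm), ncol(ibm))
  oracle$gains[!ibm] <- 0
  m2 <- separation_metrics(oracle, sc$target_ref, sc$interferer_ref)
  expect_equal(m2$mask_agreement, 1)

  # soft mask covering every energetic interferer bin: residual is the
  # squared inside gain
  covered <- mask
  covered$gains <- matrix(1, nrow(ibm), ncol(ibm))
  covered$gains[!ibm] <- 0.2
  m3 <- separation_metrics(covered, sc$target_ref, sc$interferer_ref)
  expect_equal(m3$interferer_residual_db, 20 * log10(0.2), tolerance = 0.2)
})
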