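# Shared fixtures, built once per test run. Calibrating a spiral model from
# 5 s of noise takes a few seconds, so models are cached in this environment
# and reused across test files.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

front_hrirs <- function() {
  fixture("front_hrirs", function() synth_hrir_set())
}

# frontal + right-rear grid covering all study geometries
wide_hrirs <- function() {
  fixture("wide_hrirs", function() {
    synth_hrir_set(azimuths_deg = sort(unique(c(seq(-90, 90, by = 5),
                                                seq(95, 180, by = 5)))))
  })
}

front_model <- function(variant = "eq4") {
  fixture(paste0("front_model_", variant), function() {
    calibrate_spiral(front_hrirs(), seed = 7, variant = variant)
  })
}

wide_model <- function(variant = "eq4") {
  fixture(paste0("wide_model_", variant), function() {
    calibrate_spiral(wide_hrirs(), seed = 7, variant = variant)
  })
}

# Disjoint-band sparse fixture scene: the oracle-separable case.
disjoint_bands_target <- list(c(300, 900), c(1800, 2600))
disjoint_bands_interferer <- list(c(1100, 1600), c(3000, 3800))

disjoint_scene <- function(hrirs, target_az, interferer_az, seed = 11L,
                           duration_s = 2) {
  binaural_scene(hrirs, target_az, interferer_az, snr_db = 0,
                 duration_s = duration_s, seed = seed,
                 target_bands = disjoint_bands_target,
                 interferer_bands = disjoint_bands_interferer)
}

expect_equal_signal <- function(a, b, tol = 1e-10) {
  expect_equal(a$left, b$left, tolerance = tol)
  expect_equal(a$right, b$right, tolerance = tol)
}

# wrap an angle difference into (-pi, pi]
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  ifelse(y == -pi, pi, y)
}
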