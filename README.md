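# spiralsep

Binaural sound localization and speech segregation with a spiral cluster
model — an R implementation of a physiologically motivated algorithm for
spatial hearing-aid processing.

Hearing-aid users struggle most in cocktail-party scenes: several talkers
overlap in time, and conventional processing destroys the interaural cues a
normal binaural system would use to pull them apart. `spiralsep` implements
a combined localization-and-segregation strategy that works directly on the
two-microphone (left/right ear) signal, with no training data and no more
machinery than an STFT, a normalization, and k-means.

## The model

A stereo mixture is analysed with a 40-ms short-time Fourier transform
(25-Hz bins at the 32.1-kHz working rate). Each time–frequency bin
`(X_L, X_R)` is mapped into the closed unit disk:

```
right-referenced:  X̃ = X_R · e^(−iφ_L) / √(|X_L|² + |X_R|²)
left-referenced:   X̃ = X_L · e^(−iφ_R) / √(|X_L|² + |X_R|²)
```

The denominator confines every point to the unit disk; the phase of `X̃` is
the interaural phase difference (IPD = 2πf·ITD at frequency `f`), and the
modulus encodes the interaural level difference. Natural concurrent sounds
are *sparse* in time–frequency (W-disjoint orthogonality), so almost every
bin is owned by one source — and for a single-source bin the source term
cancels exactly, leaving a point determined only by that direction's
head-related transfer at that frequency. The bins of each source therefore
collapse into a tight cluster per frequency; as a single source sweeps from
−90° to +90°, its cluster center traces an outward counterclockwise
**spiral** (ITD turns the phase, with more turns at higher frequencies; the
head shadow moves the modulus), which is calibrated once from broadband
noise and stored per frequency.

Sources are localized by energy-weighted k-means on the disk and matched to
the nearest spiral point. An unwanted source is removed by a **hard mask**
(gain 0 inside a circle of radius 0.2 around its model point, 1 elsewhere)
or attenuated by a **soft mask** (gain 0.2 ≈ 14 dB attenuation); the mask
multiplies the *original* mixture STFT (no inverse normalization exists or
is needed), and overlap-add inversion returns the cleaned waveform. When the
clusters at a frequency cannot be told apart (side geometries, front–back
confusion), a safeguard leaves that frequency untouched rather than deleting
target and interferer alike.

Scoring utilities implement the associated statistics: the normal-
approximation proportion CI (coefficient 1.960 ⇔ two-sided p = .05), the
unpooled two-proportion z test with Bonferroni correction, an order-free
key-word transcript scorer, and objective separation metrics (interferer
residual, target preservation, agreement with the ideal binary mask, SNR
improvement) that replace recognition engines in simulation.

## Worked example

Calibrate a spiral model on a synthetic spherical head, build a two-source
scene (sparse tone-burst fixtures at −60° and +60°, 0 dB SNR), localize
both sources, and remove the interferer with a hard mask:

```r
library(spiralsep)

hrirs <- synth_hrir_set()                       # -90..+90 deg, 10 deg grid
model <- calibrate_spiral(hrirs, seed = 1, variant = "eq4")

target     <- generate_sparse_source(seed = 11,
                 list(c(300, 900), c(1800, 2600)),  duration_s = 2)
interferer <- generate_sparse_source(seed = 12,
                 list(c(1100, 1600), c(3000, 3800)), duration_s = 2)
scene <- mix_scene(spatialize(target,     get_hrir(hrirs, -60), 32100),
                   spatialize(interferer, get_hrir(hrirs, +60), 32100),
                   snr_db = 0)

cloud <- disk_normalize(stft(scene), "eq4")
locate_sources(cloud, model, k = 2, seed = 1)
#> <localization_result> 2 source(s): -60, +60 deg; 80/91 frequencies single-cluster

seg <- segregate(scene, model, interferer_azimuth_deg = 60,
                 mask_spec(mode = "hard", safeguard = "off"))
seg$mask
#> <tf_mask> hard mask (radius 0.2, inside gain 0): 1.6% of bins attenuated;
#>   640 frequencies masked, 0 left unmasked
```

Scoring the mask against the clean references:

```r
tgt <- spatialize(target,     get_hrir(hrirs, -60), 32100)
itf <- spatialize(interferer, get_hrir(hrirs, +60), 32100)
g   <- attr(scene, "interferer_gain")
itf <- stereo_signal(itf$left * g, itf$right * g, 32100)
separation_metrics(seg$mask, tgt, itf)
#> <separation_metrics> interferer residual -58.1 dB, target preserved 99.9%,
#>   mask agreement 98.0%, SNR improvement +58.1 dB
```

Both sources are recovered exactly on-grid; the hard mask removes the
interferer to −58 dB while keeping 99.9% of the target energy — the
behaviour expected when the scene is well separated at the front. (Many
frequencies are flagged "single-cluster" here only because the disjoint
fixture gives most frequencies a single owner; the safeguard is off to
apply the always-remove protocol.) The same pipeline with
`mask_spec(mode = "soft")` leaves a −14 dB interferer residual instead,
trading separation for robustness.

The statistics reproduce their worked values:

```r
two_proportion_z(0.64, 0.45, 100)
#> <z_test_result> a1 = 0.640 vs a2 = 0.450 (n = 100): z = 2.748, p = 0.005988 < 0.05 *
keyword_score("the park opens in eleven months",
              c("PARK", "OPENS", "ELEVEN", "MONTHS"))
#> <score_stats> 100.0% +/- 0.0 (n = 4), significantly above zero
```

## Command line

A thin CLI over the same functions lives at `inst/cli/spiralsep`
(installed under `system.file("cli", "spiralsep", package = "spiralsep")`):

```sh
spiralsep calibrate --seed 1 --out model.json
spiralsep segregate --model model.json --interferer-az 60 --mask hard scene.wav
spiralsep locate    --model model.json scene.wav --k 2
spiralsep benchmark --out benchmark.tsv
spiralsep score     --keywords words.txt transcript.txt
```

Configuration is a single YAML file (`--config`); all defaults are the
working analysis values (32.1 kHz, 40 ms, radius 0.2, soft gain 0.2,
coefficient 1.960).

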