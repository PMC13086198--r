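---
title: "Binaural segregation in the unit disk: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binaural segregation in the unit disk: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spiralsep)
```

## The problem and the model

Two microphones, one per ear, receive a mixture of spatial sound sources.
The goal is to remove or attenuate one source given (or having estimated)
its azimuth, using only the interaural cues the mixture itself carries —
an *underdetermined* blind-separation setting, since there are usually more
sources than microphones.

The method rests on two observations:

1. **Sparseness.** Concurrent natural sounds (speech, music) rarely occupy
   the same time–frequency bin with comparable energy. After a short-time
   Fourier transform, almost every energetic bin belongs to one source.

2. **Cue cancellation.** For a bin owned by a single source rendered
   through head-related filters, `X_L = H_L S` and `X_R = H_R S`. The
   disk normalization

   `X̃ = X_R e^(−iφ_L) / sqrt(|X_L|² + |X_R|²)`

   (right-referenced; the left-referenced variant swaps the channel roles)
   cancels the source term `S` exactly: the point depends only on
   `H_R / H_L` at that frequency. Its phase is the interaural phase
   difference, its modulus a monotone image of the interaural level
   difference, and the denominator keeps it in the closed unit disk.

Consequently all bins of one source pile onto (numerically: very near) a
single disk point per frequency. Sweeping a single broadband source across
azimuth traces, per frequency, a spiral: the phase `2πf·ITD(θ)` advances
counterclockwise toward the leading ear — with more turns at higher `f` —
while the head-shadow ILD moves the modulus between the disk center and
the unit circle. `calibrate_spiral()` measures this locus once, per
frequency and azimuth, as the energy-weighted complex mean of the
non-void normalized bins of 5 s of spatialized white noise. Broadband
noise is the right calibration signal (it excites every bin) even though
it is exactly the signal class the segregation stage cannot separate
(it violates sparseness); calibration presents one source at a time, so
no conflict arises.

Localization (`locate_sources()`) clusters each frequency's disk points
with energy-weighted k-means and matches cluster centers to the nearest
spiral point; segregation (`build_mask()`, `segregate()`) places a circle
of radius 0.2 around the interferer's spiral point at every frequency and
multiplies the bins strictly inside it by 0 (hard mask) or 0.2 (soft mask,
≈ 14 dB attenuation) — on the *original* mixture STFT, never on the
normalized points, so reconstruction is a plain inverse STFT and no
"inverse normalization" is involved.

### Choosing the variant

The normalization is asymmetric: under the right-referenced form, sources
on the right spread toward the unit circle (they do not cluster tightly),
sources on the left concentrate. A cluster must be compact to be removable,
so `choose_variant()` picks the left-referenced form when the interferer is
to the right of the target and the right-referenced form otherwise. The
target's own cluster may spread freely — it is never selected, and the
inverse STFT returns everything that was not masked.

### The single-cluster safeguard

Where the two sources' spiral points nearly coincide (small angular
separations at the side, front–back confusion cones), the mask circle
covers target and interferer alike and masking only destroys information.
`check_separability()` flags a frequency *single-cluster* when the two
k-means centers lie closer than one circle diameter (2 × radius) or when
less than 10% of the bin energy lies outside the candidate interferer
circle; with `safeguard = "on"` such frequencies are left unmasked. The
safeguard defaults to on for autonomous use. The benchmark and the
side-condition analyses run it off deliberately, reproducing the
always-remove protocol under which the side failure mode is visible.

## Parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| sample rate | 32 100 | Hz | makes the 40-ms window exactly 1284 samples and the bin spacing exactly 25 Hz |
| STFT window | 40 | ms | periodic Hann, 50% hop; a partition of unity, so overlap-add inversion is exact |
| analysis band | 25 – 16 000 | Hz | full one-sided range; a 4-kHz ceiling is available (`max_frequency_hz`) since speech energy is mostly below 4 kHz |
| circle radius | 0.2 | disk distance | the working value for cluster membership |
| soft gain | 0.2 | linear amplitude | 20·log10(0.2) ≈ −14 dB |
| energy floor | −60 | dB re max bin | bins below it are *void*: excluded from clustering, always passed through |
| calibration noise | 5 | s | seeded Gaussian white noise |
| calibration grid | −90…+90, 10° | degrees | frontal sweep; the benchmark extends it to the right-rear quadrant in 5° steps |
| safeguard outside fraction | 0.10 | energy ratio | the concrete reading of "few datapoints outside the cluster" |
| head radius / speed of sound | 0.0875 / 343 | m, m·s⁻¹ | spherical-head constants for the synthetic HRIRs |

## The synthetic head and what it does and does not emulate

No measured HRTF database ships with the package; `synth_hrir()` builds a
spherical-head stand-in with the cue structure the model exploits:

* ITD follows the Woodworth law `τ(θ) = (a/c)(θ + sin θ)` on the lateral
  angle, split across the ears as a fractional delay — zero at front and
  back, maximal at ±90°, monotone within each lateral quadrant;
* ILD is a one-pole head-shadow low-pass on the far ear whose effective
  cutoff falls with `sin|θ|` — exactly 0 dB at 0°, monotone toward ±90° at
  any fixed frequency;
* rear azimuths get a +2 dB high-shelf above 6 kHz on both ears, a stand-in
  for pinna cues that keeps front/back mirror pairs acoustically
  distinguishable instead of exactly degenerate.

Left/right mirror pairs are exact by construction. What the synthetic head
deliberately does **not** model: elevation dependence, near-field distance
cues, pinna notches, torso reflections, room reverberation, or the
measurement idiosyncrasies that give each individual database a different
number of spiral turns. Passing tests on this head therefore show that the
algorithm recovers whatever monotone ITD/ILD structure the rendering
system has — not that any particular measured database would yield the
same scores.

Scene fixtures (`generate_sparse_source()`) are sums of amplitude-gated
tone bursts on 25-Hz bin centers with randomized onsets — sparseness made
literal. Two sources on disjoint band sets overlap in less than 1% of
their time–frequency energy, which provides an *oracle*: any residual
interferer energy after masking is attributable to the mask, not to bin
sharing. Benchmark scenes instead share three bands between 200 and
4000 Hz (where most speech energy lives), so both sources populate the
same frequencies at different times. Tone fixtures do not emulate speech
statistics: harmonic structure, formant continuity, co-modulation and
crest factor are all absent, so the objective metrics here are not
recognition scores.

### Ambiguous frequencies

At frequency `f` the two sources' spiral points share a phase whenever
`f · Δτ` is an integer (Δτ the ITD difference): for ±60° that happens
near multiples of ≈ 1.02 kHz, where only the ILD separates the points and
the separation can fall inside the 0.2 circle. A broadband target loses
only those narrow slices; a tone fixture that happens to place a loud
burst there loses a visible fraction of its energy, which is why
fixture-based preservation figures vary a few percent with the seed. This
is the method's intrinsic "misbehavior" at cue-ambiguous frequencies, not
a property of the implementation.

## Numerical choices

* **STFT inversion.** Analysis uses a periodic Hann at 50% hop, whose
  shifted copies sum exactly to 1; synthesis is plain overlap-add of the
  inverse-DFT frames with no window division. Signals are reflect-padded
  by one window at each end, so the round trip is exact (≲ 1e−14
  relative) over the whole original extent, not just interior samples.
* **Zero-phase convention.** `Arg(0 + 0i)` is 0, so a bin whose reference
  channel is exactly zero gets a well-defined point on the unit circle;
  zero-energy bins are void, never divided by.
* **Strict circle membership.** A point at distance exactly `radius` is
  kept; strictness makes the boundary case deterministic.
* **Weighted k-means.** Energy weighting is required so a handful of loud
  bins dominates diffuse leakage; `stats::kmeans` has no observation
  weights, so a seeded k-means++ Lloyd iteration with 10 restarts (best
  weighted inertia kept, centers ordered lexicographically for stable
  labels) is implemented here and cross-checked against `stats::kmeans`
  on uniform weights in the tests.
* **Model lookup.** Nearest azimuth and nearest frequency bin, no
  interpolation: the spiral wraps, and a chord between grid centers can
  leave the locus entirely.
* **Azimuth aggregation.** Per-frequency cluster-to-azimuth matches vote
  with their cluster energy; the k azimuths with the greatest vote mass
  are the estimates (a weighted median is available as an alternative).
  The voting rule is a documented default — nothing canonical exists for
  combining several hundred per-frequency decisions.
* **Mixing convention.** Sources are RMS-equalized over the whole signal
  (levels are specified as averages, not per frame), then the interferer
  is scaled by `10^(−SNR/20)`. Exact dB arithmetic gives 0.70795 for 3 dB;
  the half-power shorthand prints it as 0.707.

## Problem sizes

The test and acceptance runs use 1.5–2 s fixture scenes (≈ 100 STFT
frames), 5-s calibration noise, a 19-azimuth frontal model for
localization (20 two-source scenes) and a 55-azimuth extended model for
the geometry benchmark; these sizes give stable metrics while keeping a
full run in tens of seconds. Durations and grids are parameters, and all
results scale with them in the expected way.

## Known limitations

* Azimuth only: elevation would require tracking spectral cues across
  frequencies, which the spherical head does not provide.
* The interferer's azimuth must be known or estimated first; nothing in
  the method says which source is the *target*.
* Reverberation and diffuse noise violate the single-point-per-source
  geometry and are not modelled.
* Masking at 25-Hz resolution across 640 frequencies is not a real-time
  design; a hearing-aid port would restrict the band to ≤ 4 kHz and
  coarsen the grid.
* The soft mask cannot remove more than 14 dB of interferer by design;
  that is its point — misclassified target bins survive attenuated.
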