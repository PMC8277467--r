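---
title: "Locating elephant rumbles from seismic and acoustic arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating elephant rumbles from seismic and acoustic arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumbleloc)
```

## The problem

African elephant rumbles are low-frequency calls (fundamental roughly
20–40 Hz, 3–5 s long, with a rising-then-falling frequency contour) that
propagate simultaneously through the air and through the ground. A small
array of co-located seismometers and microphones that records the same
rumble at several GPS-synchronized stations can localize the calling
animal by multilateration: the difference in arrival time between a pair
of stations constrains the source to a hyperbola, and three such pairs
(four stations) pin down a position.

`rumbleloc` implements the full chain: spectrogram computation and
enhancement, time-difference-of-arrival (TDOA) estimation by spectrogram
cross-correlation with a peak-prominence quality gate, deterministic and
Bayesian multilateration with an unknown wavespeed, a residual metric
that scores every estimate in metres, comparative summary statistics,
and a synthetic scene generator that stands in for field recordings.

## Signal model and processing chain

### Spectrograms

Each record is converted to a magnitude short-time-Fourier-transform
image. The defaults — 0.5 s Hann window, 90% overlap, truncation above
100 Hz — resolve a 20–40 Hz contour at 2 Hz and 0.05 s, giving at least
fifty time columns across a 3 s call; 100 Hz is also the upper end of
the seismometer's flat response. Multi-channel records (the four
microphone channels of one station) are first summed sample-by-sample:
the coherent call adds linearly while independent noise only adds in
power. Acoustic records are decimated (anti-alias filtered) to a 400 Hz
analysis rate so both modalities share the same time resolution; the
correlation step requires matched time bins within a modality, and
nothing above 120 Hz or so carries rumble energy.

### Structure-tensor enhancement

A rumble appears in the spectrogram as a thin oriented ridge, while wind
and broadband noise are isotropic texture. The enhancement weights every
pixel by a local anisotropy (coherence) measure: the log-compressed
image is smoothed at `gradient_scale` (1 bin), differentiated, the
gradient outer-product tensor is smoothed componentwise at
`integration_scale` (3 bins), and coherence is the normalized eigenvalue
gap

$$c = \left(\frac{\lambda_1 - \lambda_2}{\lambda_1 + \lambda_2 +
\varepsilon}\right)^{p}, \qquad \varepsilon = 10^{-12},$$

with exponent $p = 1$ by default. The enhanced pixel is
`magnitude * max(c, floor)` with `floor = 0.05`, so oriented ridges pass
unchanged ($c \to 1$) and isotropic regions are attenuated twenty-fold
but never zeroed. Log compression before differentiation stops the
loudest pixels from dominating the gradients. The exact enhancement
used on the original field data was not published in full; the
formulation above is the standard structure-tensor coherence measure,
chosen because it matches the stated goal — keep anisotropic contours,
suppress isotropic noise.

### TDOA by spectrogram correlation

For each event the reference station is the one whose enhanced
spectrogram holds the most total magnitude (ties break
lexicographically). Every other station is cross-correlated against it
along the time axis; the score at each whole-bin lag is the cosine
similarity of the overlapping sub-images, which is bounded in $[0, 1]$
for non-negative images and invariant to amplitude scaling. The peak is
refined to sub-bin precision by parabolic interpolation of the three
samples around it — on clean synthetic scenes this recovers lags to a
few tenths of a millisecond, fifty times finer than the 0.05 s bin.
The search is bounded at 1.5 × (array diameter / 200 m s⁻¹), since no
physical arrival-time difference can exceed the inter-station travel
time; the margin also suppresses spurious high-cosine scores from tiny
edge overlaps.

Quality is gated on the topographic prominence of the correlation peak
(its height above the lowest contour enclosing it alone), not on the
correlation value itself, which noise deflates uniformly. An event is
rejected — naming the failing pair — if any pair's prominence falls
below `min_prominence` (default 0.1; no published threshold exists, and
on the cosine scale 0.1 cleanly separates chance alignments of noise
from true ridge matches in the synthetic scenes).

## Localization

With stations $p_i$ in a horizontal plane, a source at $x$ and
wavespeed $v$ predicts the arrival-time difference
$(\lVert x - p_i\rVert - \lVert x - p_0\rVert)/v$ for each non-reference
station. Two solvers invert the measured lags:

* **Deterministic**: for each wavespeed on a grid (acoustic 320–380 m/s
  in 5 m/s steps around the field estimate of 350; seismic 200–1500 m/s
  in 25 m/s steps, since near-surface ground speeds vary widely), the
  position minimizing the sum of squared lag mismatches is found by
  multi-start Levenberg–Marquardt least squares (nine starts on a 3×3
  grid over the prior box — hyperbola intersections are non-convex).
* **Bayesian**: a posterior over $(x, v)$ — or $(x, v_{seis}, v_{acou})$
  for the joint bimodal variant, which shares one position across both
  modalities' likelihoods — with uniform priors (position: station
  bounding box padded 200 m; wavespeed: per-modality interval) and
  independent Gaussian likelihoods on each lag with
  `tdoa_sigma` defaulting to one spectrogram time bin, the dominant
  known lag error. Sampling is random-walk Metropolis seeded at the
  maximum-a-posteriori point with proposal scales from a Laplace
  approximation (falling back to a tenth of the prior width in flat
  directions), 4000 kept samples after 1000 burn-in. A random-walk
  chain is entirely adequate for a 3–4 parameter posterior; the MAP
  point is kept among the samples so downstream selection always sees
  the mode.

Every candidate — each grid wavespeed, each posterior sample — is
scored by the residual

$$r = v \cdot \operatorname{mean}_i\,
\lvert \text{lag}_i^{obs} - \text{lag}_i^{pred}(x, v) \rvert,$$

the mean absolute TDOA mismatch expressed in metres, and the candidate
with the smallest residual is reported. (The original description of
this metric says the averaged mismatch was *divided* by the wavespeed
yet reports metres; seconds divided by m/s is dimensionally
inconsistent, so this package multiplies. For the joint method each
pair's mismatch is converted with its own modality's wavespeed before
averaging; the same metric serves both solvers.)

### Identifiability: the wavespeed valley and ghost solutions

Three reference-pair TDOAs against three unknowns $(x, y, v)$ is an
exactly identified polynomial system, with two consequences users must
understand:

1. The least-squares objective has a long shallow valley: position
   trades off against wavespeed, so over a wide wavespeed range the
   best-fit position drifts tens of metres while the residual changes
   by only centimetres. Residual-based selection is correspondingly
   noise-sensitive when the wavespeed grid or prior is wide.
2. For a substantial fraction of source positions (about a quarter, in
   the bundled geometry) the system admits a second *exact* solution at
   a different wavespeed inside a wide prior such as 150–1600 m/s. No
   estimator can reject such a ghost from the TDOA data alone; only a
   tighter wavespeed prior, more stations, or independent ground truth
   can. The MAP search therefore profiles over a wavespeed grid
   (position-only fits, each polished by a full Levenberg–Marquardt
   pass) and ranks candidates by the raw least-squares objective, which
   still separates fits whose likelihoods agree to within
   double-precision rounding.

Because the residual is a TDOA-mismatch metric, not a distance to the
(unknown) true animal, the two can differ by the geometric dilution
factor of the array — on synthetic scenes with half-bin lag noise the
median true-position error is roughly 7–9 m while median residuals are
2–3 m. Validation quantities in this package therefore state explicitly
whether they are residuals or true-position errors.

## The synthetic scene generator

`generate_scene()` builds fully synthetic ground-truth scenes: four
co-located seismo-acoustic stations ringing a central source region
(aperture just over 300 m; the coordinates are synthetic — the original
field geometry was never published), a rumble with a piecewise-linear
rising-then-falling fundamental (defaults 24 → 38 → 26 Hz over 4 s),
harmonics decaying by half per order, phase-continuous synthesis and 5%
raised-cosine tapers. Propagation is single-path at a constant speed
per modality (defaults 350 m/s acoustic, 400 m/s seismic, the field
estimates), with spherical spreading ($1/r$), sub-sample delays by
interpolation, and modality filtering: a 45 Hz low-pass for the ground
path (so the seismic arrival carries essentially only the fundamental)
and the published microphone low-frequency roll-off (−2 dB at 50 Hz,
−4 dB at 40 Hz, −10 dB at 20 Hz, interpolated in dB) for the air path.
Noise is additive white Gaussian, set by the amplitude SNR at the
station nearest the source. The seismic rate matches the field
instruments (200 Hz); the acoustic rate defaults to 4 kHz — far above
the rumble band — to keep scenes light.

What the generator does **not** emulate: multipath and reflections
(the field site had a dam), wavespeed heterogeneity and dispersion,
wind noise with realistic spectra, overlapping calls from multiple
animals, and clock drift. Tests passing on these scenes therefore
validate the algorithmic chain under the constant-wavespeed,
single-path assumptions that the solvers themselves make — they do not
certify performance on field data, where event selection and the
prominence gate carry more of the load.

## Numerical choices

* Least squares uses `minpack.lm::nls.lm` with `ftol = ptol = 1e-14`,
  which converges to machine precision and makes estimates equivariant
  under rigid motions of the coordinate frame to better than a
  millimetre.
* Sub-bin peak refinement uses the three-point parabola; degenerate
  peaks (at the curve edge, or with non-concave neighbours) fall back
  to the integer-bin lag.
* Coherence uses $\varepsilon = 10^{-12}$ in the denominator; an
  all-constant image has coherence 0 everywhere, so its enhanced output
  is exactly `floor` times the input.
* Ties in reference-station selection and in best-estimate selection
  break deterministically (lexicographic id; first occurrence).
* Scene generation, the Metropolis chain and every test are seeded; the
  sampler restores the caller's RNG state on exit.

## Problem sizes used in the validation suite

The bundled tests run the full waveform chain on 20 noiseless and 10
SNR-10 scenes, lag-level recovery on 100 half-bin-noise scenes, and
brute-force oracles (exhaustive correlation loops, a 50 × 50 × 10
position–wavespeed grid) on reduced images; the acceptance script
repeats the lag-level suite at 100 scenes and the waveform chain at 6
scenes. These sizes were chosen so the whole suite completes in a few
minutes on one core while keeping Monte-Carlo margins comfortable.

## Known limitations

* Waveform I/O is WAV and a plain-text CSV container; miniSEED, the
  native field format, is not read (no R reader was available), so
  field archives must be converted upstream.
* Event windows are supplied by the user (catalogue CSV); there is no
  automated rumble detector.
* All stations are assumed coplanar and GPS-synchronized; elevation,
  clock drift and 3-D propagation are out of scope.
* With four stations the free-wavespeed problem is exactly identified;
  see the identifiability section above for what that implies about
  ghost solutions and noise amplification.
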