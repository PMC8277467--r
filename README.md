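# rumbleloc

Seismo-acoustic localization of elephant rumbles.

African elephant rumbles (fundamental ~20–40 Hz, 3–5 s, rising-then-falling
frequency contour) travel both through the air and through the ground. A
small array of co-located, GPS-synchronized seismometers and microphones can
localize the calling animal by multilateration: the time-difference-of-arrival
(TDOA) between a station pair constrains the source to a hyperbola, and three
pairs (four stations) determine a position. `rumbleloc` is for
bioacousticians and wildlife-monitoring researchers who want to run that
chain end to end — and to study how well it works — without field data,
via a fully synthetic scene generator with ground truth.

## What it computes

With stations **p**ᵢ in a horizontal plane, a source at **x** emitting a
wave of speed *v* predicts lags

> lagᵢ = (‖**x** − **p**ᵢ‖ − ‖**x** − **p**₀‖) / *v*,

where **p**₀ is the reference station (the one with the strongest signal).
Measured lags come from cross-correlating structure-tensor-enhanced
spectrograms along the time axis (cosine similarity per lag, parabolic
sub-bin refinement), gated on the topographic prominence of the correlation
peak. Two solvers invert the lags:

* **deterministic** — for each wavespeed on a grid, multi-start
  Levenberg–Marquardt least squares over position;
* **probabilistic** — Metropolis sampling of the posterior over
  (**x**, *v*) with Gaussian lag likelihoods and uniform priors, including
  a **joint** bimodal variant with one shared position and independent
  seismic and acoustic wavespeeds.

Every candidate is scored by the residual
*r* = *v* · meanᵢ |lagᵢᵒᵇˢ − lagᵢᵖʳᵉᵈ| (metres); the smallest-residual
candidate is the reported estimate.

## Worked example

Simulate one rumble at (40, 30) m in the bundled four-station geometry,
with waveform SNR 10, and localize it from the seismic records:

```r
library(rumbleloc)

stations <- synthetic_stations()
scene <- generate_scene(stations = stations, source = c(40, 30),
                        snr = 10, seed = 42)
specs <- lapply(scene$waveforms$seismic, function(w)
  enhance_spectrogram(compute_spectrogram(w)))
tdoas <- build_tdoa_set(specs, max_lag = default_max_lag(stations))
tdoas
#> <tdoa_set> [seismic] reference NTA, 3 pairs
#>   station       lag_s prominence
#> 1     ETA -0.03393357  0.8477580
#> 2     STA  0.11475688  0.8435248
#> 3     WTA  0.16591434  0.8412050

best_estimate(localize_deterministic(tdoas, stations, solver_config()))
#>   method modality      x_m      y_m   v   residual
#> 1    det  seismic 40.11084 29.87939 400 0.02208169
```

The lags carry a prominence near 0.85 (the quality gate defaults to 0.1),
and the deterministic sweep recovers the true position to about 0.16 m with
a 0.022 m residual at the true wavespeed of 400 m/s. The Bayesian solver
agrees:

```r
post <- localize_probabilistic(tdoas, stations, solver_config(rng_seed = 1))
best_estimate(post, tdoas, stations)
#>   method modality      x_m      y_m        v     residual
#> 1   prob  seismic 40.27687 30.01939 401.7294 2.787558e-15
```

The comparative statistics of the nine published field events ship with the
package:

```r
summarize_residuals(field_residual_table())
#> <residual_summary> 9 events
#>      det_acoustic det_seismic prob_acoustic prob_seismic prob_joint
#> mean         6.77        5.14          5.18         4.45      11.60
#> sd           7.98        7.55          5.42         6.16       5.48
#> Pearson correlations:
#> det_acoustic~prob_acoustic   det_seismic~prob_seismic
#>                     0.9898                     0.9990
#>    prob_joint~prob_seismic   prob_joint~prob_acoustic
#>                     0.7548                     0.5069
#> events with seismic < acoustic in both frameworks: 6/9

interaural_delay(1, 350) * 1e3   # ms across a 1 m ear separation, acoustic
#> [1] 2.857143
interaural_delay(1, 400) * 1e3   # seismic
#> [1] 2.5
```

Seismic localization beats acoustic in both frameworks for 6 of the 9
events, and the 2.86 / 2.50 ms interaural delays quantify the azimuth cue
an elephant could extract from either wave type.

A thin command-line wrapper lives at `inst/cli/rumbleloc`
(`simulate`, `spectrogram`, `tdoa`, `locate`, `summarize`, `run`):

```sh
Rscript inst/cli/rumbleloc simulate --seed 4 --out scene/
Rscript inst/cli/rumbleloc run --scene scene/ --out out/
```

See `vignettes/seismoacoustic-localization.Rmd` for the model details, the
enhancement formulation, parameter defaults, the identifiability limits of
four-station TDOA with a free wavespeed, and what the synthetic scenes do
and do not emulate.

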