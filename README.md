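# sptmix

Diffusive-state decomposition for single-particle tracking (SPT), with the
companion in-vitro kinetics analyses of a condensin-like plasmid-defense
study: 1:1 bio-layer interferometry binding kinetics, Hill/Michaelis–Menten
ATPase kinetics, and efficiency-corrected qPCR relative copy numbers. A
synthetic-data module generates every input type with known ground truth, so
the whole pipeline is testable without raw microscopy or plate data.

The package is written for microscopists and biochemists who have track
tables (TrackMate XML or CSV) and plate/sensor CSV exports, and want the
downstream statistics reproducible in code: every user-facing function takes
a data frame and returns a tibble, so analyses compose with the pipe.

## The core model

Pooled squared single-lag displacements $x$ of a static mixture of $k$
Brownian states follow the exponential-mixture CDF

$$F(x) = 1 - \sum_{i=1}^{k} f_i\,
  \exp\!\left(-\frac{x}{4 D_i \tau + 4\sigma^2}\right),
  \qquad \textstyle\sum_i f_i = 1,$$

fitted by least squares on the empirical CDF (`fit_sqd_mixture()`). The
number of states is chosen by nested-model comparison (`select_model()`): an
extra state is accepted only when the F-test is significant (p < 0.05), the
BIC ($n\ln(\mathrm{rss}/n) + p\ln n$) drops by more than 5%, and the new
state is identifiable (scale separation ≥ 3×, occupancy ≥ 5%). Ensemble and
time-averaged MSD, shared-D global fits across conditions, jump-distance
verification and TAMSD k-means classification complete the SPT side; see the
vignette `vignettes/diffusive-states.Rmd` for the full methods account.

## Worked example

Simulate a wild-type-like three-state condition (fast 0.479 µm²/s at 47.7%,
slow 0.105, immobile 0.0151 µm²/s), run the SPT chain, and fit a sensorgram:

```r
library(sptmix)

ts <- simulate_tracks(3000, d = c(0.479, 0.105, 0.0151),
                      fractions = c(0.477, 0.2615, 0.2615),
                      localization_sigma = 0, seed = 42) |>
  filter_tracks()                      # ≥5 frames, past the bleach window

fit_msd_linear(compute_msd(ts))
#> Linear MSD fit: D = 0.262 um^2/s (se 0.00099), intercept = -0.0003372 um^2, R^2 = 1.0000 (4 lags)

sel <- select_model(compute_sqd(ts), seed = 1)
tidy(selected_fit(sel))
#> # A tibble: 3 × 4
#>   component label            d fraction
#>       <int> <chr>        <dbl>    <dbl>
#> 1         1 fast mobile 0.488     0.465
#> 2         2 slow mobile 0.109     0.284
#> 3         3 immobile    0.0149    0.252

fit_sensorgram(simulate_sensorgram(7.42e4, 0.16, analyte_conc = 2e-6))
#> 1:1 binding fit: ka = 7.42e+04 /(M s), kd = 0.16 /s, kobs = 0.3084 /s
#>   KD = 2.156e-06 M (2.16 uM); R^2 = 1.0000
```

The MSD fit reads out the *ensemble* diffusion coefficient (a
population-weighted average, here 0.26 µm²/s); the SQD decomposition then
resolves it into three states whose diffusion coefficients and fractions
recover the simulation ground truth to a few percent, and model selection
confirms k = 3. The binding fit inverts the noiseless 1:1 sensorgram exactly:
k_obs = k_a[A] + k_d = 0.3084 s⁻¹ and K_D = k_d/k_a ≈ 2.16 µM.

Each fitted object has `tidy()`/`glance()` methods and an `autoplot()`
(MSD curves, SQD CDF overlays, jump-distance histograms, sensorgrams, Hill
curves, TAMSD cluster profiles). `run_pipeline()` drives
simulate → filter → MSD → SQD → selection → jump-distance → clustering plus
the BLI/ATPase/qPCR stages from one YAML/list config and writes JSON + TSV
results; `make_fixtures()` writes a small fixture set with a ground-truth
manifest.

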