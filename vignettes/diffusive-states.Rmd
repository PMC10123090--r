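---
title: "Diffusive-state decomposition for single-particle tracking, with companion binding and enzyme kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusive-state decomposition for single-particle tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptmix)
library(dplyr)
```

## The scientific problem

Live-cell single-particle tracking (SPT) of fluorescently labeled proteins —
here, subunits of a condensin-like bacterial plasmid-defense complex — yields
thousands of short trajectories. A single protein species rarely moves as one
homogeneous population: freely diffusing, DNA-bound and scaffold-anchored
molecules coexist. The analytical task is to decompose the observed mobility
into a small number of *diffusive states*, each with a diffusion coefficient
$D_i$ and an occupancy fraction $f_i$, and to decide — with an explicit
statistical rule — how many states the data actually support. The package also
implements the standard companion analyses of such a study: 1:1 bio-layer
interferometry (BLI) binding kinetics, Hill/Michaelis–Menten ATPase kinetics,
and efficiency-corrected qPCR relative copy-number quantification, plus a
synthetic-data module that generates every input type with known ground truth.

## Models and procedures

### Ensemble MSD

For 2D Brownian motion the mean squared displacement is linear in the lag
time, $\mathrm{MSD}(\tau) = 4D\tau + b$. The ensemble MSD is computed at four
lags ($\tau = \Delta t, \dots, 4\Delta t$; 24–96 ms at the default 24 ms frame
interval) by averaging squared displacements over all localization pairs whose
*frame indices* differ by exactly $m$ — gap-closed tracks therefore never
contribute a spurious long jump. Pairs ending at a track's final localization
are excluded by default, since track ends are enriched for mislinked or
out-of-focus spots. An ordinary least-squares line gives $D$ as slope/4; the
intercept absorbs static localization error ($b = 4\sigma^2$), which is why
fitting an intercept rather than forcing the line through the origin matters.

### SQD mixture decomposition

Under a static mixture of $k$ Brownian states, the squared single-lag
displacement $x$ is exponentially distributed within each state, so its
cumulative distribution is

$$F(x) = 1 - \sum_{i=1}^{k} f_i \exp\!\left(-\frac{x}{4 D_i \tau + 4\sigma_\mathrm{eff}^2}\right),
\qquad \sum_i f_i = 1 .$$

`fit_sqd_mixture()` fits this model to the empirical CDF of the pooled
squared displacements by least squares. Fractions are kept on the simplex by
a softmax parameterization and diffusion coefficients positive by a log
parameterization. The optimizer is multi-start Nelder–Mead (starts from
rank-block means of the sorted sample plus perturbed restarts, 8 starts by
default) followed by a BFGS polish; the one-component model is solved by 1-D
golden-section search, which makes noiseless inversion exact to optimizer
tolerance. For speed the objective is evaluated on at most 1000
rank-decimated points of the empirical CDF — these are exact $(x_{(r)}, r/n)$
pairs, not smoothed values — while the reported residual sum of squares and
BIC are always recomputed on the full sample. On the study-scale problems
(3000 tracks, ~33,000 displacements) decimation changes the estimates by less
than the sampling noise while cutting the fit time ~30-fold.

The localization-error offset $\sigma_\mathrm{eff}$ is fixed at 0 by default:
the offset is shared by all components and is statistically indistinguishable
from a small shift of every $D_i$, so we prefer to expose it as an explicit
parameter rather than fit it silently.

### How many states? F-test, BIC, and an identifiability guard

`select_model()` fits $k = 1, 2, 3$ and accepts each additional state only if
the nested F-test is significant at $\alpha = 0.05$,

$$F = \frac{(\mathrm{rss}_{k-1} - \mathrm{rss}_k)/2}{\mathrm{rss}_k/(n - p_k)},
\qquad p_k = 2k - 1,$$

*and* the BIC of the Gaussian-residual form
$\mathrm{BIC} = n \ln(\mathrm{rss}/n) + p \ln n$ decreases by more than 5% in
relative terms, $(\mathrm{BIC}_{k-1} - \mathrm{BIC}_k)/|\mathrm{BIC}_{k-1}| >
0.05$. The search stops at the first rejection. Both thresholds are
parameters; the defaults are the conventional ones for this analysis.

These two gates alone are not enough, and this is a deliberate design choice
of the package: residuals of an empirical CDF are strongly autocorrelated
(the deviation from the true CDF is a smooth Brownian-bridge-like wiggle), so
the F-test's independence assumption fails and an extra exponential component
can soak up that wiggle, occasionally producing large spurious RSS drops. In
repeated simulation from a single-state truth, about a third of runs passed
both gates with a fictitious second state — one that was always either nearly
degenerate with the first (scales within a factor of ~2) or nearly empty
(a few percent occupancy). `select_model()` therefore additionally requires
an accepted state to be *identifiable*: adjacent exponential scales must
differ by at least a factor of 3 (`min_d_ratio`) and every state must hold at
least 5% of the population (`min_fraction`). Components closer than that are
not resolvable from a CDF in principle, so the guard rejects only states that
could never be interpreted. With the guard, single-state data keep $k = 1$ in
virtually all runs, while the three-state wild-type-like configuration
(separations 4.6× and 7×, smallest printed fraction 15.2%) is selected
correctly. Setting `min_d_ratio = 1, min_fraction = 0` restores the bare
two-gate rule.

### Global fits, jump distances, TAMSD clustering

`global_fit_sqd()` minimizes the summed CDF residual across conditions with
one shared $D$ vector and per-condition fractions, which is how fractions are
compared across strains without conflating them with small $D$ shifts. A
single condition reduces exactly to the individual fit.

`fit_jump_distance()` is a verification step, not a refit: the jump-distance
histogram (Freedman–Diaconis bins, empty bins merged) is compared against the
Rayleigh mixture implied by the fitted CDF model,
$p(r) = \sum_i f_i \, (2r/a_i)\, e^{-r^2/a_i}$ with
$a_i = 4D_i\tau + 4\sigma_\mathrm{eff}^2$, reporting $\chi^2$ and $R^2$ with
parameters held fixed.

`cluster_tamsd()` classifies individual tracks by k-means on standardized
$\log_{10}$ time-averaged MSD values at lags 1–4 (10 restarts, fixed seed).
The number of groups is supplied by the caller — in the standard workflow the
component count selected by the SQD analysis — and is never refit here.
Clusters are reported in descending mean-TAMSD order. Tracks shorter than
`max_lag + 2` localizations cannot provide all four TAMSD lags under
last-point exclusion and are excluded with a warning.

### Binding kinetics (BLI)

The 1:1 model is fitted phase by phase, as per-sensor instruments do:
association $Y = Y_0 + a(1 - e^{-k_\mathrm{obs} t})$, dissociation
$Y = Y_0 + a\, e^{-k_d t}$, then $k_a = (k_\mathrm{obs} - k_d)/[A]$ and
$K_D = k_d / k_a$. A titration series can instead be given to
`estimate_ka()`, whose regression slope is $k_a$ and whose intercept should
reproduce $k_d$ — a useful self-consistency diagnostic. Flat phases are
flagged unidentifiable rather than fitted; $\chi^2$ uses unit weights because
instrument noise models vary by vendor.

### ATPase and qPCR

`preprocess_rates()` turns plate time courses into rates by linear regression
over the window with maximal $R^2$ (sliding window, default the full course),
then subtracts the ATP auto-hydrolysis and no-substrate control rates.
Corrected rates may be negative when a sample sits at the detection limit;
they are flagged, never clipped, because clipping would bias titration fits.
`fit_hill()` fits $v = v_\mathrm{max} S^{n_h}/(K^{n_h}_{1/2} + S^{n_h})$, with
$n_h$ fixable to 1 for pure Michaelis–Menten behavior.

Relative plasmid copy number uses the efficiency-corrected (Pfaffl-style)
ratio
$E_\mathrm{tgt}^{-C_{t,\mathrm{tgt}}} / E_\mathrm{ref}^{-C_{t,\mathrm{ref}}}$
times the dilution/volume correction
$(d_\mathrm{ref}/v_\mathrm{ref})/(d_\mathrm{tgt}/v_\mathrm{tgt})$, which
reduces to the classical $2^{-\Delta C_t}$ for equal factors and perfect
doubling. The exact combination of dilution factors and purification volumes
is not standardized across labs, so the correction implemented here is the
one the simulator inverts exactly, and both are documented together.
`primer_efficiency()` recovers $E = 10^{-1/\mathrm{slope}}$ from calibration
dilution curves.

## What the synthetic data emulate — and what they do not

`simulate_tracks()` draws each track's state once (a *static* mixture, the
same assumption the SQD model makes), applies Gaussian per-axis steps with
variance $2D_i\Delta t$, and adds i.i.d. Gaussian localization error
($\sigma$ = 0.02 µm per axis by default) to every stored position. Track
lengths are geometric with mean 12 frames truncated at the 5-frame analysis
minimum — tracking studies report many short tracks and few long ones, and
only the ≥ 5-frame filter is a stated analysis condition, so the length
distribution is a package choice exposed as a parameter. Start frames are
drawn uniformly from frames 500–9000 of an emulated 10,000-frame acquisition
so that the default 500-frame bleach filter does not remove simulated data.
Optional circular confinement reflects steps at the boundary.

Deliberately **not** modeled: state switching within a track (HMM-style
dynamics), blinking/bleaching photophysics, anomalous diffusion exponents,
cell-geometry effects on localization, and detection/linking errors. Passing
the recovery tests therefore shows that the estimators invert the model they
assume — it does not certify performance on real data where those effects are
present. That caveat applies equally to the original analysis chain the
package reimplements.

Defaults that mirror the study conditions: frame interval 0.024 s (20 ms
exposure plus transfer), four MSD lags, 5-frame minimum length, 500-frame
bleach cutoff, ~3000 tracks per condition for the recovery checks (the study
reports ≥ 1007 tracks per sample; we simulate 3000 so that fraction estimates
are stable at the ±5-percentage-point level). The three-state recovery
scenario uses the printed fast-state parameters (0.479 µm²/s, 47.7%) and the
printed slow/immobile diffusion coefficients (0.105, 0.0151 µm²/s); the
slow/immobile fractions are not printed, so the remaining mass is split
evenly — a choice stated here once and used everywhere.

## Numerical choices and degenerate inputs

* Empirical CDF is rank/$n$; the mixture model approaches 1 only
  asymptotically, a negligible $O(1/n)$ mismatch at the largest draw.
* Nested fits that come back with *higher* RSS than the simpler model
  (impossible in exact arithmetic, possible for a finite optimizer) reuse the
  simpler solution with a logged note, so model selection can only be
  conservative.
* An exactly zero RSS (noiseless inputs) makes the F statistic undefined; the
  comparison is reported as "perfect fit, simpler model retained".
* k-means with fewer distinct TAMSD profiles than clusters would error in
  base R; the package instead assigns each distinct profile its own cluster,
  leaves the rest empty, and warns.
* Negative analyte times, non-normalized fractions, negative diffusion or
  rate constants, efficiencies outside $(1, 2]$, and positive dilution-curve
  slopes are rejected with named errors rather than coerced.

## Problem sizes used by the automated checks

The test suite and the acceptance script simulate 2000–3000 tracks per
condition (30,000–100,000 displacement pairs), 5000-displacement samples for
the 50-seed model-selection calibration, 2000-sample oracle comparisons
against a brute-force likelihood grid, and 21-point noiseless titrations for
the kinetics round trips. These sizes reproduce the study-scale uncertainty
(a few percent on $D$, 1–2 percentage points on fractions) while keeping a
full run in minutes on one CPU.

## Known limitations

* The SQD model assumes state constancy within tracks; molecules that switch
  state mid-track bias fractions toward intermediate values.
* The identifiability guard intentionally refuses to report states separated
  by less than ~3× in scale; genuinely close states require longer tracks or
  HMM-type analysis, both out of scope.
* The BLI module fits 1:1 kinetics only; heterogeneous or avid binding (seen
  at high analyte concentrations in the underlying study) shows up as lack of
  fit, not as a second site.
* qPCR quantification is relative; absolute copy numbers require standard
  curves that are out of scope.

## A worked pipeline run

```{r, eval = FALSE}
report <- run_pipeline(list(
  seed = 1,
  spt = list(
    simulate = list(n_tracks = 3000,
                    d = c(0.479, 0.105, 0.0151),
                    fractions = c(0.477, 0.2615, 0.2615),
                    localization_sigma = 0)),
  bli = list(simulate = list(ka = 7.42e4, kd = 0.16, analyte_conc = 2e-6)),
  atpase = list(simulate = list(vmax = 0.023, k_half = 0.5, n_h = 0.97)),
  qpcr = list(simulate = list(true_copy_ratio = 5,
                              efficiency_target = 1.9))),
  out_dir = "pipeline-out")
report$results$spt$selection$selected_k   # 3
```
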