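---
title: "From probe signals to drought-response inference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From probe signals to drought-response inference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sapflux)
```

`sapflux` implements the measurement-to-inference chain used in sap-flow
studies of tree water use: thermal dissipation probe (TDP) signals are
converted to sap flux density, corrected for radial variation with heat
field deformation (HFD) profiles, scaled to whole-tree water use, and fed
into a statistical battery that quantifies how soil moisture (SWC) and
atmospheric demand (VPD) control water use across species with different
drought-coping strategies. This vignette documents the models, the tunable
parameters, the synthetic world used for validation, and the numerical
choices — in that order.

## 1. The measurement chain

### TDP conversion

A TDP sensor pair reports the temperature differential \(\Delta T\) between
a heated and an unheated needle. Flow past the heated needle cools it, so
\(\Delta T\) is maximal at zero flow. The flow index is
\[
K = \frac{\Delta T_{max} - \Delta T}{\Delta T},
\qquad J_s = a\,K^{b},
\]
with the original empirical calibration \(a = 42.84\) g cm\(^{-2}\)
h\(^{-1}\) and \(b = 1.231\). The coefficient is the classical
\(119\times10^{-6}\) m\(^3\) m\(^{-2}\) s\(^{-1}\) converted to a mass flux
(\(\times 100\) cm m\(^{-1}\) \(\times 3600\) s h\(^{-1}\), sap density
assumed 1 g cm\(^{-3}\)); the conversion is asserted in the test suite
rather than trusted. Negative \(K\) from nocturnal noise is clipped to zero
and counted (`computeK()`); it is not an error.

**Zero-flow baseline.** Field deployments rarely log a designated zero-flow
\(\Delta T_{max}\), so `estimateDeltaTmax()` takes, for each day, the
maximum predawn (00:00–06:00) differential within a centred moving window
(default `windowDays = 10`). The moving maximum tracks slow sensor drift
and is robust to individual nights with non-zero flow: only one predawn
record at true zero flow per window is needed. Because a maximum over
~120 noisy records rides ~2.5 SD above the true baseline, the
differential is first smoothed with a centred running mean
(`smoothRecords = 5`, i.e. 2.5 h) — exact under zero flow, and enough to
keep the median daily-maximum flux error below 5 % at the default 0.05 K
sensor noise. A known (e.g. seasonal
constant) baseline can be supplied to `sensorFlux()` instead, which makes
the inversion exact.

Each tree carries a north- and a south-facing sensor; `combineAzimuths()`
averages them per timestamp and falls back to the surviving sensor where
one record is missing (counted, logged).

### Radial correction and whole-tree scaling

The TDP probe senses only the outer 20 mm of xylem, while conductive depth
profiles differ strongly between species. HFD observations (mean daily flux
at eight depths, 1 cm apart) are normalized to the TDP reference —
by default the *mean over the 0–2 cm span*, because that is what the 20-mm
probe physically integrates; a value-at-1-cm alternative is selectable —
and fitted with a Gaussian
\(f(d) = A e^{-(d-\mu)^2/(2\sigma^2)}\) (`fitGaussianProfile()`).
The effective conducting area is the solid of revolution
\[
A_{e\!f\!f} = \int_0^{D} f(d)\; 2\pi\,(R - d)\; \mathrm{d}d ,
\]
with \(R\) the under-bark radius (DBH/2 minus a 1-cm bark allowance) and
\(D\) the integration limit, `min(8 cm, R)` by default (the HFD sensing
span; whether one should integrate to the sapwood boundary instead is
unknowable without sapwood measurements, so `D` is configurable).
Because \(f\) is normalized to the TDP reference, whole-tree water use is
simply
\[
WU\;[\mathrm{kg\,day^{-1}}] = J_{s,sum}\;[\mathrm{g\,cm^{-2}\,day^{-1}}]
\times A_{e\!f\!f}\;[\mathrm{cm^2}] \times 10^{-3}.
\]
When HFD measurement fails for a species (it does, by design, for the
evergreen in the synthetic study), `substituteProfile()` assigns the mean
*fitted parameters* of a donor species — averaging parameters rather than
raw profiles is robust to missing depths — and flags the substitution in
every downstream table.

### Microclimate

VPD is computed from air temperature and relative humidity with the Magnus
saturation-pressure form \(e_s(T) = 6.112\,
\exp(17.62\,T/(243.12+T))\) hPa, \(VPD = e_s(T)(1-RH/100)\). The
coefficients are package constants, exposed because several Magnus variants
circulate. Daily aggregation (mean, and maximum for VPD) requires 80 % of
the 48 half-hourly records by default (`minCoverage`); partial days are
flagged missing rather than averaged. The daily VPD entering the analyses
is the 24-h mean, with a daytime-only (06:00–18:00) option, since field
reports rarely state which was used. Sites with failed hygrometers can
alias another site's humidity channels through the reader's `alias` map
rather than by editing data.

Moisture periods follow the two-week convention: a *dry* period is a run of
at least 14 consecutive days with daily SWC < 15 %, a *wet* period > 25 %;
maximal qualifying runs are trimmed to exactly 14 days from their start for
the contrasts. Thresholds and window length are configuration keys.

## 2. The statistical battery

* **Driver regressions** — OLS of daily mean \(J_s\) on daily SWC per
  species × elevation (`regressFluxOnSWC()`), and logarithmic regressions
  \(J_s = a + b\ln(VPD)\) within wet or dry periods
  (`regressFluxOnVPD()`).
* **Wet/dry maxima** — per-tree maxima of half-hourly \(J_s\) within each
  moisture period, summarized as group mean ± SD with a one-way ANOVA and
  Tukey-HSD compact letters (`jsmaxSummary()`).
* **Mixed model** — `fitMixedModel()` fits, by REML,
  daily \(J_s\) on SWC, VPD, species, elevation (fixed), DBH (covariate),
  exactly the six two-way interactions SWC:VPD, SWC:species,
  SWC:elevation, VPD:species, VPD:elevation, species:elevation, and a
  random intercept per tree. Covariates are mean-centred before
  interactions are formed (collinearity; reversible via the stored means)
  and factors are coded sum-to-zero, so testing a term's coefficient block
  gives marginal (type-III style) tests. An empty species × elevation cell
  — the design has no evergreen trees at the top site — simply loses its
  inestimable interaction contrast (the term's numerator df drops from 6
  to 5).
* **Denominator df** — the package computes Satterthwaite degrees of
  freedom itself: the covariance of the fixed effects as a function of the
  variance parameters \((\theta, \sigma)\) uses the Woodbury identity
  (cheap for a single scalar random intercept), the asymptotic covariance
  of \((\hat\theta, \hat\sigma)\) comes from a numerical Hessian of the
  unprofiled REML deviance, and multi-df terms combine per-eigenvector
  one-df Satterthwaite values (Fai–Cornelius). On balanced designs this
  reproduces the classical split-plot df exactly (asserted in the tests
  against a tree-means ANOVA oracle).
* **Variance explained** — marginal and conditional R² follow the
  variance-partition formulation:
  \(R^2_m = \sigma^2_f/(\sigma^2_f+\sigma^2_{tree}+\sigma^2_e)\) and
  \(R^2_c = (\sigma^2_f+\sigma^2_{tree})/(\cdot)\), with \(\sigma^2_f\)
  the variance of the fixed-effect predictor.
* **Least-squares means** — `lsMeans()` evaluates model-implied adjusted
  means, or marginal SWC/VPD sensitivities (finite-difference slopes of
  the fixed predictor), per species × elevation at reference covariate
  values (sample means), with Satterthwaite df per contrast,
  Tukey-adjusted (studentized range) pairwise comparisons and an
  insert-absorb compact letter display. Cells absent from the data are
  reported absent, never extrapolated. Both slopes and adjusted means are
  computed and labelled, since "trend" can mean either.
* **Hysteresis** — `buildLoop()` averages a group's half-hourly flux to
  hourly vertices (matching how such loops are classically constructed;
  a half-hourly option exists because observed peak times are often
  reported on the half hour), closes the (VPD, \(J_s\)) polygon, and
  reports the shoelace signed area. Clockwise rotation — flux peaking
  before demand — corresponds to a negative signed area with x = VPD. The
  wet/dry contrast reports \(|area|_{dry}/|area|_{wet}\) and the flux
  peak-time shift.

## 3. The synthetic world

`simulateStudy()` generates the full design the package is validated
against: 3 elevations (670/860/1100 m), four species — a stem-succulent
deciduous, a deciduous, a brevi-deciduous and an evergreen — with 4 trees
each except no evergreen at the top site (44 trees), over
January–June 2015. DBH is drawn per species × elevation from the design's
reported means ± SD. All functional forms below are *modelling choices of
the generator*, not estimates: they exist to give the statistical stages
known, recoverable structure.

* **Temperature**: diurnal sinusoid (amplitude 5 K × a lognormal daily
  weather factor, peak 14:30) around a 23.7 °C lowland mean with a
  6.5 K km\(^{-1}\) lapse.
* **Humidity**: anti-phased with a mid-afternoon dryness bump (peak
  15:30, exponent 3 — the sharpened bump keeps mornings humid, pins the
  VPD peak near 15:30, and gives daily mean/max flux ratios near the
  half-sine value so that whole-tree water use lands at the reported
  magnitude, ~10² kg day\(^{-1}\) for the largest stem succulents).
  Nights sit near saturation, so nocturnal VPD is below the stomatal
  activation threshold (0.5 hPa) and true nocturnal flux is zero — this
  is what makes the predawn \(\Delta T_{max}\) identifiable, as in real
  TDP practice.
* **Soil moisture**: a deterministic seasonal envelope per elevation
  (dry January, wet-season plateau late March–April, drydown from May)
  plus AR(1) weather noise and stochastic rain pulses with exponential
  drydown (pulse probability by month, none in January). Envelopes are
  ordered 670 < 860 < 1100 m in every month, reproducing the gradient's
  soil-moisture ordering. Two deliberate departures from the emulated
  study's monthly tables: January at the top site is held below 15 % and
  the low-site wet plateau slightly above 25 %, so that *every* site
  exhibits one classifiable two-week dry and wet period — without them
  the wet/dry contrasts would be undefined for some sites, which the
  real study did not face over its longer campaign.
* **Flux response**:
  \(J_s(t) = S\, s_f \left[1-e^{-(VPD(t+\tau)-v_t)_+/v_0}\right]
  g(SWC)\,foliage(t)\,a_{dry}(t)\,\epsilon(t)\) with a per-tree lognormal
  size factor \(s_f\) (σ\(_{log}\) 0.2), multiplicative lognormal noise
  (σ\(_{log}\) 0.15) and a logistic soil-moisture response \(g\):
  *increasing* (midpoint ~10 %, scale 4 %) for the three deciduous
  classes, *decreasing* (midpoint 15 %, scale 25 %) for the evergreen,
  whose deep roots decouple it from topsoil drought. Defoliated days
  carry a 1.5 % residual. Base fluxes (12–26 g cm\(^{-2}\) h\(^{-1}\))
  were set so *realized* daily maxima — after saturation, the logistic
  and noise inflation of maxima — fall in the reported
  wet-season ranges (~10–16 g cm\(^{-2}\) h\(^{-1}\)). The phase lead
  \(\tau\) (flux anticipating demand: clockwise hysteresis) is 2–4 h wet;
  under dry soil it drops to 0 h for the deciduous classes (flux peak
  drifting to mid-afternoon) but only to 3 h for the evergreen, and the
  dry-state amplitude factor is 0.8–0.85 (deciduous) versus 1.2
  (evergreen) — together these encode the qualitative contrast that dry
  soil shrinks deciduous hysteresis loops and enlarges the evergreen's.
* **Sensors**: true \(J_s\) is inverted through the Granier equation with
  per-sensor \(\Delta T_{max} \sim N(10, 0.5^2)\) K, a ±3 % azimuthal
  flux asymmetry and 0.05 K additive noise.
* **Radial profiles**: Gaussian truths centred at 2 cm (stem succulent),
  0 cm (deciduous, bark maximum) and 1 cm (brevi-deciduous); amplitudes
  are fixed by the normalization convention (mean over 0–2 cm = 1). The
  evergreen generates no profile — its HFD "fails" — so the pipeline must
  substitute, as its field counterpart did.

**What the generator does not emulate:** rainfall interception and fog,
radiation (sunny days are proxied by daily VPD amplitude), stem water
storage dynamics (the hysteresis lead is imposed, not emergent from
capacitance), temporal autocorrelation of flux noise, sensor wounding
drift, and within-tree azimuthal heterogeneity beyond a fixed offset.
A green test therefore establishes that the pipeline recovers structure of
this kind when present — not that the field estimates themselves were
unbiased.

`simulateResponseTable()` is a second, direct simulation harness for the
mixed model only: it draws a tree-day table straight from the linear mixed
model in the model's own coding, so type-I error (all effects null) and
CI coverage (the documented non-null configuration: SWC 0.05, VPD 0.4,
species and elevation main contrasts 0.5/−0.4, DBH 0.02, SWC:species 0.2,
SWC:VPD 0.01) can be checked against exact truth without inverting the
whole measurement chain.

## 4. Numerical choices

* Conducting-area quadrature splits the integral at the Gaussian's
  \(\mu \pm \{1,4\}\sigma\) (clamped to \([0, D]\)) so narrow peaks and
  steep tails cannot slip between adaptive nodes; the brute-force annulus
  sum handles its final partial annulus explicitly. The two routes agree
  to 0.1 % over randomized profiles (tested).
* Profile fitting uses bounded `nls` (port): \(A \in (0,10]\),
  \(\mu \in [-2, d_{max}+2]\), \(\sigma \in (0.1, 20]\) cm, started at the
  profile maximum with \(\sigma = 2\) cm. A parameter ending on a bound
  flags the fit degenerate (e.g. a constant profile), triggering the
  species-mean fallback.
* Satterthwaite df uses central finite differences for contrast-variance
  gradients and `numDeriv::hessian` for the REML information; df below 1
  are floored only inside the studentized-range call (such contrasts carry
  no information — they arise in deliberately degenerate configurations
  like one tree per cell).
* Determinism: every stochastic operation takes a seed; the study
  generator derives per-stage sub-seeds (kept below 2³¹) from one master
  seed, and identical configuration + seed reproduce byte-identical
  fixture and output files (tested via md5).
* Period classification requires *every* day of a window to pass the
  threshold; ties between equally demanding loop days resolve to the
  first maximum (`which.max`).

## 5. Known limitations

The Satterthwaite machinery is implemented for the package's model class —
a single scalar random intercept — and refuses richer random structures.
The Granier calibration is used as universal; species-specific
recalibration and wound corrections are out of scope, as are heat-ratio
methods, stand-level upscaling and mechanistic storage modelling. The
generator's drought responses are stationary within the season; real
phenology (early leaf flush of stem succulents after isolated rain events)
is represented only through the fixed foliation calendar.
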