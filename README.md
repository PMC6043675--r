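# sapflux

Sap-flow processing and drought-response analysis for trees measured with
thermal dissipation probes (TDP), written for ecophysiologists studying how
co-occurring species with different drought strategies — deciduous,
stem-succulent deciduous, brevi-deciduous, evergreen — regulate water use
as soil moisture and atmospheric demand change.

The package covers the full chain from raw probe signals to inference:

1. **TDP conversion** — zero-flow baseline ΔTmax by predawn moving maximum,
   Granier's index K = (ΔTmax − ΔT)/ΔT and calibration
   Js = 42.84 · K^1.231 (g cm⁻² h⁻¹), azimuth averaging, daily summaries.
2. **Radial correction** — HFD depth profiles normalized to the TDP span,
   fitted with a Gaussian f(d) = A·exp(−(d−μ)²/2σ²), and rotated around
   the stem axis: A_eff = ∫₀ᴰ f(d)·2π(R−d) dd; whole-tree water use
   WU = Js,sum × A_eff / 1000 (kg day⁻¹), plus the WU–DBH scaling fit.
3. **Drivers** — VPD from T/RH by the Magnus form, daily aggregation with
   coverage control, and two-week dry (SWC < 15 %) / wet (SWC > 25 %)
   period classification.
4. **Statistics** — per-species SWC regressions and ln(VPD) regressions by
   moisture period; wet/dry Jsmax ANOVA with Tukey letters; a linear mixed
   model of daily Js (SWC, VPD, species, elevation, DBH, six two-way
   interactions, random tree intercept) with Satterthwaite denominator df,
   marginal/conditional R², and least-squares means/sensitivities.
5. **Hysteresis** — diurnal (VPD, Js) loops, shoelace signed area,
   rotation direction, peak times, and wet/dry loop contrasts.
6. **Synthetic study** — a generator that emulates the study design
   (3 elevations, 4 species × 4 trees, no evergreen on top, 44 trees;
   elevation-ordered soil moisture; species-specific drought responses)
   and exports full ground truth, so every stage is testable end to end.

## Worked example

Simulate the default synthetic study and run every pipeline stage:

```r
library(sapflux)

dir <- tempfile("study")
runPipeline(dir, config = studyConfig(), seed = 1)

read.csv(file.path(dir, "dbh_scaling.csv"))
#>   slope intercept     r2        p  n
#> 1 1.411    -13.31 0.9415 1.6e-27 44

read.csv(file.path(dir, "r2.csv"))
#>     r2m   r2c varTree varResid
#> 1 0.614 0.875   0.626      0.3

head(read.csv(file.path(dir, "loop_contrasts.csv"))[,
  c("group", "areaRatio", "rotationWet", "jsPeakShift")], 4)
#>           group areaRatio rotationWet jsPeakShift
#> 1     Ceiba_670    0.0191   clockwise           1
#> 2 Eriotheca_670    0.0389   clockwise           3
#> 3 Erythrina_670    0.0171   clockwise           2
#> 4  Capparis_670    2.8490   clockwise           1
```

Reading the output: whole-tree water use rises ~1.4 kg day⁻¹ per cm of
stem diameter across species (R² = 0.94 on 44 trees) on sunny wet-period
days. The mixed model explains 61 % of daily-flux variance with the fixed
drivers alone and 87 % including tree identity. All diurnal hysteresis
loops rotate clockwise (flux peaks before demand); under dry soil the
deciduous species' loop areas collapse (ratios ≪ 1) and their flux peaks
shift later, while the evergreen's loop area grows (ratio > 1) — the
drought-avoidance vs drought-tolerance contrast the statistics are built
to detect.

Individual stages are plain functions on plain objects, e.g.:

```r
computeVPD(25, 50)            # 15.80 hPa
kToFlux(0.25)                 # 7.78 g cm-2 h-1
st <- simulateStudy(studyConfig(), seed = 1)  # full study + ground truth
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch
— it simulates the default study at the given seed and executes all seven
pipeline stages against the installed package — and writes the target
report as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

- `R/` — implementation (S4 classes for series, profile fits, loops,
  model results, synthetic studies; camelCase exported functions).
- `tests/testthat/` — unit, property and acceptance tests (all fixtures
  generated in code).
- `vignettes/sapflow-methods.Rmd` — models, assumptions, generator design,
  numerical choices, limitations.
- `scripts/acceptance.R` — see above.
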