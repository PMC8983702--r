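---
title: "Quantifying a hotter-drought fingerprint from tree-mortality sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying a hotter-drought fingerprint from tree-mortality sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdfingerprint)
library(dplyr)
```

## The scientific question

Episodes of climate-driven tree die-off have been documented on every
forested continent. A recurring hypothesis is that these events share a
common climatic driver: *hotter drought* — drought co-occurring with
anomalously high temperatures. `hdfingerprint` implements a pipeline to
test that hypothesis quantitatively from two inputs:

1. a geo-referenced table of field-documented mortality plots, each with
   a mortality onset year, and
2. monthly series of six climate variables at those locations — maximum
   temperature (TMAX, °C), vapor pressure deficit (VPD, kPa), climatic
   water deficit (CWD, mm), soil moisture (SOIL_M, mm), precipitation
   (PPT, mm) and the Palmer Drought Severity Index (PDSI) — on a
   1/24° monthly grid covering 1958–2019.

The *hotter-drought fingerprint* is the joint pattern of warm/dry
anomalies across all six variables in the mortality onset year,
composited across sites.

## The procedure

**Gridding and deduplication.** Plots are validated
(`read_plot_table()`), assigned to 1/24° cells with a fixed
north-west-origin floor convention (`assign_grid_cell()`), and collapsed
to one *site-event* per occupied cell (`deduplicate_to_sites()`) so
dense plot networks do not dominate composites. When member plots
disagree on the onset year, the site takes the modal year with ties
broken to the earliest; the source literature does not dictate a rule
here, and the earliest onset is the conservative choice for epoch
alignment (a late choice would label pre-onset drought years as
"after onset").

**Biomes.** Sites are placed in Whittaker biome space by mean annual
temperature (°C) and precipitation (cm/yr), classified by
point-in-polygon test against a polygon table shipped with the package
(`whittaker_polygons()`), a coarse digitization of the classic Whittaker
diagram bounded above by the moisture envelope `MAP = 10·MAT + 150`.
Shipping and checksumming the table removes a runtime dependency and
pins the classification across versions. Shared polygon edges resolve by
a fixed priority order; anything outside every polygon — e.g. 800 cm of
precipitation at 5 °C — is labelled `outside`. The six analysis
variables do not include mean air temperature, so when normals are
derived from the climate table (`climate_normals()`), MAT is
approximated as mean TMAX minus a fixed offset (default 7.5 °C, about
half a typical diurnal range); supply true mean-temperature normals and
an offset of zero where available.

**Climatology and anomalies.** For each site and variable the monthly
climatology over the reference period (default: the full 1958–2019
record) gives per-calendar-month means and standard deviations
(`monthly_climatology()`). The *sample* (n−1) standard deviation is
used; the self-normalization property — z-scores of all
reference-period values of a month have mean 0 and sd 1 — is exact
under that convention and is tested to 1e-9. The climatological extreme
month (`find_extreme_month()`) is the month with the highest long-term
mean for TMAX/VPD/CWD and the lowest for SOIL_M/PPT/PDSI, fixed from
the reference climatology (not re-chosen per year, which would bias
anomalies upward) with ties to the earliest month. Anomalies of the
extreme month are standardized to z-scores; the water-balance variables
are sign-flipped to *oriented* z-scores so positive always means
warmer/drier. `epoch_zscores()` evaluates the nine relative years −4…+4
around each site's onset. Missing values, zero-sd months, and epoch
years outside the record are flagged missing and excluded pairwise —
never imputed, never set to zero.

**Compositing and exceedance.** `composite_fingerprint()` averages
oriented z across sites per variable and relative year (optionally per
biome), with the standard error and a t-based 95% interval; the
t-distribution matters at per-biome sample sizes of order 20. No
multiple-testing correction is applied across the 54 variable × year
cells; intervals are reported per cell. `exceedance_tally()` counts per
site how many variables had oriented z above a cutoff in the onset
year. The cutoff defaults to 0 with a strict inequality — the weakest
reading of "anomalously warm/dry", chosen because no stronger cutoff is
canonical — and is an explicit argument, so stricter definitions (say
0.5 σ) are one keystroke away. `trend_regression()` fits ordinary least
squares of anomalies on calendar year (onset-year anomalies across
sites are restricted to 1970–2018, the span of documented onsets).

**Thresholds and warming scenarios.** `build_threshold_set()` records
each site's onset-year extreme-month values in native units — the local
mortality-year conditions. `count_concurrent_exceedance()` counts, over
a 31-year window (default 1985–2015), the years in which *all six*
variables met or exceeded those thresholds in the extreme direction.
"Met or exceeded" is non-strict by construction: under the identity
scenario the onset year must meet its own conditions, and this
consistency property is tested. Rates are expressed as years per decade
(`10 · count / window_years`, bounded by [0, 10]); a year missing any
extreme-month value at a site leaves both numerator and denominator.
Scenario climates come either from an external pattern-scaled product
(read with `read_climate_long()`) or from the built-in pattern scaler
`apply_warming_scenario()`:

$$x'(m, y) = \mu_m + \delta_m \Delta T + (x(m, y) - \mu_m)\,(1 + \gamma_m \Delta T)$$

with baseline monthly mean $\mu_m$, per-month mean sensitivity
$\delta_m$ (native units per °C of global-mean warming) and fractional
variability scaling $\gamma_m$ (per °C). `default_sensitivities()`
provides synthetic stand-in values of realistic sign and magnitude
(amplified land warming for TMAX, drying for the water-balance
metrics); they exist to exercise the machinery, and real-site analyses
should substitute sensitivities from a pattern-scaled climate dataset.
Scenario warming levels are expressed above pre-industrial; with the
observed window already 0.7 °C above pre-industrial, a "+2 °C" scenario
applies ΔT = 1.3 °C to the baseline. `fit_exponential()` summarizes
frequency versus warming as `rate = a·exp(b·ΔT)` by least squares on
log rate — deterministic and exactly identified enough for three
scenario points; the method tag is recorded in the output. The fit is
to the aggregate mean rates, unweighted; fitting per-site rates is not
attempted because zero rates are common and have no logarithm.

## The synthetic-data generator

Every stage is testable without downloads through `synth_config()` /
`synth_dataset()`. The generator emulates the statistical structure the
analysis relies on:

- **Seasonality**: a 12-month mean profile per variable (defaults:
  mid-latitude profiles peaking in July for the heat metrics, driest
  mid-summer for the water metrics, PDSI centered on 0).
- **Interannual noise**: Gaussian innovations with per-variable sd
  (defaults: 1.5 °C TMAX, 0.35 kPa VPD, 22 mm CWD, 20 mm SOIL_M,
  18 mm PPT, 2 PDSI units).
- **Memory**: optional AR(1) across consecutive months (defaults 0.15
  for TMAX/VPD up to 0.85 for PDSI, whose definition carries
  multi-month water-balance memory; the true interannual dependence of
  PDSI at mortality sites is not documented, so these are modeling
  choices).
- **Cross-variable coupling** via a multivariate-normal copula on the
  monthly innovations (heat metrics +0.6 among themselves, water
  metrics +0.45, heat–water −0.45). Because variables carry different
  AR(1) coefficients, the innovation correlations are internally
  compensated by $(1-\phi_i\phi_j)/\sqrt{(1-\phi_i^2)(1-\phi_j^2)}$ so
  the *stationary* cross-correlations match the configured targets;
  the compensated matrix is re-checked for positive semidefiniteness at
  configuration time.
- **Events**: `inject_events()` shifts each variable's extreme month
  (optionally a 3-month window) in designated years by a configured
  severity in σ units of the *unperturbed* site/month distribution, in
  the warm/dry direction. Defining severity against the unperturbed
  distribution makes recovery targets exact, up to the small
  attenuation caused by the perturbed year re-entering the downstream
  climatology (about 2% of the severity for a 62-year record).
- **Trend**: an optional linear trend per decade per variable.

What the generator does *not* emulate: the physical water-balance
coupling among CWD, soil moisture and PDSI (correlations here are
statistical only), spatial correlation between sites (sites are
independent, which makes composite standard errors conservative
relative to real spatially-clustered networks... and means passing
recovery tests demonstrates statistical correctness of the pipeline,
not fidelity of any particular climate), non-Gaussian tails, and
sub-monthly extremes. `synth_plot_table()` separately generates a plot
*database* with a designed composition — plots clustered into a chosen
number of distinct grid cells with a chosen hemisphere split (defaults:
1303 plots, 675 cells, 471 northern, onsets 1970–2018, matching the
published database composition) — used to test that ingest, validation
and gridding recover designed totals exactly.

## Numerical and design choices

- Grid origin (90°N, 180°W), row index increasing southward, `floor`
  applied exactly as written: assignment is bit-reproducible, and
  boundary coordinates belong to the cell the floor gives.
- The record 1958–2019 contains 62 years; climatology uses all
  available years of the reference period and records the per-month
  count `n` rather than hard-coding a year total.
- Zero-sd months yield *missing* z-scores (flagged), not 0 or ±Inf.
- Tie-breaks are deterministic everywhere: earliest month for extreme
  months, earliest year for modal onset years, first polygon in
  priority order for shared biome edges.
- One master seed drives a run; module-level streams are derived
  deterministically from it, so end-to-end runs are bit-identical
  (`run_full_analysis()` writes md5 checksums of all artifacts into
  its manifest, and the reproducibility test compares them).
- Problem sizes used by the shipped tests are chosen to make
  Monte-Carlo tolerances meaningful at interactive runtimes: 200–300
  sites for parameter recovery (composite SE ≈ 0.05–0.07 σ), 500
  replicates of 25 sites for the null-calibration coverage check
  (binomial 2σ band 93–97%).

## Limitations

- The tally cutoff (oriented z > 0, strict) and the modal/earliest
  onset rule are documented defaults where the field has no canonical
  convention; both are parameters.
- The Whittaker polygon table is a coarse digitization; boundaries
  between adjacent biomes are approximate at the few-cm / fraction-°C
  level, though the tiling is exhaustive and exclusive by construction.
- Climate input is long-format delimited text (site, variable, year,
  month, value); gridded netCDF sources should be point-extracted to
  that layout upstream.
- PPT can be climatologically zero in the driest month at arid sites;
  the zero-sd flag then removes that variable from the site's composite
  rather than fabricating a z-score.
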