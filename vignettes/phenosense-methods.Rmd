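---
title: "Estimating spatially explicit phenological temperature sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating spatially explicit phenological temperature sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenosense)
```

## The scientific problem

Phenological temperature sensitivity — the shift in the timing of budding,
flowering or fruiting per degree of temperature change — is usually reported
as a single number per species. That hides the possibility that individuals
of the same species respond differently in different parts of the range.
`phenosense` estimates sensitivity as a *function of local historic
climate*: the long-term mean annual minimum temperature (MAT) and the
interannual variability of temperature (IVT) at each observation site act as
moderators of the temperature slope, so the fitted model yields a
sensitivity *surface* over (MAT, IVT) that can be projected back onto
geography.

The observational unit is one georeferenced, dated, phenophase-annotated
record of one of six widespread herbaceous species that occur across both
Eurasia and North America: the spring bloomers *Tussilago farfara*, *Ficaria
verna* and *Alliaria petiolata*, and the summer bloomers *Cirsium arvense*,
*Daucus carota* and *Lythrum salicaria*.

## Variables and their construction

**Response.** Day of year (DOY) on a fixed 1–365 scale. Leap years are
handled by clamping: DOY is the ordinal day, with 31 December of a leap year
mapped to 365. This keeps a single common scale at the cost of merging the
last two days of leap years; for spring- and summer-season observations the
distortion is nil.

**Curation.** `filter_observations()` applies the exclusion rules
sequentially — records missing coordinates or date, then records with
unannotatable phenophase, then vegetative records (vegetative plants are
unconstrained in time: rosettes and first-year individuals are visible all
season, so they carry no signal about reproductive timing), then records in
excluded regions (Iceland, Azores, eastern Asia, Australia, as configurable
bounding boxes, since the named regions have no canonical boundary).
Sequential application means each record is counted in exactly one category,
so the per-category counts plus the retained count always reconstruct the
input count; the order is the order just given. The report is returned as a
tibble and logged by the pipeline.

**Seasonal standardized climate (Tstd, Pstd).** Reproductive phenology
responds mostly to conditions directly preceding the event, so the
temperature/precipitation covariate is the mean over a three-month window of
the observation year: January–March for spring bloomers, March–May for
summer bloomers. Both are then mean-centred. The centering group is
configurable (`species`, `species_continent`, `global`); the default centres
within species across both continents, matching the per-species seasonal
windows — a species' records are compared against that species' own typical
season. Precipitation is standardized over the same windows as temperature.
Centering uses monthly *mean* temperature (`tmp`); the long-term metrics
below use monthly *minimum* temperature (`tmn`). At the 0.5° scale the two
are nearly collinear, so the choice is one of convention, not substance.

**MAT and IVT.** For each grid cell, the annual value for year *y* is the
mean of that year's 12 monthly minimum temperatures. MAT is the mean of the
annual values over the full series; IVT is their *sample* standard deviation
(denominator n − 1, the conventional estimator from a finite series). The
series bounds are 1901–2021 inclusive — 121 annual values; we follow the
stated bounds of the climate product rather than a rounded "120-year"
count. Unit tests pin down the intended invariances: MAT shifts one-for-one
with an additive constant while IVT is unchanged, and both are invariant to
month order within a year.

**Cell lookup.** Climate cells are half-open 0.5° boxes `[lower, upper)` in
both axes; a point exactly on a shared boundary belongs to the higher cell.
Out-of-grid points and cells with all-missing series raise errors naming the
offending record — silent nearest-neighbour fallback would hide georeferencing
problems.

## The global model and its fitting

The global model is

```
DOY ~ Tstd*MAT*IVT*species + Pstd*MAT*IVT*species + phenophase*MAT*IVT*species
```

with treatment coding and alphabetical reference levels (configurable; all
marginal quantities are invariant to the reference choice, and a test
asserts this by refitting with permuted levels). With six species and three
reproductive phenophases this expands to 120 coefficients. Fitting is
ordinary least squares via QR decomposition; the coefficient covariance is
`s²(XᵀX)⁻¹`. Rank deficiency is an *error* that names the aliased columns,
never silent column dropping: the design is full-rank on well-formed data,
so a deficiency always indicates a data or specification bug.

AIC uses the full Gaussian log-likelihood including its constant, counting
the error variance as a parameter (`AIC = n log(2π) + n log(RSS/n) + n +
2(p+1)`), so values are directly comparable with the common statistical
software convention; this is verified against an independent reference in
the tests. `aic_select()` requires all candidates to resolve to the same
rows — AIC comparisons across differing observation sets are meaningless —
and reports ΔAIC. Under affine rescaling, covariate scaling leaves AIC
unchanged (the column span is preserved) while scaling the response by *a*
shifts every candidate's AIC by `2 n log a`, leaving rankings invariant;
both facts are asserted as tests rather than assumed.

Gaussian OLS is retained even though DOY is mildly leptokurtic (the model
reports excess residual kurtosis via `residual_kurtosis()`): with tens of
thousands of observations the Gaussian fit is robust, and non-Gaussian
alternatives cannot accommodate the multi-way interactions that are the
point of the analysis. Mixed-effects and robust variants are deliberately
out of scope.

## Marginal inference

The estimated-marginal-means engine is the package's core. A *reference
grid* fixes every model variable at each prediction point: moderators named
in `at` take the supplied values, every factor not in `at` is averaged with
*equal weights* per level (the post hoc convention "averaged across species
and phenophases"; observed-proportion weighting is a one-line change in the
grid weights if wanted), and every remaining covariate sits at its sample
mean — the conventional realization of "statistically controlled". Because
Tstd and Pstd are mean-centred *exactly* (a tested invariant, group means
zero to 1e−9), fixing them at the sample mean and fixing them at zero are
the same thing, so the question of which to use does not arise.

Estimates are linear combinations `c'β`; standard errors are delta-method,
`sqrt(c'Σc)`, exact for linear combinations. The *marginal slope* of a focal
covariate uses the fact that every treatment-coded design column is affine
in any single covariate: the derivative contrast is computed **exactly** as
`X(focal = 1) − X(focal = 0)` evaluated on the grid — no numeric
differentiation, no step-size tolerance. The mixed second derivative (e.g.
the change of temperature sensitivity per °C of MAT) is likewise the exact
four-corner difference. The test suite checks both against centered finite
differences of brute-force averaged predictions (which are exact for linear
models) at 1e−8, and against `emmeans` — which is the independent
cross-check, not the implementation — to the same tolerance.

Out-of-range `at` values warn rather than error: the sensitivity surface is
deliberately evaluated out to the edges of the climatic study box (MAT −5 to
15 °C) even where the observed data do not reach the corners; the delta
method propagates the (large) extrapolation uncertainty honestly.

Pairwise contrasts use Tukey's HSD: adjusted p-values from the
studentized-range distribution with k groups at the model's residual df. At
k = 2 this reduces exactly to the unadjusted t test (q = t√2), and for
k = 4 the implementation is checked against a 10⁶-draw Monte-Carlo
simulation of the studentized range. p-values are two-sided t at the
residual df throughout — single-stratum OLS needs no Satterthwaite
machinery.

## Sensitivity surfaces and variation summaries

`sensitivity_surface()` evaluates the marginal temperature slope on a
regular MAT × IVT grid. Two grids are used by convention: a fine grid (0.2
°C × 0.05 s.d.; 101 × 17 = 1717 nodes) for surfaces and maps, and a coarse
grid (1 °C × 0.1 s.d.; 21 × 9 = 189 nodes) for the headline
intraspecific-variation range; both are config-exposed, and a step that
does not divide its range evenly is an error. Because the pooled marginal
slope is bilinear in (MAT, IVT), its extremes over the box lie at the
corners, which gives an exact corner-evaluation oracle for the range — the
tests exploit this.

`map_sensitivity()` assigns each record the slope at its *exact* (MAT, IVT)
— not the nearest grid node — avoiding discretization artifacts; records
sharing a climate cell share a sensitivity value by construction.
`interspecific_range()` conditions the slope on species instead (averaged
over phenophases, climate moderators at sample means) and reports
Tukey-adjusted pairwise contrasts plus the max–min range.
`precipitation_sensitivity()` applies the same machinery to Pstd and labels
its output in days/mm.

## The synthetic-data generator

The generator exists so that the whole pipeline is verifiable offline by
parameter recovery, and its defaults *are* the study conditions the package
targets: a two-band, two-continent 0.5° grid spanning latitudes 35–65°,
monthly series 1901–2021, with MAT cooling by 0.45 °C per degree latitude,
IVT rising by 0.02 s.d. per degree latitude, and Eurasia 4.91 °C warmer and
0.22 s.d. less variable than North America at equal latitude — the
empirical gradients of the mid-latitude range of these six species.

Monthly minimum temperature is built as a sinusoidal seasonal cycle
(zero-mean over the year, minimum in January, amplitude 10 °C) around the
cell's target MAT, plus a *shared annual anomaly* — one draw per cell-year,
applied to all 12 months — plus independent monthly noise (s.d. 1 °C). The
annual anomaly is the lever that makes IVT tunable: its variance is set to
`IVT² − monthly_sd²/12` so the realized interannual s.d. of annual means
hits the target after the averaged monthly noise is accounted for. This is
the simplest structure in which MAT and IVT can be dialled independently; a
configuration whose implied anomaly variance is non-positive is rejected.
Monthly mean temperature shares the cycle and anomaly with a positive offset
above the minimum (so `tmn ≤ tmp` holds in every cell-month, an enforced
container invariant), and precipitation is an independent seasonal cycle
truncated at zero.

Observations draw a uniform cell within each continent (a sampling-bias
weight knob exists but is off by default — continents are balanced by
design), uniform coordinates within the cell, a year in 2017–2019, and a
phenophase. DOY is generated as

```
DOY = baseline(species) + offset(phenophase)
      + b(MAT, IVT, species) * Tstd + betaP * Pstd + noise,
```

rounded and clamped to [1, 365] (clamped, not wrapped, to respect the fixed
DOY scale), where the truth slope is the bilinear surface

```
b(MAT, IVT) = gamma0 + gammaM*MAT + gammaV*IVT + gammaMV*MAT*IVT
```

plus optional per-species, sum-to-zero offsets. Crucially, Tstd and Pstd in
the generator are computed *through the same covariate machinery the
analysis uses* (same windows, same centering), so the generating process is
exactly representable by the global model and recovery tests are sharp.

**Default truth parameters.** The default surface coefficients
(γ0 = −1.58875, γM = 0.01225, γV = −0.278125, γMV = −0.140625) are the
unique bilinear surface through a 3 × 3 grid of empirically reported
marginal slopes for these species (−1.48 days/°C in cold/low-IVT climates
through −2.31 at mid-range to −4.27 in warm/high-IVT climates), so the
default generator emulates the observed regime: sensitivity strengthens
with MAT, but only where IVT is high. Species baselines place spring
bloomers at DOY 80–115 and summer bloomers at 175–195; phenophase offsets
are 0/+10/+25 days for budding/flowering/fruiting; the species slope
offsets span 2.25 days/°C, sized to reported interspecific extremes; the
precipitation slope is +0.03 days/mm. The residual noise s.d. is not an
empirically reported quantity; the package default of 20 days is a choice,
recorded in the serialized truth config, picked to put the global-model
adjusted R² in the mid-0.8s — the signal-to-noise regime of real
community-science phenology data.

**What the generator does not emulate:** observer effort and spatial
sampling bias (beyond the continent-weight knob), spatial autocorrelation in
residuals, image-level annotation uncertainty, and species range limits
(every species occupies the whole grid). Passing recovery tests therefore
demonstrates the correctness of the estimation machinery under the model's
assumptions, not robustness to these real-data complications.

## Verification strategy and problem sizes

The test suite is oracle-driven: OLS against explicit normal-equations
solutions; marginal means against brute-force prediction averaging; slopes
and trends against centered finite differences; Tukey against the t-test
identity (k = 2) and Monte Carlo (k = 4); ranges against corner evaluation;
and end-to-end parameter recovery — 20 independent replicates of a
24 000-record study (2000 records per species per continent) whose
estimated sensitivity surface must cover the known truth within nominal 95%
confidence intervals at ≥ 90% of the 189 coarse-grid nodes. Module tests
use a shared 3600-record fixture; these sizes keep the full suite around a
minute on one core while leaving the recovery test enough power to detect
systematic bias. `scripts/acceptance.R` re-runs the full-size pipeline from
scratch and writes the headline quantities as JSON.

## Known limitations

- Correlative, not causal: MAT/IVT moderation of sensitivity is a geographic
  association; plasticity and local adaptation are not separable here.
- The MAT × IVT grid corners are extrapolations for real ranges (warm,
  high-IVT climates are rare in-sample); estimates there carry large,
  honestly propagated standard errors.
- Single-stratum OLS ignores spatial and observer-level dependence;
  standard errors may be mildly optimistic on clustered real data.
- The climate container keeps full monthly arrays in memory; at 0.5°
  resolution over continental extents this is fine (tens of MB), but global
  grids would need a chunked backend.
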