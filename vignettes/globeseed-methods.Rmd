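---
title: "Methods: standardizing and modeling global soil seed bank surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: standardizing and modeling global soil seed bank surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(globeseed)
```

## The problem

Soil seed banks — the viable seeds stored on and in the soil — are a hidden
reservoir of future plant diversity. Field surveys of seed bank *diversity*
(species richness per soil sample) and *density* (viable seeds per unit soil
surface) accumulate in the literature, but they are collected with wildly
heterogeneous protocols: different sampling seasons, quadrat areas, and soil
depth slices, and densities reported either per square metre or as raw seed
counts per sample. Before such records can be modeled jointly against
environmental gradients, they must be made comparable. `globeseed`
implements that harmonization, the downstream regression-forest modeling of
both responses against 31 environmental predictors, the accompanying
diagnostics, and the projection of fitted models onto a gridded predictor
stack — together with a synthetic-data generator whose ground-truth ledger
lets every stage be verified quantitatively.

## Standardization model

Records are harmonized to a common convention — winter sampling season,
0.01 m² quadrat, the 0–5 cm depth slice, and seeds per m² — in a fixed,
configurable order: density units, season, area (diversity only), depth.
All corrections are multiplicative ratios applied to the record's value,
never replacements by curve predictions, so record-level variation is
preserved.

**Season.** Seed banks peak in winter. Sampling months are mapped to
hemisphere-aware meteorological seasons (northern DJF = winter, southern
JJA = winter; an explicitly recorded season wins over the month). For each
measure, the ratio $r_s = \bar{y}_{\mathrm{winter}} / \bar{y}_s$ is
computed over all eligible records pooled, and season-$s$ values are
multiplied by $r_s$, making winter the fixed point ($r_{\mathrm{winter}} =
1$). Records from (sub)tropical biomes — decided by biome identity (any
TEOW biome whose name contains "tropical"/"subtropical", plus mangroves),
not by a latitude cutoff — are exempt, because tropical seasonality is
weak; they pass through unchanged but count as seasonally comparable. The
ratio-of-means definition is the default because pairing of individual
records across seasons is undefined across studies; a per-biome
mean-of-ratios variant is available (`fit_season_ratios(method =
"per_biome_mean")`).

**Area.** Diversity follows a species–area power law $S = C A^Z$. $\log S$
is regressed on $\log A$ by ordinary least squares separately per biome
(species–area slopes vary geographically), with a pooled fallback when a
biome has fewer than `min_n` usable records or a single distinct area.
Records are then rescaled by $S_{0.01} = S\,(0.01/A)^{Z}$. Before the fit,
extreme values are capped: a generalized extreme studentized deviate
(Rosner) test flags up to $\max(1, \lceil 0.05\,n\rceil)$ outliers at
$\alpha = 0.05$, and flagged values *above* the sample mean are replaced by
the sample's 95th percentile (linear-interpolation definition, computed on
the full pre-capping sample). Low-side outliers are flagged but kept: the
capping exists to tame the right tail before a log-scale fit, and small
values carry real signal. The test is skipped with a warning below $n =
10$. All of these constants are arguments.

**Depth.** $\log_{10}$ of the value is regressed on the *untransformed*
upper and lower boundaries $(u, l)$ of the sampled slice — boundaries
include 0 cm, so they cannot themselves be log-transformed — per biome and
measure, again with pooled fallbacks. Values move to the 0–5 cm reference
slice via $y_{0\text{–}5} = y \cdot 10^{\,b_1 (0 - u) + b_2 (5 - l)}$.
Empirically the diversity and density of seed banks fall as the slice
starts deeper ($b_1 < 0$) and rise as it extends deeper ($b_2 > 0$); when a
dataset only ever reports slices of one thickness the two boundaries are
collinear and a reduced-rank lower-boundary-only model is fitted and
flagged. **Units.** Density values in the schema are raw seed counts for
the stated `sample_area_m2`; division by the area yields seeds per m².
Sources that already report per m² are encoded with `sample_area_m2 = 1`,
making the conversion the identity (the published schema has no separate
unit column, so the area field carries that information).

Every step is the identity on records already at its convention, sets a
per-record flag, and never drops a record; unstandardizable records simply
keep their value and lack the flag, and the report tallies them.

### Known parameters versus fitted parameters

`run_standardization()` fits all standardization models from the data by
default, but accepts a pre-fitted bundle (`options = list(models = ...)`).
The distinction matters for validation: with the generator's *true*
parameters (via `truth_models()`), standardization inverts the noise-free
generative distortions exactly, record by record — a test of the correction
machinery. With *fitted* parameters the recovery is statistical, not exact,
even at zero noise, because the finite sample induces chance correlations
between the sampling mixtures and the environment-driven latent values; the
right check there is parameter recovery (e.g. $|\hat{Z} - Z|$ small at
realistic sizes), which the tests perform separately.

## Forest models

Both responses are modeled with regression forests of 100 trees (the
`randomForest` engine), reporting two importance metrics: increase in node
purity (the decrease in residual sum of squares attributable to splits on
the variable, averaged over trees) and percent increase in out-of-bag MSE
when the variable's values are shuffled (5 permutation repeats per tree).
Rows with any missing predictor are dropped and counted — no imputation,
and grid cells with missing layers are likewise nodata.

**Variable selection** proceeds in two noise-calibrated stages. Screening:
the candidate matrix is augmented with one shuffled copy of every
candidate; permutation importance is averaged over several seeded forests,
and candidates that do not beat the *maximum* importance attained by any
shuffled copy are discarded. Forward addition: starting from the null model
(mean prediction), surviving candidates are added in rank order and kept
only when the mean OOB-error decrease exceeds a threshold equal to the mean
plus two standard deviations of the absolute OOB-error changes observed
when permuted-copy noise variables are appended to the screened-candidate
model. The threshold is computed against that model rather than a one- or
two-variable model because small forests are unstable and would inflate the
threshold. Counts, forest sizes and the multiplier are arguments. The
number of predictors a run selects is data-driven; nothing is hard-coded.

**Cross-validation** follows a repeated random-holdout protocol: 99
iterations, each withholding 10% of rows, refitting and scoring held-out
MSE and $R^2 = 1 - \mathrm{MSE}/\widehat{\mathrm{Var}}(y_{\mathrm{held}})$.
On data without strong spatial autocorrelation this agrees closely with the
forest's own OOB pseudo-$R^2$, and the tests assert that agreement.

**Partial dependence** is the canonical "marginal effect": the predictor is
clamped to each grid value in every training row and predictions are
averaged. Grid points outside the training range are computed but flagged
as extrapolation. A caveat the tests encode: with deep regression trees,
the partial-dependence curve of a predictor unrelated to the response is
not numerically flat — tree noise leaves wiggle of a few tenths of the
response SD — so flatness is asserted *relative* to an informative
predictor's curve, and shape recovery (e.g. the humped pH response peaking
between pH 6 and 7) is asserted by the position of the curve's maximum.

## Diagnostics

*Semivariogram.* Classical Matheron semivariance per lag bin with
great-circle (haversine) pair distances in km; default 15 bins to half the
maximum pairwise distance. A flat semivariogram near the sample variance
indicates no spatial autocorrelation (the situation in which random
holdout CV is honest). The crude range estimator takes the sample variance
as the sill — the theoretical plateau — and reports the first lag at which
the monotonized semivariance reaches 90% of it; long-lag bin means are
avoided because finite-domain drift biases them.

*Biome contrasts.* Kruskal–Wallis rank tests (tie-corrected, chi-square
reference) compare each measure across biomes. *Hemisphere bias.* For
every biome present in both hemispheres, a Wilcoxon rank-sum test compares
values north versus south of the equator; a rank test was chosen over a
t-test because seed bank values are strongly right-skewed. Single-
hemisphere biomes are reported as skipped.

## Mapping

A `predictor_grid` is a cell-center-registered geographic stack, one matrix
per predictor, with `abs.latit` always equal to |cell-center latitude|.
Prediction is cellwise and identical by construction to
flatten–predict–reshape; cells missing any predictor are nodata. For
display, density maps can be log10-transformed (positive cells only; zero
or negative cells become nodata; the transform is flagged in metadata).
Rasters are read and written as headered plain-text ASCII grids (the
standard six-line header) with a small JSON sidecar for the metadata the
format cannot carry; the format requires square cells. The 5-arcmin
resolution of a production run is configurable; desk-scale analyses and all
tests use coarse small-extent grids.

## The synthetic generator

`generate_dataset()` draws records from configured mixtures of biome
(default 30% (sub)tropical), hemisphere (default 80% northern, mirroring
the literature's sampling imbalance), season, quadrat area (mode at
0.01 m²), and depth slice (mode at 0–5 cm), attaches a 31-predictor vector
(absolute latitude from the coordinate, the others i.i.d. uniform within
plausible ranges), evaluates a latent response from configurable effect
shapes (linear, humped, threshold — e.g. diversity humped in pH around 6.5,
density humped in NPP), and then *distorts* the latent value
multiplicatively: season multipliers (winter = 1, (sub)tropical exempt),
$(A/0.01)^{Z_b}$ for diversity area, $10^{b_1 u + b_2 (l - 5)}$ for depth,
seed-count conversion for a configurable fraction of density records, and
lognormal noise $e^{\sigma \varepsilon}$. Because generation is exactly the
multiplicative inverse of the standardization model, the corrections are
identifiable, and at $\sigma = 0$ exactly invertible given the true
parameters. The truth ledger stores every latent value, every distortion
factor, all true parameters and per-biome tallies.

Default sizes (400 records per measure for pipeline runs; 2,000 diversity
records across four biomes for species–area recovery; 1,000–2,000 rows for
selection experiments) were chosen as desk-scale stand-ins for a
literature compilation an order of magnitude larger: large enough that the
statistical properties under test (exponent recovery within ±0.05, support
recovery of 5 informative predictors among 31) hold with margin, small
enough to iterate on. What the generator deliberately does *not* emulate:
integer-valued species counts (values stay continuous so corrections are
exactly checkable), spatial autocorrelation in the record-level predictors
(record predictors are i.i.d.; only grids are spatially smooth), correlated
predictors (real bioclimatic variables are strongly collinear), and any
taxonomic structure. Passing tests therefore demonstrate that the machinery
is correct and the procedures identifiable under the stated conditions —
not that real compiled data meet those conditions.

## Numerical choices and edge rules

* Percentiles use the linear-interpolation definition (`quantile` type 7).
* Zero values are excluded (and counted) from log-scale fits.
* Zero-thickness depth slices, negative values, and non-positive areas are
  rejected at parse time with row-level diagnostics; `parsed + rejected =
  rows` always.
* Ties in ranks use average ranks (tie-corrected Kruskal–Wallis); ties in
  importance ranking break by first occurrence.
* Seasons derive from months only when the explicit season is missing;
  records with neither remain unstandardized for season and are reported.
* All stochastic operations take an explicit integer seed and record it;
  reruns with the same configuration and seeds are numerically identical.

## Limitations

Standardization uncertainty is not propagated into the forests; the
selection threshold is a heuristic calibration, not a formal test; random
holdout CV is honest only in the absence of strong spatial autocorrelation
(which the semivariogram step is there to check); and the ASCII-grid raster
format carries no CRS beyond implied geographic WGS84 coordinates.
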