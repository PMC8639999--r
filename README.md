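# globeseed

Soil seed banks — the viable seeds stored on and in the soil — are a hidden
reservoir of future plant diversity. Surveys of seed bank **diversity**
(species richness per sample) and **density** (seeds per m²) are compiled
from a century of literature, but with incompatible protocols: different
sampling seasons, quadrat areas, soil depth slices, and density units.
`globeseed` is an R package for macroecologists working with such
compilations. It:

* **harmonizes** records to a common convention — winter season, 0.01 m²
  quadrat, the 0–5 cm depth slice, seeds per m² — using multiplicative,
  per-biome corrections: season ratios
  $r_s = \bar{y}_{winter}/\bar{y}_s$ (with a (sub)tropical exemption), the
  species–area law $S = C A^Z$ fitted by log–log OLS per TEOW biome (after
  capping extreme values with a generalized ESD / Rosner test at the 95th
  percentile), and depth-boundary regressions
  $\log_{10} y \sim b_0 + b_1 u + b_2 l$;
* **models** both responses against 31 environmental predictors with
  100-tree regression forests, reporting node-purity and %IncMSE
  importance, with a noise-thresholded forward variable selection (a
  candidate survives only if it beats shuffled-copy noise variables, both
  in screening importance and in out-of-bag error decrease);
* **validates** by repeated random holdout (99 iterations, 10% withheld)
  and **diagnoses** spatial autocorrelation (great-circle semivariograms),
  biome contrasts (Kruskal–Wallis) and hemispheric sampling bias
  (per-biome rank tests);
* **maps** fitted models onto gridded predictor stacks (plain-text ASCII
  grid rasters, log10 display transform for density);
* **generates synthetic data** with a ground-truth ledger (known season
  multipliers, species–area exponents, depth slopes, and effect shapes
  such as a humped pH response), so the whole pipeline is verifiable
  end to end.

## Worked example

```r
library(globeseed)

cfg <- generator_config(n_diversity = 400L, n_density = 400L, sigma = 0.25)
ds  <- generate_dataset(cfg, seed = 42)
ds
#> Synthetic seed bank dataset: 800 records, 31 predictors
#>   informative predictors (diversity): abs.latit, pH, AP, CEC
#>   informative predictors (density):   npp, PDQ, BULK, TWM

std <- run_standardization(ds$records)
std
#> Seed bank standardization: 800 records
#>   units    applied to 400 record(s), 0 not standardizable
#>   season   applied to 800 record(s), 0 not standardizable
#>   area     applied to 400 record(s), 0 not standardizable
#>   depth    applied to 800 record(s), 0 not standardizable

std$models$area_models$TBMF$Z     # fitted species-area exponent
#> 0.276                           # generator's true Z for this biome: 0.25

tab <- merge(std$records[std$records$measure == "diversity",
                         c("record_id", "value")],
             ds$predictors, by = "record_id")
fit <- fit_forest(tab[, predictor_names()], tab$value, seed = 1)
fit
#> Regression forest: 100 trees, 31 predictors, 400 rows
#>   OOB MSE 343.5, % variance explained 36.6
#>   top predictors (node purity): AP, CEC, pH, abs.latit, PDM

kfold_cv(tab[, predictor_names()], tab$value, seed = 2)
#> Cross-validation: 99 iterations, 10% holdout
#>   held-out MSE 353.9 (sd 109), R2 0.340 (sd 0.096)

kruskal_wallis_by_biome(std$records, "diversity")
#> Kruskal-Wallis among biomes: H = 17.63, df = 13, p = 0.172
```

Reading the output: standardization touched every record (unit conversion
for the 400 density records; season, and depth corrections for all; area
correction for the 400 diversity records). The fitted species–area exponent
(0.276) sits close to the generative truth (0.25). The full 31-predictor
forest explains ~37% of out-of-bag variance and ranks the four genuinely
informative diversity predictors (`AP`, `CEC`, `pH`, `abs.latit`) at the
top; held-out cross-validation R² (0.34) agrees with the OOB estimate. The
Kruskal–Wallis contrast is non-significant here because the generator's
default biome multipliers are all 1.

`select_variables()`, `partial_effect()`, `generate_grid()` /
`predict_grid()` / `log10_display()` continue the pipeline;
`run_all(config)` orchestrates every stage from one (YAML-able)
configuration and returns a manifest with per-stage counts, fitted
parameters, selected variables, CV summaries and — for synthetic runs —
recovery metrics against the truth ledger. A thin command-line wrapper
lives at `inst/cli/globeseed.R` (`validate`, `simulate`, `standardize`,
`run`).

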