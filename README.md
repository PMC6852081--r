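# deltagb

Derivation of IPCC Tier-1 style default rates of **aboveground net biomass
change** (ΔAGB, Mg dry biomass ha⁻¹ yr⁻¹) for natural tropical and
subtropical forests, from plot-level field data to a category-level
default-rate table with uncertainty.

National greenhouse-gas inventories need per-category defaults — a category
being a continent (Africa, North and South America, Asia) × FAO ecozone ×
forest type (younger secondary ≤ 20 yr, older secondary 20–100 yr,
old-growth) — but the underlying evidence lives in two very different kinds
of plot data. `deltagb` implements both estimation paths and the table
assembly that joins them:

- **Chronosequences** (secondary forests). Within each continent × ecozone
  stratum, plot biomass is fitted by the REML linear mixed-effects model

  AGB<sub>ij</sub> = (β₀ + b₀ᵢ) + (β₁ + b₁ᵢ)·ln(t<sub>ij</sub>) + ε<sub>ij</sub>

  with site-level random intercepts b₀ᵢ and slopes b₁ᵢ (lme4; BLUP site
  curves; a documented degradation ladder down to per-site OLS on
  convergence failure). Site rates are chord slopes of the fitted curve:
  AGB(20)/20 for younger secondary, and
  (AGB(t_max) − AGB(20))/(t_max − 20) for older secondary.
- **Permanent plots** (old-growth and managed/logged). Census-interval
  rates are averaged per plot, weighted by plot area × monitoring years,
  and summarised by the weighted mean, weighted SD and a 95% percentile
  bootstrap CI (plots resampled with replacement, 1,000 repetitions).

Secondary categories with ≥ 2 sites get mean ± 1.959964·SD/√n intervals;
managed/logged plots pool into older secondary; categories with
insufficient data are filled by a three-rung recommendation ladder (single
donor continent → best-aligned of two donors → user-supplied IPCC-2006
fallback). A synthetic-data module generates chronosequence and
permanent-plot datasets with known ground truth so every stage is testable
without access to the (undistributed) global plot networks.

## Worked example

```r
library(deltagb)

fx  <- make_study_fixture(seed = 20190816)   # synthetic two-ecozone study
res <- derive_rates(fx$chrono, fx$plots, fx$ipcc2006,
                    seed = 20190816, reps = 1000, cells = fx$cells)
res$rendered
```

```
 Ecozone               Continent         Type Mean Median SD  CI (95%)  n  Status
 tropical_rainforest   Africa            YS   7.1  7.7    1.5 6.0, 8.2  7  derived
 tropical_rainforest   Africa            OS   1.5  1.2    1.4 0.9, 2.2  18 derived
 tropical_rainforest   Africa            OG   1.5  1.4    1.7 0.5, 2.4  20 derived
 tropical_rainforest   NorthSouthAmerica YS   5.8  6.1    1.0 5.2, 6.3  11 derived
 tropical_rainforest   NorthSouthAmerica OS   1.1  1.0    1.2 0.6, 1.7  22 derived
 tropical_rainforest   NorthSouthAmerica OG   1.3  0.5    2.6 -0.0, 2.7 20 derived
 tropical_rainforest   Asia              YS   3.6  3.6    0.4 3.3, 3.9  8  derived
 tropical_rainforest   Asia              OS   1.1  1.0    1.2 0.6, 1.7  22 recommended_from_donor
 tropical_rainforest   Asia              OG   0.2  0.8    2.5 -1.0, 1.6 20 derived
 tropical_moist_forest Africa            YS   2.9  2.8    0.5 2.6, 3.2  11 derived
 tropical_moist_forest Africa            OS   0.4  0.4    0.1 0.4, 0.5  12 derived
 tropical_moist_forest Africa            OG   2.0                          ipcc2006_fallback
 tropical_moist_forest NorthSouthAmerica YS   2.9  2.8    0.5 2.6, 3.2  11 recommended_from_donor
 ...
```

Each row is one category: mean/median/SD and 95% CI in Mg ha⁻¹ yr⁻¹
(rounded half-away-from-zero to 1 decimal only at rendering), `n` the number
of chronosequences and/or permanent plots, and `Status` whether the value
was derived from data, recommended from a donor continent (here the Asian
rainforest older-secondary cell, whose chronosequences are all ≤ 20 yr
old), or taken from the IPCC-2006 fallback config (the moist-forest
old-growth cells, which have no permanent plots in this fixture).
`res$table` holds the same values at full precision;
`res$report` counts records dropped by each inclusion filter (here the one
continental-US record and the one 101-year-old stand built into the
fixture).

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/deltagb simulate --kind fixture --seed 7 --out fx/
Rscript inst/scripts/deltagb derive-rates --chrono fx/chrono.csv \
    --plots fx/plots.csv --ipcc2006 fx/ipcc2006.yaml \
    --seed 20190816 --out table.csv --log report.json
```

## Layout

- `R/` — data IO and filters, growth-curve fitting and site rates,
  weighted plot statistics and bootstrap, table assembly and gap filling,
  synthetic-data generators
- `inst/extdata/` — published refined default-rate table and AGB-at-20
  values (plain-text fixtures), synthetic IPCC-2006 example config
- `vignettes/deltagb-methods.Rmd` — model, assumptions, parameter choices
  and limitations
- `tests/testthat/` — unit, property and end-to-end suites
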