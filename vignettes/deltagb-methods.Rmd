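---
title: "Deriving forest biomass-change default rates with deltagb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving forest biomass-change default rates with deltagb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltagb)
```

## The problem

National greenhouse-gas inventories at IPCC Tier 1 need default rates of
aboveground net biomass change (&Delta;AGB, Mg dry biomass ha^-1^ yr^-1^) for
natural forests: how fast regrowing secondary stands accumulate biomass, and
what the net balance of growth and mortality is in old-growth and
managed/logged stands. `deltagb` implements the full derivation pipeline from
plot-level field data to a category-level default-rate table, where a
*category* is a continent (Africa, North and South America, Asia) crossed
with an FAO tropical/subtropical ecozone and a forest type (younger
secondary &le; 20 yr, older secondary 20--100 yr, old-growth).

Two data sources feed the pipeline:

* **Chronosequences** -- sets of single-visit plots of different stand age
  under similar conditions, a space-for-time substitute for long-term
  monitoring of secondary succession;
* **Permanent plots** -- repeatedly censused old-growth or managed/logged
  stands, each census interval yielding one &Delta;AGB rate.

## Data preparation

Inputs are plot-level CSV tables (`read_chronosequence_csv`,
`read_permanent_plot_csv`). Values reported as aboveground carbon are
converted to biomass by dividing by the carbon fraction cited in the source
or, failing that, the IPCC default CF = 0.47 (`convert_to_agb`). Records in
the continental United States and secondary stands older than 100 years are
excluded, with a machine-readable report of the counts dropped per rule
(`apply_inclusion_filters`). Invalid records (non-positive stand age,
missing biomass, out-of-range coordinates) are rejected with an error rather
than silently dropped, so data problems surface early.

In Africa and Asia, where many sites hold only one or two plots, *proximate*
sites in the same ecozone are merged and treated as a single chronosequence:
sites closer than 1.5 decimal degrees (Africa) or 4.0 degrees (Asia) are
joined by single linkage, i.e. connected components of the below-threshold
graph, which is deterministic and order-independent
(`group_proximate_sites`). Distance is Euclidean in (lat, lon) degrees --
the unit the thresholds are stated in; at these scales the difference from
great-circle distance is immaterial to the grouping decision, and a
great-circle metric would be a straightforward extension. In the Americas
no merging is done and chronosequences need at least 3 plots; a merged
African/Asian chronosequence must retain at least 2 plots at distinct ages,
the minimum that identifies a slope.

## Secondary forests: the growth-curve model

Within each continent x ecozone stratum, plot AGB is modelled as a linear
mixed-effects model on log stand age,

$$AGB_{ij} = (\beta_0 + b_{0i}) + (\beta_1 + b_{1i})\,\ln(t_{ij}) +
\varepsilon_{ij}, \qquad (b_{0i}, b_{1i}) \sim N(0, \Sigma),$$

fitted by REML with lme4. The log transform captures the decelerating
accumulation of biomass with age; the site-level random intercept and slope
give each chronosequence its own curve while borrowing strength across
sites (the site curves use the shrunken BLUP deviations). Fitting is per
stratum because rates are subsequently pooled within that stratum.

Convergence handling is a fixed degradation ladder: if the correlated
random-intercept-and-slope model fails to converge or is singular, the
correlation is dropped, then the random slope, and finally the model falls
back to independent per-site ordinary least squares. The structure actually
used is recorded on the fit object (`fit_method`, `ranef_structure`) and
`converged` is set honestly. A stratum with a single chronosequence goes
straight to per-site OLS. Data in which every site has a single distinct
age raise a rank-deficiency error.

Site-specific rates are chord slopes of the fitted curve
(`ys_rate`, `os_rate`, `site_rates`):

* **younger secondary**: predicted AGB at 20 years divided by 20 --
  a straight line from the origin, i.e. an assumption of linear
  accumulation over the first 20 years that is intended to be unbiased *on
  average* in a bookkeeping context rather than instantaneous;
* **older secondary**: (AGB at the site's maximum age minus AGB at 20
  years, or at the youngest age if the site starts after 20) divided by the
  age difference.

Sites whose plots are all &le; 20 yr contribute only a younger-secondary
rate; sites entirely > 20 yr only an older-secondary rate anchored at their
youngest age. The curve is never extrapolated beyond a site's maximum
observed age. Negative predictions and negative rates are retained, never
clamped: declining stands are real.

## Permanent plots: weighted category statistics

Census-interval rates are averaged per plot (plain mean across intervals;
interval-length weighting is available but off by default, matching the
convention that the plot mean is a simple mean). Plot weights default to
area x total monitoring years -- larger, longer-monitored plots estimate
their stand's rate more precisely -- with `area_only`, `years_only` and
`equal` as config alternatives; if every plot in a category shares the same
area and monitoring period, weights collapse to 1 (`plot_weight`,
`permanent_plot_summaries`).

Old-growth categories are summarised by the weighted mean, the
frequency-style weighted SD
$$\sqrt{\frac{\sum w_i (x_i - \bar x_w)^2}{\frac{M-1}{M}\sum w_i}},$$
(which reduces to the sample SD under equal weights and is invariant to
rescaling the weights), an unweighted median, and a 95% percentile
bootstrap CI with 1,000 repetitions, resampling plots -- the independent
units -- jointly as (rate, weight) pairs (`bootstrap_ci`,
`estimate_og_category`). The percentile method (not BCa) is used; the
bootstrap seed is an explicit argument (default 20190816) so every run is
reproducible.

## The default-rate table

Site rates are pooled per category (`derive_rates`). Managed/logged plot
means are combined into the older-secondary category of the same continent
and ecozone, entering unweighted as one observation each -- consistent with
secondary categories being unweighted throughout. Secondary categories with
&ge; 2 sites get mean, median, sample SD and the analytic z interval
$\bar x \pm 1.959964\, SD/\sqrt n$ (`normal_ci`); the z form (rather than
t) is adopted because it exactly reproduces the published refined default
tables at 1-decimal rounding, which the t interval does not. Old-growth
categories with &ge; 2 plots get the weighted/bootstrap summary above.

Categories with fewer than 2 sites fall to a three-rung recommendation
ladder (`fill_gaps`):

1. exactly one other continent has a derived rate for that ecozone and
   forest type: copy it (`recommended_from_donor`);
2. both other continents have one: choose the donor whose mean is closest
   (mean absolute difference) to the derived means of the *other* forest
   types in the target continent and ecozone; ties break to the donor with
   more sites, then to the fixed order Africa, Americas, Asia (the
   alignment rule needs a deterministic tie-break, which is a package
   decision);
3. no donor anywhere: the user-supplied IPCC-2006 default, with older
   secondary and old-growth both mapped to the 2006 ">20 years" class.

Derived cells are never overwritten and `fill_gaps` is idempotent. The
IPCC-2006 values are configuration, not package data (a YAML schema,
`read_ipcc2006_config`); the shipped
`inst/extdata/ipcc2006_synthetic.yaml` is a synthetic example, not the real
2006 table. Rounding (half away from zero, one decimal) is applied only at
rendering (`render_table`); the pipeline keeps full precision internally.

## The synthetic-data generators

`simulate_chronosequences` draws site deviations from a bivariate normal
with chosen SDs and correlation, plot ages uniformly (or log-uniformly, to
emulate the real-world skew toward young stands) over an age range, and
adds Gaussian residual noise; AGB is floored at 0 -- biomass cannot be
negative -- and the flooring count is reported so tests can detect when the
floor distorts the linear model. The truth ledger records each site's
analytic younger-secondary rate $((\beta_0+b_{0i}) +
(\beta_1+b_{1i})\ln 20)/20$ and the chord-slope older-secondary rate
between its realised anchors. Default parameters (30 sites of 8 plots,
$\beta_0 = 10$, $\beta_1 = 35$ Mg/ha per ln-year, random-effect SDs 10 and
5, residual SD 10 Mg/ha, ages 1--80 yr) describe a well-sampled tropical
stratum.

`simulate_permanent_plots` draws plot true rates $N(\mu, \sigma_{plot})$
(negative $\mu$ allowed -- declining old-growth categories exist), census
rates around them with SD $\sigma_{census}$, and areas/monitoring spans
uniform over their ranges (defaults: 0.25--10 ha, 5--30 yr, 1--5 censuses,
$\sigma_{plot} = 2$, $\sigma_{census} = 1$ Mg ha^-1^ yr^-1^ -- typical of
tropical plot networks). Both generators are byte-reproducible given a
seed.

`make_study_fixture` assembles a small two-ecozone, three-continent
end-to-end dataset (40 chronosequences, 80 permanent plots) that contains,
by construction, a record dropped by each inclusion filter, a
managed/logged subset to pool, and empty categories that traverse every
rung of the gap-filling ladder. What the generators deliberately do *not*
emulate: real geography (coordinates are grid points), allometric
measurement error, temporal autocorrelation between censuses, and
heavy-tailed disturbance events. Green tests on synthetic data therefore
validate the estimation machinery, not the field-data quality issues of a
real compilation.

## Numerical choices and validation scale

* ln() is the natural logarithm throughout.
* z = 1.959964 for 95% intervals; CI level, reps and seeds are arguments.
* lmer singularity (tolerance 1e-5), warnings or convergence messages all
  trigger the degradation ladder; per-site OLS with an unidentifiable
  slope (single distinct age) keeps the pooled slope and refits the
  intercept.
* The test and validation suite uses 200 replicate fits of 30 x 8 plots for
  parameter recovery, 500 simulated categories x 1,000 bootstrap reps for
  CI calibration, and 1,000 random instances for the weighted-statistics
  oracle -- sizes chosen to give Monte-Carlo error well below the effect
  sizes being checked while keeping a full run around a minute.

## Known limitations

* The percentile bootstrap mildly undercovers for weighted means of ~30
  heterogeneously weighted plots (effective sample size nearer 20):
  empirical coverage sits at the low edge of 93--95%. BCa or a studentised
  bootstrap would improve this but the percentile method is the normative
  procedure implemented.
* Category CIs reflect between-site dispersion only; uncertainty from the
  growth-model fit itself is not propagated into secondary-category
  intervals.
* The mixed model assumes Gaussian residuals on the AGB scale and a common
  residual variance within a stratum.
* Covariate refinements (precipitation, soil, land-use history) are beyond
  Tier-1 scope and not modelled.

## A worked run

```{r example, eval = FALSE}
fx <- make_study_fixture(seed = 20190816)
res <- derive_rates(fx$chrono, fx$plots, fx$ipcc2006,
                    seed = 20190816, reps = 1000, cells = fx$cells)
res$rendered          # the IPCC-style table, rounded to 1 decimal
res$report            # counts dropped per inclusion filter, merges
write_rate_table(res, "table.csv", "report.json")
```
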