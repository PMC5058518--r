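---
title: "Methods: decadal hindcasting, driver attribution and forecasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decadal hindcasting, driver attribution and forecasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdmdrivers)
```

## The model and the question

White-tailed deer have been expanding into the western boreal forest for
half a century, with two candidate drivers acting at the same time:
climate amelioration (milder winters, longer growing seasons) and the
growth of the industrial land-use footprint (agriculture, forestry cut
blocks, well pads). `sdmdrivers` implements the full chain needed to ask
which driver did the work, cell by cell and decade by decade, using a
fixed logistic species distribution model (SDM):

$$\operatorname{logit} p = \beta_0 + \beta_d\,D + \beta_w\,W +
\beta_f\,F + \beta_{wsi}\,\mathrm{WSI} + \beta_{gs}\,\mathrm{GS}$$

where $D$, $W$, $F$ are the per-cell proportions of deciduous forest,
wetland and total land-use footprint, WSI is a cumulative-mean winter
severity index and GS a cumulative-mean growing season length. The
default coefficients in `sdm_coefficients()` are the published model for
this system (intercept $-10.12$; deciduous $4.98$; wetland $-3.11$;
footprint $9.79$; WSI $-0.07$ per index point; GS $0.11$ per day). The
model itself is *configuration*: the package applies it, it does not
reselect it. `fit_sdm()` exists so that synthetic-data tests can verify
the whole simulate-predict-refit loop recovers those coefficients.

## Climate indices

**Winter severity** (`compute_wsi()`) counts days in the November
1--April 30 window whose minimum temperature is *below* $-17.7\,°C$
and/or whose snow depth is *above* 38 cm; a day meeting both criteria
counts once. Both comparisons are strict, a literal reading of the
defining thresholds. The window spans the calendar boundary and a
"winter year" is labeled by its November; by the true calendar the
window is 181 days, or 182 when the spring falls in a leap year, which
bounds the index. The original index was adapted elsewhere for
snow-water-equivalent inputs; the conversion is not specified in the
defining sources, so this package operates on snow depth in cm as
supplied by the data layer and keeps the threshold configurable --- any
SWE-to-depth translation belongs to input preparation.

**Growing season** (`compute_growing_season()`) starts on the first day
of the first run of at least five consecutive days with mean temperature
$\ge 5\,°C$, searched from March 1, and ends on the first day strictly
after August 1 with minimum temperature $\le -2\,°C$. The defining text
leaves three conventions open, which we fixed as: the season's start is
the *first day of the run* (not its fifth); length is `end - start` in
whole days with the end day exclusive; and if no qualifying frost occurs
the end falls back to December 31. All three are arguments, so a user
who prefers other conventions can change them without touching the
index logic. A year with no qualifying run has season length 0.

Missing days inside either window raise an error listing the gaps ---
the indices are day counts, and silent imputation would bias them.

**Decadal covariates** are cumulative means (`cumulative_mean()`): WSI
averaged from 1961 and GS from 1950, each up to the *label year* of the
decade of interest (the decade "1980" covers 1980--1989 and its climate
means end at 1980). Long-term means are what the model was trained on;
both base years are arguments.

## Decadal landscapes

`footprint_for_decade()` composites three industries with different
temporal rules, all motivated by how each disturbance persists:

* **well pads** are cumulative (sites are not reclaimed and natural
  regeneration is poor); each pad contributes 100 m² by default;
* **cut blocks** age out after 30 years, measured from the decade
  label, because regrowing browse becomes too tall to be useful --- so
  a 1965 cut contributes nothing to the 2000s footprint while a 1970
  cut still does. Cuts with unknown year (a real feature of vegetation
  inventories; the generator reproduces it) are included or excluded by
  a flag, and including them can only increase the footprint;
* **agriculture** comes as census-epoch snapshots; each decade uses the
  earliest epoch at or after its end year (the 1991 ecumene describes
  the 1970s and 1980s, the 2006 ecumene the 1990s and 2000s), unioned
  with earlier epochs because farmland once developed is assumed to
  stay on the landscape.

Overlapping layers are handled by capping the per-cell union at the
cell area, so the footprint proportion never exceeds one. The footprint
snapshot is taken at the decade's last calendar year (the choice
between decade start and end is not forced by the hindcast design; the
end is used and the mapping is configurable via `agri_epoch` /
`cut_age_years`).

Because the land-cover layers come from a different resolution than the
land-use layers, their sum can exceed one. `reconcile_landcover()`
resolves this exactly as the hindcast design prescribes: the excess is
removed from the two land-cover proportions only, in proportion to
their coverage, so development functionally erases cover and
$F + D + W \le 1$ afterwards. The operation conserves
$F + D' + W' = \min(1, F + D + W)$.

## Attribution by counterfactual freezing

For a decade pair, `attribute_change()` predicts probabilities on the
current landscape and on two counterfactuals built by
`counterfactual_landscape()`: one with climate held at the previous
decade (current land use, previous WSI/GS means) and one with land use
held at the previous decade (current climate, previous
footprint/cover). Land cover travels with the land-use factor because
reconciliation ties it to development. The differences

$$\Delta_{clim} = p(\text{curr}) - p(\text{climate held}), \qquad
\Delta_{lu} = p(\text{curr}) - p(\text{land use held})$$

are compared in absolute value and the larger one names the driver.
Three properties matter for interpretation:

* when exactly one factor changed, the other difference is *exactly*
  zero, so attribution is exact --- this is the strongest testable
  guarantee and the suite checks it on 1,000-cell grids;
* the inverse logit is nonlinear, so $\Delta_{clim} + \Delta_{lu}$ need
  not equal the actual change; all three are reported per cell so the
  discrepancy stays visible rather than being renormalized away;
* exact ties ($|\Delta_{clim}| = |\Delta_{lu}| \ne 0$) are measure-zero
  on continuous inputs but must be deterministic: they are labeled
  climate and counted separately in `summarize_attribution()`.

Cells whose presence classification (inclusive $\ge$ threshold, 0.73 by
default --- the training prevalence 218/299) changes between the
decades are flagged as threshold crossings with their driver; downward
crossings are recorded too even though range-expansion summaries
usually report only gains. Summaries count cells; since cells are
equal-area, cell percentages are area percentages.

## Validation

`validation_stats()` assembles the standard accuracy-table row:
sensitivity, specificity, their bootstrap standard deviations,
TSS $= \text{sens} + \text{spec} - 1$, AUC, and prevalence at full
precision. Choices worth stating:

* **AUC** is the rank-sum (Mann--Whitney) estimator with ties counted
  one half; it is provably identical to brute-force counting over all
  presence-absence pairs, and the suite asserts that equivalence to
  $10^{-12}$ on 200 random fixtures, plus agreement with an independent
  reference implementation (pROC).
* **Rate SDs**: the accuracy-table design reports standard deviations
  for sensitivity and specificity without stating a method; we use a
  seeded nonparametric bootstrap (1,000 replicates by default), which
  matches the analytic binomial scale $\sqrt{r(1-r)/n}$ at large $n$.
* **Calibration** (`calibration_fit()`) regresses observed
  presence/absence on the *raw* predicted probability with a binomial
  GLM, exactly as the validation protocol states. This family cannot
  represent the identity curve: even for a perfectly calibrated model
  the maximum-likelihood fit has slope near 5 (the local slope of the
  logit over mid-range probabilities) and an irreducible deviation from
  the identity of about 0.027 on $p \in [0.1, 0.9]$. The conventional
  alternative --- regressing on $\operatorname{logit}(p)$, under which
  perfect calibration means slope 1 and intercept 0 --- is available
  via `regressor = "logit"`. Degenerate (constant-prediction) and
  separated fits are flagged rather than silently reported.
* **Sticky township aggregation** (`aggregate_townships()`): once a
  township records a presence, later absences there are treated as
  false absences. This is a preprocessing step for multi-year survey
  tables, kept separate from the scoring functions.

## Forecasting

`forecast_scenario()` fits per-cell ordinary least-squares trends to
the observed annual index series (`fit_trend()`), optionally restricted
to the canonical fitting windows (WSI 1961--2002, GS 1950--1999).
`forecast_decade()` then extends the cumulative means: observed annual
values are used where available and trend extrapolations beyond the
observed record, with WSI floored at 0 and GS floored at 0 and capped
at 366 (physical bounds). Whether future cumulative means should reuse
observed values or be pure trend values is not forced by the design;
the blended convention is used because it makes the forecast at the
base decade reproduce the hindcast *exactly* (a property the suite
asserts), and it degrades gracefully to the zero-trend case. Land use
and land cover stay frozen at the base decade. With declining WSI
trends and lengthening GS trends the predicted presence set is
non-shrinking across forecast decades, which the suite also checks.

## The synthetic-data generator

No public deposit exists for the original gridded climate surfaces or
the provincial GIS layers, so the generator (`generate_climate()`,
`generate_landuse_history()`, `generate_landcover()`,
`sample_observations()`) emulates their statistical structure:

* **Climate** is generated *constructively*: for each winter a target
  index value is drawn from the configured trend line plus interannual
  noise (`wsi_base + wsi_trend * t + N(0, wsi_sd)`), and exactly that
  many qualifying days are planted in the window (cold, deep-snow, or
  both; cold days are confined to November--February so they cannot
  collide with the growing-season onset). Each calendar year likewise
  gets a planted onset run and season-ending frost matching a drawn
  season length. Daily noise perturbs all temperatures, but planting
  margins keep each day's qualification status as drawn, so OLS on the
  derived annual series recovers the configured slopes up to the
  interannual noise --- the suite verifies 95% of cells recover a
  $-1.0$/yr trend within $\pm 0.3$ over 50 winters.
* **Defaults are the study conditions**: WSI starting near 145 index
  points declining 0.8/yr (inside the observed per-cell range of
  roughly 0.16--2.2/yr declines), GS near 163 days lengthening 0.15/yr
  (observed $-0.06$ to $+0.38$), years 1950--2009 so both cumulative
  bases are covered, training-range land cover (deciduous mean ~0.25,
  wetland a few percent). The WSI level was chosen once so that decadal
  cumulative means pass through the presence-threshold region over the
  simulated half-century --- a range *edge*, which is the setting the
  method is for.
* **Land use** grows as clustered point processes: events attach to a
  small set of nuclei with probability `landuse_clustering`, else fall
  uniformly; a join-count statistic relative to its random-placement
  expectation verifies the clustering. Thirty percent of cut blocks
  lose their year, mirroring real vegetation-inventory data.
* **Observations** are cell-level Bernoulli draws of
  $p \times \text{detection}$, sampled without replacement.

What the generator does *not* emulate: spatially correlated weather
between neighboring cells, precipitation phase, river corridors,
transect-level sampling within cells, or any feedback of deer on the
landscape. Passing tests therefore demonstrate that the pipeline's
logic is correct under the assumed statistical structure, not that the
real-data headline figures are reproduced --- those depend on
proprietary provincial GIS and survey inputs.

## Numerical and testing choices

* Identical seed and configuration give bit-identical outputs; the
  generator derives separate streams for climate (seed), land use
  (seed+1), land cover (seed+2) and the pipeline's validation sampling
  (seed+3, seed+4), and internal seeding preserves the caller's RNG
  state.
* Logistic fits use `stats::glm` with tightened convergence
  (`epsilon = 1e-10`); separation is detected from the fitted-probability
  warning or coefficient blow-up and flagged, with coefficients
  reported as-is (unbounded) rather than hidden.
* Test problem sizes: 1,000-cell grids for attribution exactness, 200
  random fixtures (up to 1,000 records) for the AUC identity, 100
  replicates of $n = 5{,}000$ for coefficient recovery (each
  coefficient within 2 SE in $\ge 90\%$ of replicates, evaluated per
  coefficient), $n = 10{,}000$ for calibration self-consistency, and a
  3x3-cell, 43-year configuration for the end-to-end pipeline
  determinism check. The full suite runs in well under a minute.
* Rasters are written as delimited matrices with a JSON sidecar (rows,
  columns, cell area, row-major from the northwest corner). This
  dialect is bit-stable and needs no geospatial stack; GeoTIFF export
  is out of scope here.

## Known limitations

The calibration family misfit described above means "curve within 0.03
of the identity" is only barely attainable on self-consistent data at
$n = 10{,}000$: the systematic floor is ~0.027, and single-draw
Monte-Carlo noise of a few thousandths straddles the band. The
attribution scheme inherits the non-additivity of the logit; drivers
are labels of the *larger* effect, not a decomposition. Cut-block aging
uses a sharp 30-year cutoff rather than a browse-growth curve. And the
forecast trusts per-cell linearity of climate change, which is the
stated design of the original analysis but grows less reliable beyond a
few decades.
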