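---
title: "Measuring economic and nutrient productivity of integrated aquaculture–agriculture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring economic and nutrient productivity of integrated aquaculture–agriculture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nutriprod` measures what a farm *produces*, not what its household eats.
The unit of analysis is one surveyed aquaculture farm's sample parcel —
a pond plus any agricultural land operated with it — over one cropping
cycle of roughly a year. This vignette documents the models, the
parameters that matter, the synthetic data the tests rely on, and the
design decisions taken where more than one defensible choice existed.

```{r setup}
library(nutriprod)
```

## The two productivity metrics

**Economic productivity** is a per-hectare gross margin:

$$\mathrm{econ} = \frac{\sum_f q_f\,p_f - C}{A},$$

with $q_f$ the whole-product (wet) weight of food $f$ produced, $p_f$ its
unit price, $C$ the farm's variable production costs (stocking, inputs,
harvesting, hired and household labour, as one aggregate), and
$A = \mathrm{land} + \mathrm{pond}$ the parcel area in hectares. Two
assumptions deserve emphasis:

* *Self-consumption is valued at sale prices.* The quantity consumed on
  farm is never stored, only derived ($q_f$ minus quantity sold), and is
  valued at the same unit price as the sold share.
* *Prices are farm-specific where observed.* A farm that sold food $f$
  contributes its own unit price (sales value / quantity sold). For a farm
  that produced but did not sell $f$, the price is imputed by a ladder:
  the median unit price among sellers of $f$ in the same upazila
  (subdistrict), else the sample-wide seller median, else a hard error.
  Each price carries a provenance flag so imputation is auditable. Whether
  and how to impute was genuinely open; the median ladder was chosen
  because it is robust to outlier sales and respects spatial price
  variation. Negative margins pass through untruncated.

**Nutrient productivity** converts production into *annual adult
equivalents per hectare*. For nutrient $n$ with daily adult requirement
$\mathrm{RDA}_n$:

$$\mathrm{AE}_n = \frac{\sum_f q_f\,\mathrm{EP}_f\,c_{fn}}{A \cdot \mathrm{RDA}_n \cdot 365},$$

where $\mathrm{EP}_f \in [0,1]$ is the edible portion and $c_{fn}$ the
concentration per kg of edible portion (stored per 100 g edible, the
food-composition-table convention, and scaled by 10 internally). One AE is
one adult whose full-year requirement the hectare covers. The phrase
"divide by the amount that would equal one daily adult equivalent and
multiply by 365" admits two readings; dividing by $\mathrm{RDA}_n \times
365$ is the one that yields person-year units and magnitudes on the order
of tens of AEs per hectare for a rice-growing pond farm, so that reading
is implemented. AEs are exactly linear in quantities and exactly inversely
proportional to the RDA — both properties are enforced by tests.

Edible-portion correction applies *only* to nutrients, never to
economics: prices are paid for whole product.

### RDA defaults

| nutrient | default daily RDA | unit |
|---|---|---|
| energy | 9,200 | kJ |
| protein | 55 | g |
| calcium | 1,000 | mg |
| iron | 13 | mg |
| zinc | 10 | mg |
| vitamin A | 900 | µg RAE |
| vitamin B12 | 2.5 | configurable, default µg |

All are overridable (`rda_set()`, or an `rda:` YAML block). The B12
requirement is deliberately carried as the bare number 2.5 with an
explicit unit attribute: the source convention for the adult B12 allowance
is µg, and the packaged composition data use µg per 100 g, but the unit is
configuration rather than hard-coded so a user whose composition table is
in other units can stay consistent. The loader warns when a terrestrial
food carries non-zero B12, since B12 occurs only in animal-source foods;
in the packaged table every plant food has zero.

## Typology, trimming, reported percentages

A farm's **aquatic** class is determined solely by presence of prawn and
shrimp among foods with positive quantity (F, FP, FS, FPS); finfish are
present on every in-sample farm because the sample frame is aquaculture
farms. Prawn/shrimp membership is a *data attribute* of crustacean entries
in the composition table (`crustacean_type`), not a hard-coded species
list. The **terrestrial** class is presence of rice and/or any
vegetable/fruit (none, rice, vf, rice_vf). Classification is invariant to
harvest-line order and to splitting or merging lines of one food; a farm
with crustaceans but no finfish is classified by crustacean presence and
logged.

The main analysis sample excludes every farm in a contingency-table cell
with 12 or fewer observations. On the packaged 721-farm reference
distribution this removes four cells and leaves exactly 700 farms.

Reported sample shares and integration rates are rounded **half-up** to
integers (`floor(x + 0.5)`), not banker's rounding: half-up reproduces
every integer percentage derivable from the reference table, which R's
`round()` does not.

## The regression design

Eight outcomes — economic productivity and the seven nutrient AE series —
are regressed by OLS on one identical design matrix:

* twelve sub-category yields in **tonnes per hectare** (four aquatic: carp,
  other stocked fish, unstocked fish, crustaceans; eight terrestrial: rice,
  leafy vegetables, vitamin A-rich vegetables, other vegetables, root
  crops, vitamin A-rich fruits, other fruits, nuts/oilseeds);
* market orientation: share of aquatic production sold (a fraction in
  $[0,1]$ — rescale the coefficient by 1/100 for percentage-point units),
  and 0/1 indicators for any vegetable/fruit and any rice sales;
* household controls: head age, head education, head female, household
  size, dependency ratio, off-farm income, travel time to the nearest
  city, and the operated agricultural-land and pond areas as two separate
  regressors;
* upazila fixed effects (one dummy per subdistrict minus a reference
  level) and an intercept.

Full column rank is verified up front; collinear columns are a named hard
error. Inference defaults to conventional homoskedastic OLS standard
errors — the simplest reproducible reading — with heteroskedasticity-robust
HC1 as a config option, since that is common field practice for survey
microdata. Significance marks are a/b/c for p < 0.10/0.05/0.01.

The **top-3 rule** flags, per outcome, the three statistically significant
(p < 0.10) coefficients of largest absolute magnitude *among the twelve
yields and three market variables only* — never the constant, controls or
fixed effects. Ties break by smaller p-value, then column order. "Largest"
could alternatively mean largest t-statistic; magnitude was chosen and
documented rather than guessed further, and the rule is isolated in
`mark_significance_and_top3()` so an analyst can re-rank.

## The synthetic-survey generator

`generate_survey()` exists so that every pipeline stage is testable
without any external download. It emulates the survey the analysis
assumes, and its defaults are fixed study conditions, not tuning knobs:

* 721 farms allocated over the 4 × 4 system grid at the reference cell
  frequencies; mean parcel size 0.78 ha (log-normal, log-sd 0.6);
* roughly nine aquatic products per farm and 3.5 vegetable/fruit types per
  producing farm, drawn from the packaged 36-food composition table;
* per-food yields log-normal around per-sub-category medians (e.g. 4 t/ha
  rice, 0.35 t/ha per carp species — order-of-magnitude choices for
  southern-delta pond farms, documented in `generator_config()`);
* shares sold zero-inflated Beta with farm-level group means 0.71
  (aquatic), 0.57 (vegetables and fruits), 0.33 (rice);
* covariates from plausible marginal distributions; 12 upazilas.

**Cell allocation.** By default cells are apportioned deterministically by
largest remainder of `n_farms × cell_probs`, which reproduces the
reference table exactly at `n_farms = 721` and hence exactly 700 farms
after trimming — so regression problem sizes are stable across seeds.
`sample_cells = TRUE` switches to true multinomial draws (each farm
drawing its cell in its own substream) for goodness-of-fit testing.

**Ground truth.** Outcomes are generated structurally — quantities flow
through prices and the composition table into productivity — rather than
writing a regression outcome directly, so recovery tests exercise the full
pipeline, not just the fitter. The known linear model lives in the
economic outcome: with one price per sub-category, value per hectare is
exactly $\sum_g 1000\,p_g\,y_g$ (yields in t/ha), and household controls
and upazila offsets enter through the per-hectare cost equation with
Gaussian noise, so the true coefficient vector and error scale are known
exactly. `recovery_config()` switches off the per-food and per-sale price
jitter that the default config adds for realism, making the model exact.
Nutrient outcomes are deterministic given harvests; their only regression
error is within-sub-category species mix, which is why their $R^2$ runs
very high on synthetic data and why coverage is evaluated on the economic
model.

**Determinism.** A master seed drives everything; each farm draws from its
own substream, so farm *i* is identical whether 40 or 40,000 farms are
generated (exactly true under `sample_cells = TRUE`; under deterministic
allocation the cell layout itself depends on `n_farms`). Identical
seed and config give byte-identical CSV output.

**What the generator does not emulate** — and therefore what passing tests
cannot certify about real data: sampling design and weights, panel
attrition, measurement error in recalled quantities, spatial correlation
of salinity and upazilas with farming systems, price–quantity endogeneity,
and seasonality. Real survey analyses should treat the regression output
as correlational, as the per-fit documentation states.

## Numerical choices and degenerate inputs

* Percentages: round half-up; all internal arithmetic in doubles; CSV
  round-trips use full `readr` precision (shortest round-trip
  representation), so write-then-load is exact.
* Decomposition identities (3-group and 12-group AE splits summing to the
  farm total) hold to machine precision and are tested at 1e-9 relative.
* Cost draws in the generator are floored at zero to respect the
  non-negative-costs schema invariant; with the default intercept
  (1,500 US$/ha) and noise sd (300 US$/ha) the floor is ~5 sd away and in
  practice never binds, keeping the ground-truth model linear.
* An empty harvest table is valid and yields all-zero productivity. A farm
  with zero aquatic production is a hard error at classification (outside
  the sample frame). Designs with fewer rows than columns are rejected
  with the observation count rather than a misleading collinearity error.
* Missing composition entries for a produced food are a hard error by
  default; `missing_composition = "skip"` drops such lines with a warning,
  because silent nutrient undercounting is the worst failure mode.

## Problem sizes used by the test-suite

The suite checks algebraic identities with 100 random cases per property,
the OLS engine against an explicit normal-equations oracle on 50 random
small instances, generator calibration on a 10,000-farm sample, pipeline
closure over 20 seeds at the full 721-farm size, and parameter recovery
over 200 replicate surveys at 721 farms (700 after trimming) — sizes
chosen so the whole suite runs in a few minutes on a single CPU while
keeping Monte-Carlo error well below the tested tolerances. The
acceptance script (`scripts/acceptance.R`) recomputes the same quantities
end to end from a single command-line seed.

## Known limitations

* The packaged composition table is a synthetic stand-in with plausible
  values; analyses of real surveys must supply the composition reference
  actually matched to their food list.
* Nutrient productivity is a supply measure; it says nothing about
  allocation, cooking losses, or bioavailability (no retinol/carotenoid
  conversion arithmetic is performed — RAE values are taken as given).
* Currency conversion is a preprocessing responsibility; all monetary
  fields are assumed US$.
* The 12-group resolution is the implemented regression level;
  species-level analyses are possible by relabelling sub-categories in the
  composition table but are not built in.
* Whether parcel denominators should include homestead land beyond pond
  plus agricultural land is an assumption (`area_ha = land_ha + pond_ha`)
  the survey schema cannot resolve.
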