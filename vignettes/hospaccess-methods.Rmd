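---
title: "Quality-weighted spatial accessibility and patient mobility: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-weighted spatial accessibility and patient mobility: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hospaccess)
```

## The problem

In a regionally organized health system, each region funds and runs its own
hospitals, and a patient treated outside their region of residence ("passive
mobility") represents both a financial transfer between regions and a signal
about where patients believe good care is. This package measures, for
elective hip-replacement surgery, (i) how accessible hospital care is from
each municipality, split into the part supplied by in-region and by
out-of-region hospitals, and (ii) how strongly that balance predicts the
share of a province's patients who travel out of region.

## The accessibility model

The engine is an enhanced two-step floating catchment area (E2SFCA) model.

**Step 1 — supply-to-demand ratios.** Each facility $j$ gets
$R_j = n_j / \sum_i P_i w_{ij}$, where $P_i$ is the population aged 55+ of
municipality $i$ (this age band covers nearly all hip-replacement patients,
so it is the demand proxy), $n_j$ is the facility's attraction, and $w_{ij}$
a distance-decay weight. Two attraction variables are run in parallel:
annual intervention volume, and the quality level described below. A
facility whose catchment holds no population ($P_j = 0$) is flagged and
contributes nothing.

**Step 2 — municipal indices.** $A_i = \sum_j R_j w_{ij}$. Restricting the
sum to facilities whose host municipality lies in the same region as $i$
gives the intraregional component, the complement gives the interregional
one; the two add up to $A_i$ exactly, and the *gravity composite*
$A^G_i = A^{INTRA}_i - A^{INTER}_i$ is kept with its sign — negative values
(out-of-region attraction dominates) are substantive, not errors.

**Decay kernel.** $w_{ij} = \exp(-d_{ij}^2 / (0.2\,d^2))$ with catchment
$d = 120$ minutes by private car. At $d_{ij} = 0$ the weight is 1, at the
catchment edge it is $e^{-5} \approx 0.0067$. The model is a *floating
catchment* model, so weights are truncated to 0 beyond 120 minutes by
default; because the Gaussian itself has unbounded support, a flag
(`truncate_beyond_catchment = FALSE`) keeps the tail for sensitivity work.
Weights below $10^{-12}$ are stored as exact zeros — numerically
indistinguishable, and it keeps weight maps sparse. Travel times are inputs
(a centroid-to-centroid OD matrix in minutes); the package never computes
routes. A pair absent from the OD table is treated as unreachable (weight
0), which is how islands without road access are handled; an `excluded`
flag on municipalities additionally drops them from the demand side
entirely. Facilities sit at their host municipality's centroid, so the
intra-municipal distance is 0; multiple hospitals in one municipality share
that centroid.

**Quality level.** $ql \in \{0, 0.2, 0.4, 0.6, 0.8, 1\}$ is a step function
of the facility's risk-adjusted 30-day readmission rate (percent), gated by
volume: 72 or fewer interventions a year give $ql = 0$ outright (the
national minimum-volume standard of 80 with a 10% tolerance, used here as a
fixed constant). Above the gate: $ret_{30} \le 3 \to 1$; $(3,4.5] \to 0.8$;
$(4.5,6] \to 0.6$; $(6,7.5] \to 0.4$; $(7.5,9] \to 0.2$; $>9 \to 0$. Upper
bounds are inclusive, so a rate sitting exactly on a cut takes the better
score. The rate is consumed already risk-adjusted; no adjustment is done
here. Facilities with $ql = 0$ still enter the quality-weighted index with
numerator 0 rather than being dropped, so catchment demand $P_j$ is
identical across attraction variables.

**Aggregation.** Municipal indices aggregate to provinces (or regions) by
the population-weighted mean
$I^G_p = \sum_{i \in p} I^G_i P_i / \sum_{i \in p} P_i$; a province with
zero reference population is emitted as missing with a warning.

## Mobility and the econometric workflow

Passive mobility of a province is
$M = paz^{INTER} / (paz^{INTRA} + paz^{INTER})$, undefined (missing, with a
warning) when no patients were treated. Year differences in $M$ are tested
with a one-way ANOVA across years followed by all pairwise paired t-tests,
pairing provinces by id and using only provinces observed in both years of a
pair — pairing requires matched units, and the package makes that choice
explicit. The pairwise p-values are reported raw by default (a Bonferroni
flag exists): the testing step is descriptive, and the downstream modelling
does not branch on it.

The regression panel joins $M$ in year $t$ with the gravity indices and
covariates of year $t-1$ — accessibility must precede the treatment
decisions it is meant to explain. All variables (response included) are
min-max standardized to $[0,1]$ over the pooled panel, so coefficients are
comparable across regressors; a constant column is an error, not a silent
NaN. The estimator is the province fixed-effects within estimator, equal to
least squares with province dummies (a property the tests enforce against
an LSDV oracle), with heteroscedasticity-consistent HC1 standard errors by
default and cluster-robust (by province) as an option. Model choice is
guided by a Hausman test against a Swamy–Arora random-effects GLS fit;
observations are screened once per model by Cook's distance from the pooled
LSDV fit with the conventional 4/n cutoff (the threshold is exposed in the
configuration — the method, not the cutoff, is canonical); and
heteroscedasticity is diagnosed with the Breusch–Pagan statistic in its
$LM = n R^2$ (Koenker) form. Both a base model (gravity indices only) and
an extended model (plus income, education, waiting times, health
expenditure, specialists, satisfaction, and the north/centre/south position
ordinal) are always fitted.

Two design points deserve emphasis. First, the territorial position code
(0 north, 1 centre, 2 south) is time-invariant, so under province fixed
effects it is collinear with the unit means and is dropped with a loud
warning naming it; obtaining a position coefficient requires the pooled or
random-effects route, and the package surfaces rather than hides this
tension. Second, year dummies are off by default but available
(`year_dummies = TRUE`), since the year ANOVA already characterizes
between-year shifts; both modes are provided because either is defensible.

The Hausman statistic uses classical covariances on both sides, as the
textbook form requires; when the covariance difference is not positive
definite — which genuinely happens when the random-effects fit is badly
misspecified and its estimated variance exceeds the fixed-effects one — the
Moore–Penrose pseudo-inverse is used and a warning emitted, and the
statistic is floored at zero. Users seeing that warning should trust the
fixed-effects fit.

## The synthetic country

The generator (`synthetic_config()`, `gen_country()`) emulates the input
tables of a national outcome registry and census, with ground truth known
for every downstream check:

* **Geography.** Region centres uniform on a 500 km square, province
  centres Gaussian around them (40 km), municipalities Gaussian around
  provinces (15 km). Travel time is Euclidean distance at 60 km/h times
  symmetric log-normal noise (sdlog 0.1) — deliberately *not* a road
  network, so triangle-inequality violations occur as they do on real
  roads, but no realistic highway structure is implied. Municipal 55+
  populations are log-normal (median 20,000, sdlog 0.6): the synthetic
  municipalities are coarser than real communes, roughly
  catchment-sized population blocks.
* **Facilities.** Hosting probability rises logistically with
  log-population (hospitals concentrate in populous places; every region
  keeps at least one, in its largest municipality). Annual volumes are
  negative-binomial (mean 120 scaled by host population, dispersion 8), so
  year-to-year volume variation — which drives the within-province
  variation the panel estimator needs — is over-dispersed as real hospital
  volumes are. Readmission rates are normal (mean 4.5%, sd 2, truncated at
  0) with a +3 percentage-point shift in the southern macro-area,
  reproducing a north–south quality gradient.
* **Mobility.** Generated at province level (the granularity of the
  observed data): $\mathrm{logit}\,E[M] = \alpha_0 + u_p + \beta_I\,
  \mathrm{std}(I^G) + \beta_Q\,\mathrm{std}(Q^G)$ with defaults
  $\alpha_0 = \mathrm{logit}(0.2)$, $u_p \sim N(0, 0.3)$, and ground-truth
  effects $\beta_I = -1$, $\beta_Q = -0.5$ per unit of min-max-standardized
  index. Treated totals are Poisson (incidence 0.5% of the province's 55+
  population) and out-of-region counts binomial. Setting `hausman_corr > 0`
  correlates $u_p$ with the standardized intervention index, violating the
  random-effects assumption on purpose. A patient-level choice model is
  out of scope.
* **Covariates.** Income and education at municipality level (poorer and
  less educated toward the south) aggregated to provinces by population
  weighting; waiting times, health expenditure, specialists and
  satisfaction drawn per region-year and broadcast to provinces; the
  position ordinal from the macro-area. Macro-areas split the region index
  range into thirds.

The `small` preset (3 regions × 5 provinces × 3 municipalities) exercises
every stage in seconds; `study-scale` (15 regions, 87 provinces — twelve
regions with six provinces, three with five — 261 municipalities, index
years 2019–2021, mobility 2020–2022) reproduces the study-scale panel of
87 provinces × 3 years = 261 rows.

What passing tests on synthetic data do and do not show: they verify the
estimators recover known effects under the stated generating model — e.g.
on 100 replicates of an 84-province, 3-year panel the fixed-effects fit of
logit mobility on the standardized gravity indices recovers the negative
ground truth within two robust standard errors in well over 90% of seeds —
but they cannot validate the behavioural assumptions (Gaussian decay,
120-minute catchment, province-level choice) against real patients. With
real registry inputs the same code runs unchanged through `read_inputs()`.

## Numerical choices and degenerate inputs

* Exact partition and conservation are maintained algebraically (dense
  matrix products, no thresholding except the $10^{-12}$ sparsity floor),
  and tested to $10^{-9}$ relative on random instances:
  $\sum_i P_i A_i = \sum_j n_j$ over facilities with nonempty catchments.
* Empty catchments, zero-volume facilities, zero-population provinces,
  zero treated patients, constant covariates, time-invariant regressors
  under fixed effects, and zero-variance paired differences each have a
  documented contract (contribute nothing / missing with warning / hard
  error naming the column) rather than silent NaN propagation.
* An essentially perfect regression fit (residual sum of squares at
  floating-point noise) reports no Cook's outliers: leverage ratios of
  round-off are not evidence.
* Years are independent cross-sections; no interpolation or smoothing
  across years anywhere.
* CSV output uses 15 significant digits so write/read round-trips are exact
  at the documented precision.

## Problem sizes used by the test suite

The suite favours many small seeded replicates over single large runs:
random instances up to 50 municipalities × 10 facilities for conservation
(100 seeds), instances of at most 5 municipalities against a scalar
triple-loop oracle, 100 replicates of the 84-province recovery experiment,
500 replicates for the Breusch–Pagan size check at $n = 100$, and 200 for
its power at $n = 261$ and for Hausman rejection under correlated effects.
These sizes give stable Monte-Carlo estimates of the rates being asserted
while keeping a full run of the suite under a minute.

## Known limitations

* Travel times, if real ones are supplied, are consumed as-is; no routing,
  no modal split, no congestion.
* The catchment (120 min) and decay shape (0.2) are fixed conventions of
  the method, not estimated from observed patient flows; sensitivity to
  them matters in applications and only the truncation flag is exposed as a
  toggle here.
* Quality is a single outcome indicator stepped onto a six-level scale;
  nothing in the package re-estimates or risk-adjusts it.
* The econometric layer is a linear within estimator on a bounded response;
  the synthetic generator's logit link is recovered on the logit scale, and
  applications worried about the bounded support should use the
  `logit_response` option.
* Mobility is modelled at province level; individual choice behaviour,
  referral networks and waiting-list dynamics are out of scope.
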