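---
title: "Methods: movement filtering, home ranges, and habitat selection for owned outdoor cats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: movement filtering, home ranges, and habitat selection for owned outdoor cats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`catroam` implements a complete analysis chain for GPS telemetry of owned
outdoor domestic cats in urban landscapes: error filtering of raw fixes,
home-range estimation, covariate construction, gamma-GLM modelling of
home-range size with information-theoretic model selection, used/available
resource selection functions (RSFs), and the derivation of a conservation
buffer distance. Because real collar data are noisy and ground truth is
unknowable, the package ships a movement simulator with known parameters;
every stage is validated by recovering what the simulator put in.

This vignette explains the models, the defaults and their units, the
numerical choices, and the limits of what the synthetic validation shows.

## The trajectory filter

Raw fixes arrive as `(animal_id, t, x, y)` with planar coordinates in
metres (lon/lat input is projected once into a UTM zone via a built-in
Krueger-series transverse Mercator; every threshold below is metric, so a
projected plane is assumed throughout). Five passes run in a fixed order,
and fixes are only ever removed — never moved:

1. **Blocklist** — fixes inside configured exclusion circles (e.g. a
   researcher's house where units were tested) are dropped first.
2. **Speed** — the speed assigned to each fix is the speed needed to
   *arrive* there from its predecessor. While any arriving speed exceeds
   100 m/min (a trot a cat will not sustain between fixes minutes apart),
   the worst offender is removed and the bridging speed across the gap is
   recomputed. The threshold is strict (`> 100` removes; exactly 100
   stays). Removing largest-first makes the outcome deterministic; ties go
   to the earlier fix. This recompute-and-repeat strategy is greedy: on
   adversarial inputs it can remove more fixes than the smallest possible
   set (the test suite compares against a brute-force search), but it
   never leaves a violating speed behind and never beats physics by
   keeping a fix it should not.
3. **Spikes** — an interior fix is removed when both its legs run at
   >= 15 m/min and the turning angle lies in 165-180 degrees (180 = exact
   reversal): the signature of a single displaced fix, an implausible fast
   out-and-back. One left-to-right pass, metrics recomputed after each
   removal; only the apex is removed.
4. **Between-removed** — a survivor whose immediate neighbours in the
   *original* sequence were both removed is removed too; a position
   interpolated between two errors is not trustworthy.
5. **Stationary collapse** — runs of consecutive fixes within
   `stationary_tol` (default 1e-9 m, i.e. bit-identical coordinates, as
   when a collar keeps logging indoors) are collapsed to their first fix.

The filter is idempotent on the simulator's scenarios (re-running removes
nothing), and each removal carries a reason label so recall can be scored
against injected-artifact ground truth.

## Home ranges

**MCP.** The 100% minimum convex polygon is the convex hull of all fixes,
area by the shoelace formula, reported in hectares. For levels below 100
the farthest fixes from the centroid are dropped first. Degenerate inputs
(< 3 distinct non-collinear fixes) are an error, not a zero.

**Kernel isopleths.** The utilization distribution is a bivariate
Gaussian kernel density evaluated on a `kde_grid` x `kde_grid` grid
(default 200) covering the fixes' bounding box padded by three
bandwidths. The p% isopleth is the smallest set of cells holding p% of
the (discretely renormalised) mass — the classic volume-contour
construction, not contour interpolation — and its area is the cell count
times the cell area. The default bandwidth is the reference rule
`href = sigma_hat * n^(-1/6)` with `sigma_hat^2 = (var(x) + var(y))/2`,
the ad hoc default of the home-range software lineage this follows; it is
a config knob because the literature pins no principled choice, and
validation tests pin the bandwidth explicitly so the checked quantity has
a closed form. On `n` draws from an isotropic normal with sd `sigma` the
p% isopleth area converges to `pi * (sigma^2 + h^2) * qchisq(p, 2)`; with
`sigma = 10` m and `h = 1` m the 95% and 50% targets are ~1,901 and ~440
square metres, and the grid estimator lands within a few percent at
n = 10,000 (grid resolution and mass discreteness set the floor). The 50%
isopleth is nested inside the 95% by construction.

**Day/night.** The diurnal window is a closed local-clock interval,
06:00-17:59 by default (owner schedules govern when cats are out, so
local clock — not solar time or UTC — is the right axis). 17:59:59 is
day; 18:00:00 is night; the two subsets partition the input exactly.
Day/night kernel bandwidths are computed per subset, since each subset is
the sample the estimate is built from.

**Sampling sufficiency.** The accumulation curve (MCP area vs number of
chronologically accumulated fixes) is non-decreasing; the package flags a
plateau when the final 20% of the curve grows the area by under 5%,
replacing visual inspection with a reproducible rule. Both knobs are
configurable; they are a diagnostic heuristic, not a test.

**Paired and spread comparisons.** Day and night areas are compared with
a Wilcoxon signed-rank test implemented in-package: zero differences
dropped, average ranks on ties, W = sum of positive-difference ranks. For
n <= 12 the two-sided p is exact, computed by convolving the generating
function of the tied-rank distribution (equivalent to enumerating all
2^n sign assignments, which is the independent oracle the tests use);
beyond that a normal approximation with continuity and tie correction
takes over. The reference implementation in base R refuses exact p-values
under ties, which is why the exact path is implemented here. Male/female
spread is compared with the Brown-Forsythe test: a one-way ANOVA F on
absolute deviations from group medians, exactly zero for location-shifted
groups of equal spread.

## Covariates

Road density is the summed length of the analytic intersection of road
polylines with a closed disc centred on the animal's mean coordinates.
The disc radius derives from the data: the radius of the circle whose
area equals the median 95% KDE home range (66 m for a 1.3685 ha median),
making "available road" comparable across animals. Length exactly on the
boundary counts (closed disc); the choice is documented because nothing
in the field fixes it. The major-road flag is 1 when any road classed
"major" intersects the 100% MCP polygon, tangencies included
(closed-set convention).

Neuroticism is scored from a 43-item, 7-point owner questionnaire: the
raw score is the mean of the 13 items mapped to the neuroticism domain,
and the reported score is the z-standardisation of raw scores across the
study's animals (raw means are always emitted too, so either convention
is recoverable). Which 13 items map to neuroticism is survey-instrument
metadata, so the item map is a required input, never hard-coded.
Cronbach's alpha (`k/(k-1) * (1 - sum(item var)/var(total))`) reports
inter-item reliability.

## Home-range size models

Home-range area is strictly positive and right-skewed, so size is
modelled with gamma GLMs with a log link. The mean model is fitted by
IRLS; the gamma shape is then profiled by maximum likelihood (bounded 1-D
search on the log scale, which keeps the degenerate zero-deviance case
finite) so that the log-likelihood entering AICc is an actual maximised
likelihood. Coefficient standard errors use the Pearson-based dispersion
(the `summary.glm` convention): the ML shape estimate is biased upward at
n ~ 30, and plugging it into the SEs would shrink every Wald interval the
retention rule relies on.

Selection is two-staged to avoid overfitting small samples: all 2^3
subsets of the intrinsic predictors (sex, age, neuroticism) are ranked by
`AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`, where k counts intercept +
slopes + shape (so the null model has df 2 and one-predictor models 3).
A predictor is retained when it appears in a model within Delta-AICc < 2
of the best AND its 85% Wald CI (z = 1.4395), read from the best model
containing it, excludes zero; retained intrinsic predictors are forced
into every candidate of the extrinsic stage (road density, major road,
ordinal start date) — that is what carrying a predictor forward means.
Model-averaged coefficients use full (zero-substitution) averaging over
the Delta-AICc < 2 set with renormalised weights, and unconditional SEs
`sum_m w_m sqrt(se_m^2 + (b_m - b_bar)^2)`; full averaging is the
conservative default where the source procedure is ambiguous, and
conditional averaging would only grow the coefficients.

Two properties of this rule are worth knowing and are quantified in the
test suite. First, with three null predictors the null model stays within
Delta-AICc < 2 of the top in about 88-89% of samples at n = 29 — the AICc
penalty for one spurious parameter (2.5 at this n) is exceeded by the
best of three chi-square-distributed improvements about 11% of the time.
Second, the per-predictor false-retention rate of the 85% CI rule is not
15% but roughly 18-25% at n = 29: the z-quantile 1.4395 ignores the
t-correction, gamma responses at CV ~ 0.7 thicken the Wald tails, and
taking the CI from the best model containing the predictor adds a small
selection effect. Anyone applying this retention rule to ~30 animals
should expect roughly one-in-five spurious retention per tested
predictor; the package reproduces that behaviour faithfully rather than
hiding it.

## Resource selection functions

Two used/available designs per animal: a disc of 300 m around the
owner's home, and the animal's own 100% MCP. Used points are the cleaned
fixes; available points are drawn uniformly inside the boundary by
rejection sampling (iteration-capped, seeded, deterministic) at exactly
10 available per used point. Points in land-cover categories that cannot
be interpreted (undifferentiated) or were effectively unused (water) are
removed from both sets, and availables are re-drawn so the 10:1 ratio
holds after exclusion. Category attachment uses the raster cell
containing the point; polygon layers use point-in-polygon with
first-feature-wins on boundaries.

Selection is fitted per habitat: a binomial GLMM with logit link of the
used/available label on a binary in-habitat indicator with a per-animal
random intercept (Laplace ML via `lme4`). One model per habitat matches
the independent-rows structure of the coefficient table this mirrors; a
single multi-category model with an intercept over exhaustive categories
would not be identifiable. The selection coefficient is the in-habitat
log-odds contrast: positive = selection, negative = avoidance. When the
random-intercept variance hits the zero boundary the fixed-effects
logistic fit with cluster-robust (per-animal) standard errors is
available as an explicit fallback; at that boundary the two estimates
agree to numerical precision, which the tests pin. A habitat with no
used points (or no available points) inside the design is a separation
error, reported rather than silently fitted.

## The simulator and what validation does (and does not) show

The generator builds three things under one seed:

* **Landscape** — quota-constrained multi-seed region growing on a raster
  (default 5 m cells): each category claims its share of cells (66%
  impervious, 26% road, 6% greenspace, 2% agriculture — an urban
  southwestern-Ontario-like composition) and grows contiguous patches, so
  realized proportions match targets to rounding while cover stays
  clustered like real urban land cover. A street-grid road network with a
  major road, and a 43-item survey with a latent neuroticism trait,
  complete the inputs.
* **Movement** — a home-tethered step-selection walk. Each step proposes
  K = 20 candidate displacements (exponential lengths, mean `step_scale`;
  headings normal around the previous heading, sd 60 degrees) on top of a
  deterministic pull of `tether_strength` of the way home, then picks a
  candidate with probability proportional to `selection_weights` at the
  candidate's land cover. Fix intervals are uniform 2-60 min; true
  between-fix speeds are capped below 100 m/min so no true fix can
  trip the speed filter. Defaults (`step_scale` 12 m, `tether_strength`
  0.05, 20 days) give an AR(1) radial deviation of roughly 40 m and MCP
  ranges of a few hectares — the observed order of magnitude for owned
  urban cats (0.3-40 ha), which is all the movement model is tuned to
  reproduce. Tracking starts are spread over a 120-day enrolment window
  so the ordinal-date covariate varies.
* **Degradation** — isotropic Gaussian GPS error (default sd 4.8 m, the
  open-sky accuracy of the collar units this emulates), plus labelled
  artifacts at configurable rates: outliers (displaced so the implied
  arriving speed exceeds 100 m/min), spikes (an inserted apex
  constructed to satisfy both-legs->=15 m/min with a 165-180 degree
  turn; the construction guarantees >= 17.5 m/min legs and <= 14.3
  degrees of deviation from full reversal), and stationary runs (2-4
  inserted repeats of the previous coordinate at intermediate times).
  Validation rates are 1% outliers, 1% spikes, 2% stationary starts per
  fix — enough artifacts to measure recall tightly without distorting the
  trajectories.

One confound deserves emphasis because it shapes two validation choices.
For a home-tethered walk, *usage is centre-weighted*: the distribution of
where the animal is does not match uniform availability over its home
range even when movement is completely habitat-blind. Comparing
used-location cover against uniform-MCP availability therefore shows
spurious "selection" for whatever surrounds the home — a well-known
availability-definition problem for RSFs, compounded by fix
autocorrelation inflating chi-square statistics. The package's
selection-neutrality check is therefore made at the choice level, where
the null is exact: under uniform weights the chosen candidate is a
uniform draw from each step's recorded candidate pool
(`simulate_trajectory(record_candidates = TRUE)`), and chosen-category
counts match pool-expected counts as chi-square across steps. Similarly,
rank-order recovery of selection-weight contrasts through the full
trajectory-to-RSF route is tested on weak-tether scenarios over
fine-grained landscapes (patches smaller than a step), where usage mixes
over the range and the confound is negligible; with the default tether
over coarse patches the RSF instead measures the confounded contrast and
recovers the injected ordering in only ~80-85% of runs. Passing tests
therefore certify the estimators and the pipeline plumbing — not that an
RSF on a strongly tethered animal measures the animal's movement
preferences, which is a scientific caveat, not a software one.

CI-coverage of the selection coefficient (~95% nominal over 200 refits)
is checked where the GLMM is well-specified: point labels drawn directly
from the logistic model with a random intercept, the setting the
asymptotics actually describe.

What the synthetic data do *not* emulate: behavioural states (hunting,
resting), temporally varying fix success, habitat-dependent GPS error,
multi-animal interactions, and any true dependence of movement scale on
covariates like road density or personality — so pipeline stages that
model home-range size against covariates are validated with
model-level simulations (gamma responses with known coefficients), not
with the walk.

## Buffer distance

The management quantity: the diameter of the circle whose area equals a
home range, `d = 2 sqrt(A * 1e4 / pi)` for A in hectares, inflated by a
20% safety margin and rounded to the nearest 10 m (the raw value is
returned alongside; rounding is for reporting). For the largest observed
100% MCP of 38.45 ha this gives 700 m and an 840 m buffer. With a zero
margin the buffer equals the diameter exactly.

## Numerical and I/O choices

* Geometry is planar throughout, in a single UTM zone (WGS84). The
  forward projection is the Krueger series in the third flattening
  (sub-millimetre in-zone); the inverse is 2-D Newton on the forward map,
  so round trips are solver-exact. Tests cross-check against an
  independently coded Snyder-series formulation to 1 cm.
* Raster land cover is read/written as ESRI ASCII grid plus a
  code-to-category mapping table (unmapped codes are an error that lists
  them); polygon land cover and road networks travel as GeoJSON; home
  ranges are written as GeoJSON MultiPolygons with full-precision
  coordinates so round trips are vertex-identical.
* Result tables are CSV with a JSON sidecar carrying the configuration
  hash and RNG seed.
* Problem sizes in the shipped analysis and validation runs (12 cats for
  the workflow; 100 filter scenarios; 200 coverage refits; 30 ordering
  runs; 10,000-draw KDE checks) are chosen to exercise every code path
  at statistically meaningful sample sizes while keeping a full run in
  minutes on one core.

## Known limitations

* The speed filter's greedy removal can exceed the minimal removal set on
  adversarial geometries (never on the artifact classes it targets).
* Grid KDE areas inherit grid-resolution error (~1-3% at 200 cells per
  axis); increase `kde_grid` for small, tight ranges.
* The retention rule's false-positive rate at n ~ 30 is ~18-25% per
  predictor, as quantified above; it is reproduced, not corrected.
* Only UTM CRSs are built in; other projections require pre-projected
  input.
* The walk reflects at the landscape boundary; simulate on an extent
  comfortably larger than the home ranges of interest.
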