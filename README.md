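# catroam

Home range, habitat selection and buffer-zone analysis for GPS-tracked
owned outdoor cats.

Owned cats with unsupervised outdoor access are both companion animals
and urban predators. Deciding whether curfews or buffer zones around
conservation areas can limit their impact requires knowing how far cats
roam, what drives the size of their home range, and which land covers
they use. `catroam` implements that analysis chain for collar GPS data —
and, because ground truth is unknowable for real collars, a movement
simulator with known parameters so every stage can be validated by
parameter recovery. It is aimed at movement ecologists and municipal
analysts working with owned-cat telemetry in urban landscapes.

## What it computes

* **Trajectory cleaning** — blocklist removal; iterative speed filtering
  (arriving speed > 100 m/min removed, largest first, bridges
  recomputed); spike removal (both legs ≥ 15 m/min with a 165–180°
  turn); removal of fixes stranded between removed neighbours;
  stationary-run collapse.
* **Home ranges** — 100% minimum convex polygons (MCP, shoelace area in
  ha) and kernel-density isopleths: the p% isopleth is the smallest grid
  cell set holding p% of the utilization mass, with reference bandwidth
  h<sub>ref</sub> = σ̂·n<sup>−1/6</sup>; day (06:00–17:59) vs night
  split; an accumulation-curve plateau diagnostic; Wilcoxon signed-rank
  (exact for n ≤ 12, ties handled) and Brown–Forsythe comparisons.
* **Home-range size models** — gamma GLMs with log link,
  E[A] = exp(Xβ); two-stage all-subsets selection by
  AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1) over intrinsic (sex, age,
  neuroticism) then extrinsic (road density, major road, ordinal date)
  predictors; retention by ΔAICc < 2 plus an 85% Wald CI excluding zero;
  full (zero-substitution) model averaging with unconditional SEs.
* **Resource selection functions** — used/available designs (10
  available per used point) inside a 300 m owner-home disc and inside
  each cat's MCP; per-habitat binomial GLMMs,
  logit P(used) = α + b<sub>animal</sub> + β·in-habitat, fitted by
  Laplace ML; β > 0 is selection, β < 0 avoidance.
* **Buffer distance** — d = 2√(A·10⁴/π) for the largest 100% MCP plus a
  20% safety margin, rounded to 10 m (38.45 ha → 700 m → 840 m).
* **Synthetic data** — clustered land cover by quota-constrained region
  growing (66/26/6/2% impervious/road/greenspace/agriculture), a street
  grid with a major road, a 43-item personality survey with a latent
  neuroticism trait, home-tethered habitat-weighted random walks with
  2–60 min fixes and 4.8 m GPS noise, and labelled artifact injection.

## Worked example

The `analysis/` scripts run the whole chain on a simulated colony of 12
cats tracked for 20 days on a 1 km² urban landscape (true selection
weights: impervious 3, road 1.5, greenspace/agriculture 0.8):

```sh
Rscript analysis/01_simulate.R   # landscape, roads, survey, 12 trajectories
Rscript analysis/02_filter.R     # four-pass cleaning, scored against labels
Rscript analysis/03_homerange.R  # MCP + KDE areas, day/night, tests
Rscript analysis/04_covariates.R # neuroticism, road density, major road
Rscript analysis/05_glm.R        # two-stage AICc selection + averaging
Rscript analysis/06_rsf.R        # used/available selection at two scales
Rscript analysis/07_buffer.R     # management buffer distance
```

Outputs land in `results/`. The printed highlights of one run:

```
retained 10902 of 11882 fixes
artifact recall: 99.1% of 233 injected outliers/spikes removed
false removal: 0.78% of clean fixes

MCP 100%: median 3.82 ha, range 3.26-6.95 ha (n = 12)
day vs night MCP: W = 31, p = 0.569 (exact, n = 12 pairs)
male vs female MCP spread: F = 0.363, p = 0.560

neuroticism inter-item reliability: Cronbach's alpha = 0.89

== scale: mcp ==
     habitat n_used n_avail   beta  lower  upper     p
 agriculture  10902  109020 -1.317 -1.555 -1.079 0.000
  greenspace  10902  109020 -0.977 -1.310 -0.643 0.000
  impervious  10902  109020  1.050  0.886  1.214 0.000
        road  10902  109020 -0.427 -0.729 -0.125 0.006

largest 100% MCP: 6.95 ha (cat10)
buffer with 20% margin: 360 m
```

Reading this: the filter removed virtually every injected GPS artifact
while touching under 1% of genuine fixes; the 12 simulated cats hold
home ranges of a few hectares with no day/night or sex difference (none
was simulated); the survey's 13 neuroticism items are internally
consistent; the RSF recovers the simulated preference — selection for
impervious cover, avoidance of everything else, with the weakest
avoidance for roads — and the widest-ranging cat implies a 360 m buffer
around a sensitive area. Because the simulator ties no covariate to
movement scale, the home-range GLMs (stage 5) demonstrate the selection
machinery under the null; retention of an occasional intrinsic predictor
at n = 12 illustrates the ~1-in-5 per-predictor false-retention rate of
the ΔAICc + 85% CI rule quantified in the methods vignette.

## Layout

* `R/` — the package: configuration, projection/geometry, I/O
  (CSV/GPX/GeoJSON/ASCII-grid), filtering, home ranges, covariates,
  gamma-GLM model selection, RSFs, simulator.
* `analysis/` — the numbered workflow drivers above.
* `tests/testthat/` — unit, property and end-to-end validation tests,
  with brute-force/enumeration/closed-form oracles.
* `vignettes/methods.Rmd` — models, assumptions, defaults, numerical
  choices and limitations.
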