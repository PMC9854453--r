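---
title: "Methods: ensemble SDMs and dispersal-constrained projections for riverine species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble SDMs and dispersal-constrained projections for riverine species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Semi-aquatic mammals — a poor-dispersing, basin-bound prey such as a desman
and a wide-ranging predator such as an otter are the motivating pair — live
on a one-dimensional habitat embedded in a two-dimensional landscape: the
river network and a narrow strip around it. Forecasting how climate and
land-use change reshapes their ranges, and how much the prey's range ends
up inside the predator's, requires a chain of methods that are standard
individually but error-prone in combination: presence-only ensemble
distribution modelling, spatially blocked validation, threshold
binarization, and a dispersal-constrained projection to a future horizon.

`riversdm` implements that chain as a reusable, tested pipeline. Because
field occurrence data and downscaled climate scenarios are rarely
redistributable, the package ships a seeded synthetic-landscape generator
with a known generating model, so every stage — and the pipeline end to
end — is testable against ground truth with no downloads.

## The suitability model

Occurrences are presence-only records `(id, x, y, year, uncertainty_m)` in
projected metres. The analysis region is the buffer of radius 1 km around
the river network (all predictor layers are clipped to it), background
points (default 10,000) are placed uniformly over it, and habitat
suitability is modelled by five learners:

* **GLM** — logistic regression with linear + quadratic terms;
* **GAM** — one modest thin-plate smooth per predictor (`mgcv`, REML);
* **GBM** — logistic gradient boosting on depth-2 trees, shrinkage 0.1,
  bag fraction 0.7, early stopping on a 20% held-out fraction
  (patience 25);
* **RF** — a class-balanced probability forest (100 trees, `mtry =
  floor(sqrt(p))`);
* **MAXENT** — an L1-penalized presence/background logistic model on an
  expanded feature space, the `maxnet`-equivalent formulation of Maxent.

No single published settings table exists for GLM/GAM/GBM/RF in this
context, so each learner's configuration here is a named, overridable
default chosen to be conventional for ecological data at desk scale. GBM and RF are built on a
small in-package Rcpp regression-tree backend because no tree-model
package is part of the supported dependency set.

### Maxent feature expansion and AICc tuning

The Maxent-style learner expands each predictor into feature classes `L`
(linear), `Q` (squares), `H` (forward and reverse hinges at
`knots_per_var = 10` evenly spaced interior knots over the *training*
range), `P` (pairwise products) and `T` (step indicators at the hinge
knots), giving the six class strings `L, LQ, H, LQH, LQHP, LQHPT`. The
penalty on a raw column equals `reg_mult` times a base penalty times the
column's training standard deviation (implemented by standardizing and
using a uniform lasso penalty). The base penalty is data-driven:
`lambda_max / 20`, where `lambda_max` is the smallest penalty that zeroes
every coefficient. A fixed constant base is wrong in a way that is easy to
miss: at low prevalence `lambda_max` itself is small, and a constant base
larger than it silently reduces *every* configuration to the null model.

Tuning fits all 8 regularization multipliers (0.5–4 in steps of 0.5)
crossed with the 6 class strings — 48 configurations — on the full
training data and selects the lowest
`AICc = -2·loglik + 2k + 2k(k+1)/(n-k-1)`, with `k` the count of non-zero
coefficients (the standard convention in ecological niche modelling) and
ties resolved towards fewer features, then the lower multiplier.
Configurations with `n <= k + 1` have no defined AICc and are excluded.

### Spatial cross-validation and the ensemble

Folds come from two nested checkerboards ("checkerboard2"): a point's fold
is `2·parity(coarse block) + parity(fine block)`, four labels in total,
with block edges measured in raster cells (defaults 8 and 2; published
checkerboard analyses rarely print their aggregation factors, so they
are exposed as configuration). Blocks use half-open intervals, so boundary points belong
to the upper/right block. Each learner is trained on three folds and
scored on the fourth by AUC (Mann–Whitney, ties one half) and maximum TSS
(scan over midpoints of sorted unique scores, plus the two just-outside
endpoints so the no-skill maps are reachable; ties take the lowest
threshold).

Models whose *cross-validated mean* AUC reaches 0.70 enter the ensemble
(the gate is conventionally stated per model without specifying the
aggregation; the mean over folds is the common ensemble-platform choice).
Ensemble suitability is the weighted average of member predictions with
raw mean-AUC weights — rescaled or decayed weight variants exist
elsewhere, raw AUC is used here and flagged. Verbal skill classes follow
the usual AUC bands (excellent > 0.90, good > 0.80, fair > 0.70,
poor < 0.60); the band `[0.60, 0.70]` has no conventional name and is
reported as `"unclassified (gap)"` rather than silently merged into a
neighbour.

## Binarization and range dynamics

Four threshold rules are implemented: equalize sensitivity and
specificity, maximize TSS, mean occurrence probability (the arithmetic
mean of presence scores), and minimize ROC-plot distance
`sqrt((1-sens)^2 + (1-spec)^2)`. Scanned rules share one candidate set —
midpoints of the sorted unique pooled scores plus the two just-outside
endpoints — and ties take the lowest threshold. Binarization is
threshold-inclusive (`suitability >= t`), so ties at the threshold are
deterministic.

Range metrics, on aligned 0/1/nodata maps:

* net change `= 100·(gain − loss)/current`. The current-range denominator
  is a deliberate choice: the phrase "with respect to the stable portion"
  admits a stable-cell denominator, but that statistic explodes as
  stability vanishes, while the current-range version is bounded below by
  −100 and matches the common range-change convention. Flagged as a
  divergence risk.
* shift `= 100·(1 − stable/future)`, the fraction of the future range in
  new territory; the mirror (fraction of the current range abandoned) is
  attached as `shift_of_current`.
* overlap(A, B) `= 100·|A∩B|/|A|`, e.g. the share of the prey's range
  exposed to the predator.

Factorial runs (scenario × GCM × threshold) are summarized per scenario by
median and SD over the 12-cell GCM × threshold factorial; single-run
groups report SD = 0.

## The dispersal automaton

Projection to the horizon uses a MigClim-style cellular automaton, one
step per year. Per step: occupied cells unsuitable this step are
decolonized (age reset); cells aged at least `maturity_steps` act as
sources; every unoccupied suitable cell whose centre lies within the
dispersal distance (2 km prey, 20 km predator are the reference values)
of a source centre, and which is admissible under the barrier policy,
is colonized at age 1; survivors age by one. Initial cells start at age
`maturity_steps` so the current range can seed colonization immediately.
Colonization is deterministic (probability 1 inside the radius): the
biology enters as a single dispersal distance per species, with no decay
kernel; a per-attempt probability is available as an opt-in stochastic
mode, which is the only use of the configuration seed. `maturity_steps`
defaults to 1 and is flagged as unverified — no published maturity value
accompanies the dispersal distances. Barriers default to the prey only
(basin and dam effects on movement are documented for the desman, not
the otter): `basins_and_dams` lets
colonization cross a basin boundary only along a dam-free river path
(8-connected components of river cells minus dam cells); `cells_block`
instead blocks any straight source–target segment crossing a barrier
cell. When a single future layer is supplied it is held constant over all
steps, matching the single-horizon projection design.

## The synthetic world — what it emulates, and what a green test means

`make_landscape()` draws smoothed Gaussian noise fields (white noise
convolved with a Gaussian kernel; correlation length in cells) rescaled to
plausible bioclimate/elevation ranges; a 6-class land-use layer by
equal-quantile binning (guaranteeing all classes are present, so the six
distance transforms always exist); a meandering 4-connected river crossing
the grid west to east; a two-basin partition along a wiggling ridge; and
dam cells on the river. Truth is
`suitability = plogis(intercept + Σ beta_j · z_j)` on buffer-standardized
predictors, nodata outside the buffer.

Defaults are a stated world, chosen once:

* grid 32 × 32 cells of 1000 m; correlation length 2 cells. Fields must be
  smooth enough to be "climate-like" yet rough enough that the ~130-cell
  river buffer spans several independent patches; at correlation length 4
  a 32-cell grid holds only ~8 patches and model skill is dominated by
  seed luck.
* `truth_beta = (intercept −3, bio3 +2, bio4 −2, bio19 +2)`: a
  range-restricted specialist (roughly a sixth of the buffer highly
  suitable) favouring stable day–night temperatures and winter
  precipitation. The negative intercept matters: with intercept 0 half the
  buffer is suitable and the *Bayes-optimal* presence/background AUC is
  about 0.69 — no model can look skilful in a world where the species is
  everywhere.
* occurrence sampling draws cells **with replacement**, proportionally to
  truth suitability, then jitters within the cell: repeat records of the
  same reach are the norm in field data, and a without-replacement scheme
  cannot produce 300 records from a ~130-cell buffer at all. Positional
  uncertainty is truncated-exponential (mean 120 m, cap 600 m), so roughly
  an eighth of records exceed the 250 m accuracy rule and the filter is
  always exercised. Sampling intensity is a free parameter (true
  prevalence and detectability are not published for either species).
* future scenarios perturb each predictor by
  `sd_j · magnitude · (0.6·direction_j + 0.4·gradient)` with magnitude
  0.4 (RCP2.6) or 1.2 (RCP8.5) predictor SDs, GCM-dependent directions and
  gradient orientation, plus land-use reassignment on 5% (B1) or 15% (A2)
  of cells — deterministic given (scenario, GCM, landscape seed).

What the generator does **not** emulate: real bioclimate covariance
structure (the 19 CHELSA-style variables and their strong mutual
correlations), dendritic river networks with tributaries, survey-transect
clustering of records, spatial sampling bias, and genuine GCM anomaly
fields. A green test therefore establishes that the *machinery* is
correct — contracts, formulas, determinism, and recovery of a known truth
under honest spatial validation — not that any ecological conclusion
about real species transfers.

The demo pipeline configuration (`default_run_config()`) uses 600 records
per species and 300 m thinning. At a 1 km cell size, sub-cell thinning is
deduplication of co-located records, which is the dominant artefact the
generator produces; the field-scale thinning distances (2 km / 20 km,
equal to the dispersal distances) remain the documented species-level
reference values and are validated as a configuration. Desk-scale spatial
folds simply cannot support 20 km thinning on a 32 km grid.

## Numerical and degenerate-input choices

* Distances are exact cell-centre Euclidean (no chamfer approximation), so
  an all-pairs oracle can check them exactly; coordinates are planar
  metres (no geodesy — swap in great-circle distances before using
  lon/lat data).
* Thinning is the randomized closest-conflicting-pair removal heuristic
  with multi-start (default 100 restarts, seeded); implemented as a
  single sweep over the distance-sorted conflict list, which is
  equivalent because removals never create new conflicts.
* VIF selection: `1/(1−R²)` by OLS of each layer on the other retained
  layers; constant layers count as infinite VIF and drop first with a
  warning; ties drop the first-listed layer; survivors return in input
  order. Computed on the combined presence + background table.
* AUC uses average ranks (ties one half); one-class inputs are rejected
  rather than defaulted.
* Horn's 3 × 3 stencil computes slope with edge replication (edge cells
  are one-sided approximations); roughness is the 3 × 3 max − min, one of
  several circulating definitions and noted as such.
* Grids are written as ESRI ASCII text (`.asc`) and sidecars as JSON: the
  supported dependency set includes no GeoTIFF or YAML reader, and both
  substitutes are standard open interchange formats.

## Known limitations

* The automaton's admissibility check is pairwise source–target; it does
  not model stepping-stone paths *around* a barrier within a single step.
* The river-path exception for basins requires both cells to lie on the
  river itself; near-river cells in different basins are blocked even if
  a river path passes nearby.
* Learner configurations are desk-scale conventions, not a reproduction
  of any published settings table.
* Monte-Carlo module examples are run at reduced seed counts in the unit
  suite for runtime; the full 50-seed versions run in the acceptance
  suite.
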