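# riversdm

Ensemble species distribution models and dispersal-constrained range
projections for riverine species.

`riversdm` is for ecologists and methodologists who need to forecast how
climate and land-use change reshapes the range of river-bound species —
and how much a prey's range ends up inside a predator's — with every step
of the chain reproducible and testable. It implements, as a single
pipeline:

* occurrence preparation: positional-uncertainty filtering (< 250 m by
  default), spThin-style spatial thinning at a species-specific minimum
  distance, uniform background sampling (default 10,000 points), and
  four-fold **checkerboard2** spatial block cross-validation;
* predictor engineering: Euclidean distance-to-land-use-class transforms,
  slope/roughness from elevation (Horn's stencil), clipping to a 1 km
  river buffer, and iterative VIF > 5 collinearity pruning;
* a five-algorithm ensemble — GLM, GAM, boosted trees, random forest and
  a Maxent-style L1-penalized logistic learner tuned by AICc over the
  48-configuration grid (8 regularization multipliers × 6 feature
  classes) — evaluated by AUC and TSS per spatial fold, gated at mean
  AUC ≥ 0.70, and combined by AUC-weighted averaging;
* binarization under four threshold rules (max TSS, sens = spec, mean
  occurrence probability, min ROC distance);
* a MigClim-style cellular automaton projecting the binary range to a
  future horizon under per-step dispersal distance, reproductive
  maturity, and basin/dam barriers;
* range metrics: net change, geographical shift, and interspecific
  overlap, summarized as median ± SD over the scenario × GCM × threshold
  factorial.

A seeded synthetic-landscape generator with a known logistic truth
(`make_landscape()`, `simulate_truth()`, `sample_occurrences()`,
`make_future()`) stands in for non-distributable field and climate data,
so the whole pipeline runs — and is tested — without downloads.

## The model in brief

Suitability is `P(presence | x) = logistic(η(x))` estimated five ways from
presence/background data; the ensemble is
`p̂(x) = Σ wᵢ p̂ᵢ(x) / Σ wᵢ` with `wᵢ` the member's cross-validated mean
AUC (members below 0.70 are excluded). AUC is the Mann–Whitney
probability that a presence outranks a background point;
`TSS = sensitivity + specificity − 1`;
`AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1)` with `k` the non-zero coefficient
count of the penalized fit. Binary maps use `p̂ ≥ t` under each threshold
rule. The automaton, one step per year: decolonize unsuitable cells,
colonize every suitable cell within the dispersal radius of a mature
source (subject to barriers), age the survivors. Metrics on 0/1 maps:
`net change = 100(gain − loss)/current`, `shift = 100(1 − stable/future)`,
`overlap(A,B) = 100|A∩B|/|A|`.

## Worked example

A complete single-species pass on a synthetic landscape (32 × 32 km at
1 km cells, seed 7):

```r
library(riversdm)

b     <- make_landscape(seed = 7)
truth <- simulate_truth(b)
occ   <- sample_occurrences(truth, n = 300, seed = 1)
occ   <- filter_uncertainty(occ, 250)
occ   <- thin_occurrences(occ, min_dist_m = 300, reps = 20, seed = 2)
nrow(occ)
#> [1] 146

stack <- build_predictor_stack(b, buffer_m = 1000)
bg    <- sample_background(stack$mask, n = 2000, seed = 3)
feats <- extract_features(stack, occ, bg)
keep  <- vif_select(feats, threshold = 5)
feats <- feats[, c("id", "label", keep)]
folds <- checkerboard2(rbind(occ[names(bg)], bg), stack$mask, 8, 2)

tuned  <- tune_maxent(feats)          # 48-row AICc table
tuned$best
#> $feature_classes  "LQHP"
#> $reg_mult         1.5

models <- fit_all(feats, folds, maxent_config = tuned$best, seed = 4)
ens    <- build_ensemble(models, min_auc = 0.70)
ens
#> <rs_ensemble> 5 member(s): GLM (w=0.791), GAM (w=0.826), GBM (w=0.812),
#>               RF (w=0.810), MAXENT (w=0.824)
```

Member weights are cross-validated mean AUCs — here all five learners
clear the 0.70 gate with "fair-to-good" discrimination. The ensemble
surface recovers the generating truth closely:

```r
suit <- predict_suitability(ens, subset_stack(stack, keep))
cor(suit$values, truth$values, use = "complete.obs")
#> [1] 0.942
```

Project to 2050 under the extreme scenario (RCP8.5 climate, A2 land use,
CCSM4), binarize at the max-TSS threshold, and let the automaton disperse
the range 2 km per year for 30 years, respecting basins and dams:

```r
p   <- predict_ensemble(ens, riversdm:::feature_matrix(feats))
thr <- find_threshold(p[feats$label == 1], p[feats$label == 0], "MAX_TSS")
current <- binarize(suit, thr, "MAX_TSS")

fb     <- make_future(b, climate = "RCP8.5", landuse = "A2", gcm = "CCSM4")
fsuit  <- predict_suitability(ens, subset_stack(build_predictor_stack(fb), keep))
future <- binarize(fsuit, thr, "MAX_TSS")

sim <- disperse(current, future,
                dispersal_config(2000, maturity_steps = 1, n_steps = 30,
                                 barrier_mode = "basins_and_dams"),
                basin_id = b$basin_id, dam_mask = b$dam_mask,
                river_mask = b$river_mask)
nc <- net_change(current, sim$final)
c(nc$net_change_pct, as.numeric(range_shift(current, sim$final)))
#> [1] 18.8 19.3
```

So under this (synthetic) extreme scenario the species gains 18.8% of its
current 48-cell range and 19.3% of its future range is new territory.

The two-species, 4-scenario × 3-GCM × 4-threshold factorial — including
interspecific overlap and the median ± SD summary — runs from one
configuration:

```r
manifest <- run_all(default_run_config(seed = 42), out_dir = "demo_out")
```

or from the command line via `inst/exec/riversdm`
(`riversdm all --seed 42 --out demo_out`). Outputs are ESRI ASCII rasters,
CSV tables (`metrics.csv`, `summary.csv`, per-species evaluation and
Maxent tuning tables) and a JSON run manifest.

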