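# synergykit

Muscle synergy analysis for rollator-assisted sit-to-stand and stand-to-sit
movements.

Standing up and sitting down are balance-critical transitions, and rollator
handle support reorganizes how the nervous system coordinates them. This
package is for movement scientists who want to quantify that coordination
from multi-channel surface EMG: it factorizes 30-channel envelope matrices
into muscle synergies, compares the temporal and spatial synergy models,
matches synergy activation profiles across movement strategies, measures
activation timing, and tests how support conditions (unassisted, light
touch, full support) shift the muscle weightings. A synthetic-data generator
with known ground truth makes the whole chain testable without any
recordings.

## The models

For the trials of one movement × floor × strategy group, each trial's
envelope matrix `M^s` (101 time samples × 30 muscles, nonnegative) is
decomposed by non-negative matrix factorization in one of two arrangements:

* **Temporal synergies** — trial-independent activation profiles
  `C_n ∈ R^101` with trial-dependent muscle weightings `w^s_n ∈ R^30`:
  `M^s ≈ Σ_n C_n w^s_n` (input matrix `101 × 30·tr`).
* **Spatial synergies** — trial-independent weighting vectors with
  trial-dependent profiles (input matrix `30 × 101·tr`).

The number of synergies is selected on a fivefold cross-validated `R² =
1 − SSE/SST` curve, either at the knee (first left endpoint where a linear
fit to the remaining curve has MSE < 1e-4) or as the smallest `n` with
`R² ≥ 0.9` and increment `< 0.05`. Model compactness is compared by
parameter counts (temporal: `101·n` trial-independent + `30·n` per trial;
spatial: `30·n` + `101·n`). Profiles are matched across movement strategies
by constrained k-means++ (centroid correlation ≥ 0.9, at most one profile
per strategy per cluster), timing is quantified as full width at half
maximum of the main peak (one-sided for boundary synergies), and support
effects on the weightings are tested with stacked-response linear mixed
models (participant random intercept, ML, reference-coded support,
effect-coded muscles, Bonferroni correction).

## Worked example

```r
library(synergykit)

# Ground truth: one sit-to-stand strategy with 3 planted synergies
gt <- make_ground_truth(list(tasks = list(list(
  movement = "sit_to_stand", floor = "non_challenging",
  strategies = list(vertical_rise = 3)))))

# Ten envelope-level trials, then extract temporal synergies at n = 3
trials <- lapply(1:10, function(i)
  generate_envelope_trial(gt, "vertical_rise", "UA", seed = i)$envelope)
ds <- build_strategy_dataset(trials, "vertical_rise")
model <- nmf_extract(ds, 3, kind = "temporal", restarts = 5,
                     max_iter = 1000, seed = 1)
round(model$r2_train, 4)
#> [1] 0.9938

# Cross-validated model-order selection
curve <- cross_validated_curve(ds, "temporal", n_range = 1:5, folds = 5,
                               restarts = 3, max_iter = 500, seed = 2)
round(curve$r2_mean, 4)
#>      1      2      3      4      5
#> 0.6161 0.8946 0.9932 0.9933 0.9934
select_n_knee(curve)$n_knee
#> [1] 3

# Timing: FWHM of the extracted profiles (% of movement duration)
fwhm_table(t(model$trial_independent))
#>       label peak_index     width boundary
#> 1 synergy_1         50  9.301336     none
#> 2 synergy_2         95 16.687851      end
#> 3 synergy_3          5 16.639664    start

# Compactness of a temporal (7) vs spatial (15) representation
compactness_summary(7, 15)[, c("sum_temporal", "sum_spatial")]
#>   sum_temporal sum_spatial
#> 1          917        1965
```

The held-out `R²` curve saturates at the planted order, the knee criterion
recovers `n = 3`, and the mid-movement synergy is markedly narrower (9.3%
of the movement) than the boundary synergies (~16.7%, measured one-sidedly)
— the timing pattern the defaults are built to emulate. The compactness
table shows why the temporal model is preferred at the study's selected
orders: 917 stored values versus 1965.

`run_full_pipeline()` chains every stage (simulate → preprocess → extract →
select → match → fwhm → stats) deterministically from one seed;
`inst/cli/synergykit.R` wraps the same functions as a small command-line
tool.

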