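# fadel

Feature-type-aware discretization ensemble learning for extremely
imbalanced binary classification on heterogeneous tabular data.

## The problem

In rare-outcome clinical prediction (1–4% positive prevalence), standard
classifiers collapse onto the majority class, and the feature panel is
heterogeneous: laboratory markers are heavily right-skewed
(Fisher–Pearson skewness ≫ 1), hematology counts are near-normal, and some
columns are binary flags. A single global preprocessing choice helps some
learners and hurts others.

`fadel` keeps the raw data untouched (no oversampling, no synthetic
minority samples) and instead makes the *feature representation* part of
the architecture:

1. **Supervised discretization.** Each flagged continuous feature gets a
   per-feature CART classifier (Gini criterion, max depth `D = 3`, leaf
   budget `L = 8`, best-first growth). Its internal-node split values,
   sorted, become thresholds `θ(1) < … < θ(K−1)` defining `K ≤ min(2^D, L)`
   right-closed intervals `(θ(k−1), θ(k)]` with virtual ±∞ boundaries; the
   interval index `C(x) = k ⇔ θ(k−1) < x ≤ θ(k)` is the discretized value.
2. **Type-aware routing.** Four base learners, each on its preferred view:
   two gradient-boosted tree learners (depthwise and leaf-wise growth) on
   the raw continuous view; an ordered-target-encoded booster
   (`TE = (Σ_prev y + a·p)/(n_prev + a)`, smoothing `a = 1`, prior `p` =
   prevalence) and a 50-stump AdaBoost
   (`α_t = ½ log((1−ε_t)/ε_t)`, `w ← w·exp(−α y h)`) on the interval view.
   Every learner obeys one contract: `probability = σ(raw_score)`.
3. **Forest fusion.** The 4-vector of base probabilities feeds a 100-tree
   random-forest meta-model. The label is the majority vote of per-tree
   argmax leaf classes (ties → negative); the continuous score is the mean
   leaf positive-class frequency, suitable for ROC/PR curves. Evaluation
   centers on sensitivity, specificity and their geometric mean
   `G-mean = √(sensitivity × specificity)`.

A seeded generator of imbalanced, skewed, clinical-like tabular data makes
every stage testable without any external dataset.

## Worked example

```r
library(fadel)

ds <- generate(scenario_config("clinical_like", n = 5000,
                               prevalence = 0.02, seed = 1))
ds
#> <tabular_dataset> 5000 rows, 9 features (8 flagged for discretization)
#>   negatives: 4900, positives: 100, prevalence: 0.02

sp <- stratified_split(ds, train_fraction = 0.8, seed = 1)
model <- fit_fadel(sp$train, fadel_config(seed = 1))
model
#> <fadel_model> 8 discretized features (K: 7/8/7/7/8/7/6/7), 4 base slots,
#>   100-tree meta-forest, meta_mode=out_of_fold

pred <- predict(model, sp$test)
metrics_report(sp$test$y, pred$score, threshold = 0.5)
#> <metrics_report> threshold 0.5
#>   sensitivity 0.7500  specificity 0.9980  G-mean 0.8651
#>   precision 0.8824  F1 0.8108  AUROC 0.9742  AUPRC 0.9198
```

Read: on a held-out 20% split of a 5,000-row dataset with 100 positives,
the ensemble ranks positives almost perfectly (AUROC 0.97) and the
majority-vote label recovers 15 of the 20 held-out positives while
misclassifying 2 of 980 negatives. Across seeds the vote's recall averages
about 0.9 (single seeds range roughly 0.75–1.00 — each held-out positive
is worth 5 points of recall at this size).

Discretization is also a skewness treatment — interval indices of the
lab-like features are far less skewed than the raw values:

```r
head(skewness_report(sp$train, model$discretizers), 3)
#>    feature k skew_raw skew_discretized high_skew_raw flagged
#> 1 crp_like 7 23.81886         5.192147          TRUE   FALSE
#> 2 alt_like 8 24.72838         1.585998          TRUE   FALSE
#> 3 ast_like 7 35.34201         1.593394          TRUE   FALSE
```

## Command line

A thin dispatcher over the same functions ships at `inst/cli/fadel.R`:

```sh
Rscript inst/cli/fadel.R simulate --config scenario.json --out train.csv
Rscript inst/cli/fadel.R fit      --data train.csv --config run.json --out model/
Rscript inst/cli/fadel.R predict  --model model/ --data new.csv --out pred.csv
Rscript inst/cli/fadel.R evaluate --predictions pred.csv --truth new.csv --out eval
```

Model archives are directories of JSON documents (manifest, per-feature
thresholds, per-slot learner state, forest node tables) written with
17-significant-digit floats: reruns with identical seeds are
byte-identical, and `load_fadel()` restores a model exactly.

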