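# eciml

Descriptor ablation analysis for enzyme–chemical activity prediction.

## What problem this solves, and for whom

Enzyme families are screened against chemical libraries to chart substrate
promiscuity, and machine-learning models are then trained on the resulting
activity matrix to propose new enzyme–chemical pairs. Whether such a model
is *actually using* the enzyme descriptors, the chemical descriptors, or
just the activity matrix itself depends on the deployment scenario — and
getting that wrong means trusting a model exactly where it cannot
generalize. `eciml` is for computational biologists and enzyme engineers
who want to measure, not assume, each descriptor's contribution before
committing to a screening campaign.

## The core design

A Random Forest is trained on concatenated enzyme + chemical descriptor
vectors in four ablation variants that differ only in which descriptor
block has been destroyed by **permutation** (descriptor rows reassigned to
objects by a random bijection, so nothing transferable survives):
`rf_all`, `rf_protein` (chemical block permuted), `rf_chemical` (enzyme
block permuted), `rf_none` (both permuted). Two non-ML baselines anchor
the scale:

* **random model** — Bernoulli(r) labels, where r is the training activity
  ratio;
* **activity model** — for any new enzyme, predicts the top-k chemicals by
  total training activity, k = round(n_chemicals · r).

Evaluation uses three splitting schemes — **LOOT** (random pairs held
out), **LPOT** (whole enzymes held out), **LCOT** (whole chemicals held
out) — with the associated imbalance filter (keep objects with activity
counts in [10%, 90%] of the opposite axis and > 1), 10 folds × 5 seeds,
AUPR/AUROC for classification, R²/MAE for regression, and pooled-variance
t-tests with significance stars between variants.

Datasets are characterized by seven statistics: object counts, activity
ratio, mean top-5 Smith–Waterman similarity (BLOSUM62, gaps 11/1,
self-score-normalized), mean top-5 Tanimoto similarity of 2048-bit Morgan
fingerprints, and the activity-order indices

* **AOIE** — mean over chemicals of the pairwise-concordance fraction
  between the enzyme ordering induced by that chemical and the global
  enzyme ordering (row sums over the other chemicals); ties count 0.5.
  0.5 in expectation for random data, 1 for a chemically unspecific
  family;
* **AOIC** — the mirror statistic on the chemical axis.

A synthetic generator produces complete datasets (sequence families with
tunable within-family similarity, chemical classes, block-structured
activity with an exact target activity ratio, tunable enzyme/chemical/
noise effects) plus ground truth, so the whole pipeline is testable
without any external download.

## Worked example

```r
library(eciml)

cfg <- synthetic_config(seed = 42)        # 40 enzymes in 4 families,
gen <- generate_dataset(cfg)              # 20 chemicals in 4 classes
gen$dataset
#> <activity_dataset> synthetic_seed42: 40 enzymes x 20 chemicals, 800 assayed pairs (binary scale)

compute_statistics(gen$dataset, scenario = "LPOT", include_similarity = FALSE)
#> <dataset_statistics> scenario LPOT
#>   n_enzymes                  40
#>   n_chemicals                20
#>   activity_ratio             0.3
#>   aoie                       0.4407
#>   aoic                       0.4662
#>   top5_protein_similarity    NA
#>   top5_chemical_similarity   NA

chem_spec <- descriptor_spec("external", vectors = gen$truth$chemical_features)
result <- run_cv(gen$dataset,
                 enzyme_spec = descriptor_spec("composition50"),
                 chemical_spec = chem_spec,
                 variants = list("rf_protein", "rf_none", "activity_baseline"),
                 scenario = "LPOT", seeds = c(101, 211), n_folds = 10)
result
#> <cv_result> scenario LPOT: 120 records, 0 skipped folds
#>            variant metric  mean     sd     sem  n
#>  activity_baseline   aupr 0.336 0.0970 0.02168 20
#>            rf_none   aupr 0.406 0.1296 0.02898 20
#>         rf_protein   aupr 0.955 0.0407 0.00910 20
#>  activity_baseline  auroc 0.466 0.1005 0.02248 20
#>            rf_none  auroc 0.581 0.1244 0.02782 20
#>         rf_protein  auroc 0.959 0.0405 0.00907 20

cmp <- compare_models(result, result, metric = "aupr",
                      variant_a = "rf_protein", variant_b = "rf_none")
sprintf("rf_protein vs rf_none: difference %+0.3f, p = %.2g %s",
        cmp$estimate, cmp$p_value, cmp$stars)
#> [1] "rf_protein vs rf_none: difference +0.549, p = 2.9e-20 ***"
```

Reading the numbers: on held-out *enzymes* (LPOT), the model with intact
protein descriptors reaches AUPR 0.955 — far above the positive
prevalence of 0.3 that a signal-free model converges to — while the
fully permuted model (0.406) sits near the non-ML activity baseline
(0.336). The gap is the measured contribution of the protein descriptor
for this dataset; the stars come from a pooled-variance t-test over the
20 per-fold values of each model. The statistics block shows the dataset
the models saw: a 40 × 20 screen, 30% active, with order indices in the
random-data range (both near 0.5, as expected here because the family
structure makes activity block-wise, not globally ordered).

The vignette (`vignettes/descriptor-ablation.Rmd`) documents the model,
the statistics, every tunable parameter and the generator's scope.

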