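# augsplit

Where should data augmentation be applied relative to the division of an
image-classification dataset into training, validation and test subsets?
Applied to the wrong place, geometric augmentation leaks information
between subsets: rotated or flipped derivatives of one parent image end up
on both sides of a split, and every estimate computed on the "held-out"
side becomes optimistic. `augsplit` is an R framework for studying this
systematically on synthetic two-class image benchmarks, built for
methodologists in biological image analysis who need to know which of
these estimates to trust.

Starting from one pool of originals, the distinct placements reduce to six
model-building ways — augment nothing (B), the validation set (A), the
training set (C), both independently (D), everything after test-set
separation but before the train/validation split (E), or everything before
any splitting (F) — and eleven testing protocols once the test-set
condition (non-augmented vs augmented) is crossed in. The package
provides:

* **`generate_synthetic_dataset()`** — balanced two-class square images
  whose class signal (radially symmetric textures at class-specific
  spatial frequencies) is exactly invariant under the 8 dihedral
  transforms, while each image carries a unique fingerprint whose
  transform-invariant component makes derivatives of one parent mutually
  recognizable — the mechanism that makes leakage measurable — plus a
  fixed oriented bias field standing in for the orientation statistics of
  real photographic data.
* **`augment_dataset()` / `apply_transform()`** — lossless eight-fold
  dihedral augmentation with full provenance (`parent_id`,
  `transform_id`); PNG + manifest I/O and bilinear resizing around it.
* **`stratified_kfold()`, `split_train_val()`, `build_fold_datasets()`,
  `leakage_audit()`** — stratified 5-fold cross-validation with 3:1:1
  train:validation:test ratios under all eleven protocols, and the
  per-subset-pair count of leaked parents.
* **`train_with_early_stopping()`, `run_experiment()`** — a mini-batch
  SGD harness (batch 10, momentum 0.9, learning rate 1e-4, L2 1e-4) that
  stops when 5 consecutive epochs fail to improve the best validation
  accuracy or at 50 epochs, for any classifier satisfying a small
  probabilistic contract; a fast logistic reference classifier is bundled.
* **`pooled_proportion_metrics()`, `pooled_roc_auc()`,
  `exact_binomial_ci()`, `mean_t_ci()`, `time_cost_correlation()`** — the
  statistical layer: micro-averaged cross-fold metrics

  Accuracy = Σₖ(TPₖ+TNₖ) / Σₖ(TPₖ+TNₖ+FPₖ+FNₖ),
  Sensitivity = ΣₖTPₖ / Σₖ(TPₖ+FNₖ),
  Specificity = ΣₖTNₖ / Σₖ(TNₖ+FPₖ),

  each with a Clopper–Pearson exact binomial 95% CI (numerator = successes,
  denominator = trials); ROC AUC on the probabilities pooled across folds
  (DeLong or exact-binomial CI); Student-t CIs (4 df under 5-fold CV) for
  epoch counts and times; and Pearson correlation of each metric with the
  log mean training time.
* **`run_matrix()` / `summarize_matrix()`** — the full study (classifiers ×
  ways × test conditions) from one seeded configuration, with the matrix
  cardinalities (6 ways, 11 protocols, 24 model groups and 44 testing
  groups at four classifiers) asserted before any training.

## Worked example

```r
library(augsplit)

ds <- generate_synthetic_dataset(synth_params(n_per_class = 100, seed = 42))
ds
#> <labeled_dataset> 200 records (100 negative, 100 positive), originals only

# Way E: separate the test set, augment the rest, then split 3:1 --------
fold1 <- build_fold_datasets(ds, protocol_config("E", seed = 42), fold = 1)
sapply(fold1[1:3], n_records)
#>      train validation       test
#>        960        320         40
leakage_audit(fold1$assignment)
#> <leakage_report> train/val: 138  train/test: 0  val/test: 0 parents shared

# Train and pool: no augmentation (B) vs augment-then-split (E) ---------
clf <- logistic_pixel_classifier()
res_B <- run_experiment(ds, "B", clf, training_config(), k = 5, seed = 42)
res_E <- run_experiment(ds, "E", clf, training_config(), k = 5, seed = 42)
dplyr::bind_rows(
  pool_fold_results(res_B, "original"),
  pool_fold_results(res_B, "augmented"),
  pool_fold_results(res_E, "augmented")
)
#>   way test_condition accuracy accuracy_lower accuracy_upper   auc
#> 1   B       original    0.770          0.705          0.826 0.800
#> 2   B      augmented    0.604          0.579          0.628 0.626
#> 3   E      augmented    0.873          0.855          0.888 0.945
#>   validation_accuracy mean_epochs leak_train_val
#> 1               0.715         8.4              0
#> 2               0.715         8.4              0
#> 3               0.954        30.0            726
```

Three findings are visible already in this single-seed run. Way E leaks
138 of 160 training/validation parents in fold 1 (726 summed over the five
folds), and its validation accuracy (0.954) is far above its own test
accuracy (0.873) — the leaked validation set flatters the model. Way E
nevertheless genuinely beats way B on the test set (0.873 vs 0.770):
augmenting the combined train/validation pool builds a better model even
though it corrupts the validation estimate. And the unaugmented-training
model of way B drops from 0.770 to 0.604 when the test set is augmented —
a model that never saw rotated images is measurably worse on them, and the
augmented test set, with eight times the trials, says so with a much
narrower confidence interval.

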