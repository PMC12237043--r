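# falearn — focal active learning for imbalanced binary classification

`falearn` implements a pool-based *focal active learning* (FAL) strategy for
tabular clinical data with rare positives — the motivating setting is
diabetes screening, where fewer than one patient in ten is positive and
labels (confirmed diagnoses) are expensive. Instead of labeling the whole
pool, the method spends a fixed annotation budget where it matters:

1. **Focal selection.** K-means under cosine similarity (spherical
   k-means) partitions the unlabeled pool into `k` clusters; the member
   most similar to each centroid becomes that cluster's *focus*, and the
   foci seed the labeled set. By default `k = round(√(n/2))`.
2. **Combined-score acquisition.** Each iteration scores every unlabeled
   candidate `i` as

   ```
   score_i = α·s̃_i + β·ũ_i + γ·δ_i
   ```

   where `s_i = max_j cos(x_i, μ_j)` is the nearest-focus similarity,
   `u_i = −max_c P(y = c | x_i)` is the prediction uncertainty of the
   current classifier, `δ_i` flags (predicted) minority-class membership,
   and `s̃, ũ` are min-max normalized over the candidate pool. The top
   `2k` candidates are labeled and moved into the sub-pool; the loop stops
   when the sub-pool reaches 20 % of the pool.
3. **Shapley attention weighting.** After each batch, exact Shapley values
   `φ_j` of the current classifier are computed by full subset enumeration
   (interventional expectation over a background sample); mean-|φ|
   importances, rescaled to mean one, multiply the feature columns so the
   features the model currently relies on are amplified in the next round.

Around the core, the package ships the standard pipeline: deduplication,
IQR outlier fences, lexicographic label encoding, z-score standardization
fitted on the training split, stratified 70/15/15 splitting, a classifier
registry (logistic regression, linear/RBF SVM, CART, random forest,
gradient boosting, naive Bayes, MLP) with inverse-frequency class weights
and grid-search CV tuning, confusion-matrix metrics, paired t-tests, and a
synthetic generator that emulates a 100k-row diabetes screening table
(8 features, 8.5 % prevalence) so everything runs without external data.

## Worked example

```r
library(falearn)

d  <- generate_synthetic(synthetic_spec(n_rows = 2000, seed = 42))
pp <- preprocess_pipeline(d, "diabetes",
        c("age", "bmi", "HbA1c_level", "blood_glucose_level"), seed = 42)

fit <- fal(diabetes ~ ., data = pp$train, seed = 42)
summary(fit)
#> Focal active learning fit
#>   pool 1380, labeled 276 (20.0%), 5 acquisition iterations
#>   classifier: logistic (fal), minority fraction of sub-pool: 0.272
#>
#> Acquisition history:
#>  iteration n_labeled batch minority_fraction
#>          0        26    26        0.07692308
#>          1        78    52        0.34615385
#>          2       130    52        0.33076923
#>          3       182    52        0.33516484
#>          4       234    52        0.30341880
#>          5       276    42        0.27173913
#>
#> Final feature importances (mean-|Shapley|, mean-one scaled):
#>         HbA1c_level blood_glucose_level                 age        hypertension
#>              2.6783              2.2935              1.3529              0.6285
#>       heart_disease                 bmi              gender     smoking_history
#>              0.4071              0.2893              0.2016              0.1487

pred <- predict(fit, pp$test, type = "class")
metrics(confusion_counts(pp$test$diabetes, pred))
#> accuracy 0.9189  precision 0.4737  recall 0.3913  F1 0.4286
#>   TP 9  TN 263  FP 10  FN 14
```

Reading the output: the foci alone (iteration 0) reflect the pool's 8 %
prevalence; the minority-priority term then lifts the labeled sub-pool to
~27 % positive, and the Shapley importances recover the planted signal —
the glycemic markers (HbA1c, blood glucose) dominate, demographics
contribute little. Only the 276 queried labels were ever revealed to the
learner.

Complete scripted runs (simulate → preprocess → run → compare, with JSON
sidecars for full reproducibility) are available as `cmd_simulate()`,
`cmd_preprocess()`, `cmd_run()` and `cmd_compare()`, or from a shell via
`Rscript inst/cli/fal.R <subcommand> ...`.

## Vignette

`vignettes/focal-active-learning.Rmd` documents the model and its
assumptions, every tunable parameter with its default and rationale, the
synthetic generator's design, numerical conventions (tie-breaks, degenerate
cases, tolerances) and known limitations.
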