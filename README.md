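# qsardpp

QSAR modeling of DPP-IV inhibitory activity with mRMR-BFS feature
selection and support vector regression.

Dipeptidyl peptidase IV (DPP-IV) inhibitors are a major class of type-2
diabetes drug candidates; medicinal chemists screen them by their
inhibitory potency, reported as pIC50 = −log10(IC50 in mol/L). `qsardpp`
is an R toolkit for building quantitative structure–activity relationship
(QSAR) models that predict pIC50 from cheap physicochemical descriptors,
aimed at computational chemists who want a transparent, fully scriptable
pipeline: descriptor computation from structure files, information-theoretic
feature screening, cross-validation-driven feature elimination, kernel
regression, and external validation.

## The method

The pipeline has three stages.

**1. Descriptors.** V2000 MOL/SDF structures are parsed into molecular
graphs and a small registry of descriptors is computed: elemental-analysis
mass fractions (e.g. `OComposition`, the percent of molecular mass due to
oxygen, with implicit hydrogens materialized by standard valence rules),
topology counts (`RingBondCount`, the number of bonds on cycles;
`AliphaticRingCount`, the number of smallest-set-of-smallest-rings members
that are not fully aromatic), and geometry descriptors
(`MinimalProjectionArea`/`MaximalProjectionArea`, the extreme areas of the
molecule's van der Waals silhouette over sampled view directions, in Å²).
Basic pKa is accepted as a precomputed input column.

**2. Feature selection (mRMR-BFS).** Features are first ranked by the
minimum-redundancy–maximum-relevance score

    score_j = I(f_j, c) − (1/m) · Σ_{f_i ∈ S} I(f_i, f_j)

where `I` is mutual information estimated after discretization and `S` is
the set already selected. The top-ranked pool (default 50) is then pruned
by backward feature selection: at each step every single-feature removal is
scored by the leave-one-out cross-validated (LOOCV) RMSE of a support
vector regression, and the removal with the lowest RMSE is applied; the
best subset is the global LOOCV-RMSE minimizer along the path.

**3. Model and validation.** An ε-insensitive support vector regression
with the RBF kernel `K(x, x′) = exp(−γ‖x − x′‖²)` is trained on
min-max-scaled features and target (defaults C = 2.0, ε = 0.05, γ = 1.0),
so the fitted model has the explicit kernel-expansion form

    pIC50(x) = s · [ Σ_i β_i K(x, x_i) + b ] + y_min

with `s`/`y_min` the training-activity range and minimum. Models are
validated by the squared correlation coefficient
`q² = 1 − Σ(y_i − ŷ_i)² / Σ(y_i − ȳ)²` and `RMSE = sqrt(Σ(y_i − ŷ_i)²/N)`,
on the training fit, on training LOOCV, and on an external test set built
by ranking compounds by activity and holding out every fourth one.

The package ships a 48-compound cyanopyrrolidine-amide benchmark
(experimental, fitted, and LOOCV pIC50 plus test flags) and a synthetic
feature-table generator with planted informative, redundant, and
irrelevant features so every stage is testable end to end.

## Worked example

```r
library(qsardpp)

syn   <- generate_synthetic(synthetic_spec())   # 48 samples x 75 descriptors
rk    <- mrmr_rank(syn, top_k = 50)             # stage 1: mRMR ranking
trace <- backward_select(syn, attr(rk, "selected"))  # stage 2: BFS
attr(trace, "best_subset")
#> [1] "inf_2"  "inf_5"  "inf_3"  "inf_6"  "inf_1"  "inf_4"  "noise_36"
round(attr(trace, "best_rmse"), 3)
#> [1] 0.684

parts <- split_every_kth(syn, every_k = 4)      # 36 train / 12 test
model <- train_svr(parts$train, attr(trace, "best_subset"))
model
#> <svr_model> 14 support vectors over 7 features (C = 2, epsilon = 0.05, gamma = 1)
evaluate(prediction_set(parts$test$sample_ids, parts$test$activity,
                        predict(model, parts$test)))
#> <evaluation_report> n = 12  q2 = 0.8235  RMSE = 0.9134
```

The generator plants 6 informative features among 60 pure-noise and 9
redundant ones; the selection funnel recovers all six (plus one stray
noise column), and the held-out q² ≈ 0.82 says the model explains ~82% of
the test-set activity variance around its mean.

The same pipeline is available from a shell via the installed script
(`system.file("cli", "qsardpp", package = "qsardpp")`), with subcommands
`descriptors`, `split`, `mrmr`, `select`, `train`, `predict`, `evaluate`,
`simulate`, and `reproduce-table2`. `reproduce-table2` recomputes the six
benchmark statistics from the packaged table and prints a pass/fail table:

```
statistic      recomputed  reference status
q2_train           0.9536      0.953   pass
rmse_train         0.1230      0.123   pass
q2_train_cv        0.8133      0.815   pass
rmse_train_cv      0.2469      0.247   pass
q2_test            0.8836      0.884   pass
rmse_test          0.1925      0.193   pass
```

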