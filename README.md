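# subgroupsim

Monte Carlo benchmarking of group-classification methods when the known
groups secretly consist of **latent subgroups**.

Clinically defined groups (depressed vs non-clinical, ADHD severity
bands, ...) are routinely treated as homogeneous although each may mix
qualitatively different sub-populations. `subgroupsim` is for
methodologists and applied researchers who want to study — or stress-test
— classifiers under exactly this kind of within-group heterogeneity. It
provides:

* a **simulator** for correlated multivariate-normal predictors
  (default: the WAIS-III five-subscale correlation matrix as the shared
  covariance, unit SDs) with 2 or 3 known groups separated by a
  standardized mean difference δ ∈ {0.2, 0.5, 0.8}, each group a
  two-component mixture whose subgroup means differ by
  s ∈ {0, 0.05, ..., 0.20}, exact group/subgroup size ratios, and a
  paired training / cross-validation (CV) sample per replicate;
* **five classifiers** behind one `fit_*()` / `predict()` contract with
  per-class posterior probabilities: LDA, baseline-category multinomial
  logistic regression (Newton–Raphson), a deviance-split classification
  tree (reduction threshold 1% of root deviance, minimum child size 10),
  an additive logistic (GAM) classifier with fixed-df cubic splines, and
  **mixture discriminant analysis** — class densities
  p(x|k) = Σ_r π_kr φ(x; μ_kr, Σ) with a shared covariance, fitted by a
  deterministic-start EM (tolerance 5e-5, ≤ 100 iterations) that also
  exposes per-observation subclass responsibilities;
* **misclassification accounting** — overall and by-group rates on
  training and CV samples (the by-group rates recombine exactly to the
  overall rate) and the equal→75/25 subgroup-ratio increase series;
* a **factorial experiment harness** with reproducible per-replicate
  seeding, tidy CSV results, condition-table summaries and marginal
  statistics, YAML/JSON configs, and a thin CLI
  (`inst/cli/subgroupsim.R` with `simulate` / `run` / `summarize`
  subcommands).

## Worked example

```r
library(subgroupsim)

design <- simulation_design(n_groups = 3, total_n = 300,
                            delta = 0.5, s = 0.15,
                            subgroup_proportions = c(0.75, 0.25))
pair <- simulate_pair(design, seed = 42)

fit  <- fit_mixda(pair$train)        # 2 Gaussian subclasses per class
pred <- predict(fit, pair$cv)
misclassification_overall(pred$class, pair$cv$group)
#> [1] 0.5433333
misclassification_by_group(pred$class, pair$cv$group)
#> group1 group2 group3
#>   0.52   0.69   0.42
round(fit$pi, 3)                     # fitted within-class mixing proportions
#>       [,1]  [,2]
#> [1,] 0.774 0.226
#> [2,] 0.716 0.284
#> [3,] 0.671 0.329
```

The overall CV rate (0.543) is the group-size-weighted mean of the
by-group rates; the middle group (flanked on both sides) is hardest to
classify, and the fitted mixing proportions approximate the 75/25
subgroup split the data were generated with. A small factorial run:

```r
g <- experiment_grid(total_n = 150, group_ratio = "equal",
                     subgroup_ratio = "equal", delta = 0.5,
                     methods = c("lda", "cart", "mixda"),
                     replicates = 20, seed = 1)
res <- run_grid(g)
pivot_methods(summarize_results(res, by = "overlap"))
#>   overlap  cart   lda mixda
#> 1    0.00 0.577 0.525 0.535
#> 2    0.05 0.608 0.542 0.551
#> 3    0.10 0.578 0.557 0.572
#> 4    0.15 0.581 0.540 0.550
#> 5    0.20 0.599 0.561 0.577
```

Mean CV misclassification per subgroup-overlap level: at this cell
(N = 150, equal ratios, δ = 0.5) LDA tracks the Bayes bound of the
generative model most closely and the tree pays an overfitting penalty;
rates drift upward as the subgroup separation s grows.

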