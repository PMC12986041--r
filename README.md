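# stagecoupling

Stage-stratified coexpression **coupling** analysis for gene panels, built
around the DDR–collagen–MMP circuit of the colorectal adenoma–carcinoma
sequence.

## The problem

As colorectal tissue progresses from normal mucosa through adenoma to
carcinoma, matrix-remodeling genes change not only *how much* they are
expressed but *how tightly* their expression is coordinated. The natural
statistic for that coordination is the squared Pearson correlation between
two genes within one disease stage,

$$R^2_{ij} = r_{ij}^2, \qquad
  r_{ij} = \frac{\sum_k (x_{ik}-\bar x_i)(x_{jk}-\bar x_j)}
  {\sqrt{\sum_k (x_{ik}-\bar x_i)^2 \sum_k (x_{jk}-\bar x_j)^2}},$$

and the object of interest is a pair's **coupling trajectory** — its $R^2$
across the ordered stages — together with hub summaries (mean $R^2$ of a
DDR receptor over its 12 matrix targets per stage) and a kinetic
classification (*de novo* activation from a near-zero baseline versus
*progressive* strengthening). The canonical example is DDR2–COL11A1, which
climbs from essentially zero coupling in normal mucosa to $R^2 \approx
0.55$ in carcinoma while DDR2's own expression stays flat.

The package implements the full analysis as a tested, seeded pipeline for
anyone who wants to run it on their own log2 expression matrices or study
its statistical behaviour on simulated data:

* a **synthetic-data generator** with planted per-stage coupling, stage
  means, batch effects and optional bimodal marginals (`synthetic_spec()`,
  `simulate_expression()`);
* parametric empirical-Bayes **batch correction** in the location/scale
  (ComBat-style) model, preserving the stage covariate
  (`correct_batch_effects()`);
* stage-stratified **correlation tables** with BH-FDR within stage, hub
  summaries, trajectories and average-linkage clustering on $d = 1 - |r|$
  (`stage_correlation_table()`, `coupling_trajectories()`);
* **differential expression**: one-way ANOVA, Tukey HSD, fold-changes and
  category summaries (`differential_expression()`);
* a feed-forward **neural-network stage classifier** (64/32/16, batchnorm,
  dropout, Adam, plateau scheduling, early stopping) with full evaluation
  metrics (`train_classifier()`, `evaluate_classifier()`);
* gradient-based **Shapley attribution** with per-gene importance and the
  hub–target interaction statistic
  $I_{h,j} = \tfrac1N\sum_k |\phi_h^{(k)}\phi_j^{(k)}|$
  (`gradient_shap()`, `interaction_importance()`);
* **STRING-format PPI evidence** filtering to within-panel pairs at
  multiple experimental-score thresholds (`filter_panel_edges()`);
* an end-to-end orchestrator with per-module seed derivation, a schema-
  validated report, and a convergence summary across the three analytical
  routes (`run_coupling_analysis()`).

Results are tibbles throughout, with `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` figures for each result type.

## Worked example

```r
library(stagecoupling)

report <- run_coupling_analysis(run_config(seed = 1), quiet = TRUE)
report
#> <coupling_report> seed 1 | config 6c1c854e
#>   hub mean R2: 0.133 -> 0.229 -> 0.380 (2.86-fold)
#>   test accuracy: 0.9804
#>   convergence: routes disagree on COL11A1, MMP11

report$hub_summary
#> # A tibble: 3 x 5
#>   hub   stage     mean_r2 transition_fold overall_fold
#>   <chr> <chr>       <dbl>           <dbl>        <dbl>
#> 1 DDR2  normal      0.133           NA            2.86
#> 2 DDR2  adenoma     0.229            1.72         2.86
#> 3 DDR2  carcinoma   0.380            1.66         2.86

dplyr::filter(report$trajectories, gene_a == "DDR2", gene_b == "COL11A1")
#>   r2_normal  r2_adenoma r2_carcinoma delta_overall kinetic_class
#> 1 2.40e-05   0.241      0.556        0.556         de_novo

report$category_summary
#> # A tibble: 3 x 3
#>   category mean_fold n_genes
#> 1 collagen     1.30        7
#> 2 mmp          1.60        5
#> 3 receptor     0.976       2
```

Reading the numbers: the generator plants the study's structure, and the
pipeline recovers it — DDR2's mean coupling with its 12 targets rises from
$R^2 = 0.133$ in normal mucosa to $0.380$ in carcinoma (a 2.86-fold gain on
this draw; the planted population value is 2.59), the DDR2–COL11A1 pair is
classified *de novo* (near-zero baseline, $\Delta R^2 = 0.556$), MMPs are
the most upregulated category (mean 1.60-fold), and the classifier reaches
98% held-out accuracy on the planted stage structure. The convergence
summary reports, per analytical route, the top-ranked hub partner; on this
seed the coupling-gain and fold-change routes pick COL11A1 while the
attribution route narrowly prefers MMP11 — the summary is computed, never
asserted, and single-seed rank flips between the two strongest planted
genes are expected.

Plots: `plot_trajectories()`, `plot_correlation_heatmap()`,
`autoplot(report$metrics)` (confusion matrix), `plot_roc()`,
`autoplot(report$attribution)` and `plot_interaction_importance()`.

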