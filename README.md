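# rocsurface

Classifier evaluation for heavily class-skewed labeled data.

In many high-throughput settings — spike-in gold standards, copy-number
break-point detection, any screen where only the top-ranked features matter —
true negatives outnumber true positives by orders of magnitude. The ordinary
ROC curve and its AUC are blind to this skew: at low false positive rates the
realized false discovery rate can already be unacceptable, so only a small
corner of the curve is practically relevant. `rocsurface` evaluates rankers
on such data with a three-dimensional ROC surface and two scalar summaries
that take the skew into account.

## The method

For a threshold `δ` swept over the scores, the true positive rate `TPR(δ)`,
false positive rate `FPR(δ)` and true discovery rate `TDR(δ) = 1 − FDR(δ)`
(FDR here is the realized false-discovery proportion, FP / (FP + TP), the
truth labels being known) trace an operating-point curve. The **ROC surface
(ROCS)** spans, at each TPR level, from that curve out to `FPR = 1` at height
TDR; its floor projection is the area under the ordinary ROC curve. Two
summaries follow, with all curves treated as step functions and integrals as
sums:

- **VUS** (volume under the surface): the TDR-weighted AUC,
  `VUS = Σ_k ΔTPR_k · TDR_k · (1 − FPR_k)`.
  It equals 1 exactly under perfect class separation at *any* class ratio,
  and approaches 0 for inseparable classes as the class ratio
  (#negatives / #positives) grows — unlike the AUC, which stays at 1/2.
- **FCAUC** (FDR-controlled AUC): the area under the ROC curve restricted to
  operating points with acceptable FDR. The most liberal cutoff `δ*` with
  `FDR(δ*) ≤ b` is located (the empirical FDR need not be monotone, so all
  cutoffs are scanned) and the curve is capped at `t* = TPR(δ*)`. If no
  cutoff attains the level, FCAUC = 0.

Significance is assessed by label permutation (for VUS / FCAUC of one study)
and, for the difference between two studies' surfaces, by a rank-based
bootstrap that first equalizes the influence of unequal class ratios by
resampling, pools within-study ranks by class under the null, and redraws
both studies `B` times. Note that, unlike ROC analysis, the positive and
negative class labels are **not** exchangeable here.

## Worked example

```r
library(rocsurface)

# six features, three spiked (positive), positives at ranks 1, 2, 5
d  <- labeled_scores(c(.9, .8, .7, .6, .5, .4), c(1, 1, 0, 0, 1, 0))
cv <- rocs_curve(d)
cv
#> # A tibble: 6 × 5
#>   threshold   fpr   tpr   fdr   tdr
#>       <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1       0.9 0     0.333 0     1
#> 2       0.8 0     0.667 0     1
#> 3       0.7 0.333 0.667 0.333 0.667
#> 4       0.6 0.667 0.667 0.5   0.5
#> 5       0.5 0.667 1     0.4   0.6
#> 6       0.4 1     1     0.5   0.5

roc_auc(cv)        # 0.7777778  (= 7/9, the Mann-Whitney concordance)
vus(cv)            # 0.7333333  (= 11/15, TDR-weighted)
fcauc(cv, 0.2)     # 0.6666667  (curve capped at TPR 2/3, the last FDR <= 0.2 cutoff)
```

On a skewed synthetic study the three numbers tell different stories: the
AUC looks strong while the FDR-aware summaries reveal how little of the
curve is usable.

```r
study <- simulate_two_class(n_neg = 9000, n_pos = 1000, mu_pos = 2, seed = 1)
cv2 <- rocs_curve(study)
c(auc = roc_auc(cv2), vus = vus(cv2), fcauc = fcauc(cv2))
#>   auc   vus fcauc
#> 0.924 0.643 0.376

tidy(rocs_perm_test(study, K = 199, seed = 7))
#> # A tibble: 1 × 6
#>   statistic estimate p.value n.resamples null.mean  seed
#> 1 vus          0.643       0         199    0.0524     7
```

`autoplot(cv2, fdr = 0.2)` draws the ROC with segments dichotomized at the
FDR level and the FCAUC region shaded; `plot_rocs_surface(cv2, "rocs.png")`
writes a static 3D rendering of the surface. Two studies are compared with
`rocs_diff_test(study1, study2, B = 199)`, and the simulation helpers
`simulate_vus_grid()` / `simulate_size_power()` map metric behaviour and
test size/power over separation and class-ratio designs.

A command-line interface wrapping these functions ships at
`inst/cli/rocs.R` (subcommands `curve`, `auc`, `vus`, `fcauc`, `permtest`,
`compare`, `simulate-grid`, `simulate-power`, `plot3d`, `plotroc`; numeric
output as `name<TAB>value` lines).

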