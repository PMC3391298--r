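---
title: "ROC surfaces for class-skewed data: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ROC surfaces for class-skewed data: models, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rocsurface)
```

## The evaluation problem

`rocsurface` evaluates rankers on labeled data where the true negative class
vastly outnumbers the true positive class — spike-in benchmarks and other
gold-standard screens. Two factors jointly determine how useful a ranker is
there: the separation between the class score distributions, and the class
ratio (#negatives / #positives). The ROC curve and its AUC capture only the
first. The realized false discovery rate at a cutoff,
`FDR = FP / (FP + TP)`, captures the second, because at a fixed FPR the FDR
worsens as positives become rarer. The ROC surface combines all three rates
in one object, and its scalar summaries (VUS, FCAUC) weight or restrict the
ROC by discovery precision.

## The surface and its summaries

Sweeping a threshold down the scores gives operating points
`(FPR(δ), TPR(δ), TDR(δ))` with `TDR = 1 − FDR`. The surface spans, at each
TPR level, from the operating-point curve out to `FPR = 1` at height TDR;
its floor projection is the region under the ordinary ROC curve. The volume
between surface and floor is then

```
VUS = Σ_k ΔTPR_k · TDR_k · (1 − FPR_k),    AUC = Σ_k ΔTPR_k · (1 − FPR_k),
```

so the VUS is the AUC with every TPR increment weighted by the precision of
the discovery set achieving it. Two consequences fix the interpretation:
perfect separation gives TDR = 1 on every relevant step and hence VUS = 1 at
any class ratio, and inseparable classes at extreme class ratio drive TDR,
and so the VUS, toward 0.

The FCAUC fixes an acceptable FDR level `b` (default 0.2 throughout the
package), finds the *most liberal* cutoff with `FDR ≤ b` — the empirical FDR
is not monotone in the threshold, so every cutoff is scanned rather than
bisected — and caps the ROC curve at that cutoff's TPR `t*`. The reported
value is the step-sum area under the capped curve; it is 0 when no cutoff
attains the level and equals the AUC at `b = 1`.

Two geometric readings of "area under the ROC corresponding to the FDR
level" are conceivable: the area under the curve *left of* `FPR(δ*)`, or the
area under the curve *capped at* `t* = TPR(δ*)`. This package uses the cap.
The left-partial reading is self-defeating for exactly the best rankers: a
perfectly separated study reaches `TPR = 1` at `FPR = 0`, so the left
partial area would be 0 where the intended value is 1, while the cap gives
FCAUC = AUC = 1. The cap also makes `FCAUC ≤ AUC` with equality at `b = 1`
immediate, and is monotone in `b`.

## Step-function conventions

All curves are empirical step functions and all integrals are sums; the
conventions below pin down every edge case and are asserted by the test
suite.

- **Discovery direction.** After orientation, a feature is a discovery at
  cutoff `δ` when its score is `≥ δ`.
- **Orientation.** If the positive-class median lies below the
  negative-class median, all scores are negated; a median tie changes
  nothing, making `orient()` idempotent and deterministic.
- **Tied blocks.** Tied scores enter or leave the discovery set as one
  block; the curve holds one operating point per distinct score value. Each
  TPR increment is credited at its block-endpoint FPR and TDR — a
  conservative choice: a fully tied score vector yields a single operating
  point at `(FPR, TPR) = (1, 1)` and AUC 0, not the trapezoidal 1/2.
- **No empty-discovery point.** The cutoff above the maximum score has
  FDR = 0/0 and is not an operating point; curves start at the first
  non-empty discovery set, and the conceptual `(0, 0)` origin enters only
  through the `ΔTPR` of the first stored point.
- **Rank invariance.** All rates depend on scores only through their order,
  so any strictly increasing transform of the scores leaves curve and
  metrics unchanged (tested property).
- **Label asymmetry.** Swapping the class labels (with score negation)
  preserves the AUC but generally changes the VUS and FCAUC; positive and
  negative labels are not exchangeable in this analysis.

## Significance testing

**One study.** The null distribution of the VUS (or FCAUC) is built by
permuting the truth labels over positions `K` times with scores fixed. A
permuted label set can flip which class scores higher, so orientation is
re-applied before each recomputation. The one-sided p-value is the plain
proportion of permuted statistics `≥` the observed one; the
`(count+1)/(K+1)` correction is available via `add_one = TRUE` but off by
default, so `p = 0` is representable and the p-value matches the raw
exceedance proportion.

**Two studies.** `rocs_diff_test()` tests whether two studies share the same
class-specific distributions of ranks, with `|VUS₁ − VUS₂|` as the
statistic. Because the VUS responds to the class ratio, a naive pooled
bootstrap would confound ratio differences with distributional ones. The
null distribution is therefore built in stages: (i) from each study,
resample `(n₀+m₀)/2` negatives and `(n₁+m₁)/2` positives (rounded), so both
studies contribute at a common ratio; (ii) convert each study's resample to
within-study ranks, breaking ties uniformly at random; (iii) pool negative
ranks across studies and positive ranks across studies; (iv) redraw both
studies at their *original* class sizes with replacement from the pools `B`
times, recomputing the statistic. Resampling is done with replacement
uniformly — it is required whenever the target count exceeds a study's own
class count, and using it everywhere keeps the procedure one rule. The
observed statistic is computed on the full original (oriented) studies, not
the stage-(i) subsample, which exists only to shape the null; for tie-free
scores the rank transform leaves the VUS unchanged anyway (tested), and
bootstrap replicas are not re-oriented since the pools already inherit the
studies' orientation. `B ≥ 199` is recommended for testing at the 0.05
level; the p-value granularity is `1/B`.

All randomness in a test flows from a single optional `seed`, which is
recorded in the returned object; a `NULL` seed leaves the caller's RNG
stream in charge.

## What the simulator emulates

`simulate_two_class()` draws the two classes from Gaussians with a shared
standard deviation of 1 (defaults: negatives at mean 0), so class separation
is the mean difference and skew is the count ratio — the two axes the
surface is designed to disentangle. `simulate_vus_grid()` maps mean VUS and
FCAUC over a separation × ratio grid with 50 replicates of 2000 samples per
cell by default, the total split by ratio with at least one positive;
defaults sweep separations 0–6 in half-unit steps and ratios
{1, 2, 4, 8, 16}. `simulate_size_power()` wraps the two-study test over
replicate pairs (defaults: 4000 samples per study, 100 pairs, `B = 199`,
`α = 0.05`); "study size" means the total count, split by the class ratio.

The generator emulates exactly one mechanism: exchangeable unimodal scores
with a location shift and known labels. Real score distributions are
heavy-tailed, multimodal and tied (discretized statistics, capped ranks),
and real gold standards mislabel some features. Passing tests on this
generator therefore validate the *metric and test machinery* — step
conventions, calibration of sizes, monotone responses to separation and
skew — not robustness to those real-data features. Tied scores specifically
are exercised by dedicated lattice-valued fixtures in the test suite rather
than by the Gaussian generator, which is almost surely tie-free.

## Problem sizes in the test suite

The suite checks calibration at the designs above: the null rejection rate
of the two-study test at 4000 samples per study over 100 pairs (and a
smaller unequal-design variant at 1000/2000), permutation p-value uniformity
over 200 small studies, metric oracles (pair counting, fine-grid Riemann
integration) at up to a few dozen features where brute force is exact, and
grid monotonicity at 2000 samples × 50 replicates per cell. The Riemann
check uses positive-class counts that divide the grid size so that step
breakpoints land on cell boundaries and the midpoint rule is exact to
floating-point precision.

## Known limitations

- The VUS and FCAUC are functions of the class ratio by design; they are
  meaningful only when the evaluation data's ratio matches the deployment
  ratio. Users foreseeing a mismatch should resample the labeled data to
  the target ratio before evaluation.
- The empirical FDR at small discovery counts is noisy; at tiny sample
  sizes the FCAUC inherits that noise through its cutoff selection.
- Curves are purely empirical steps: no smoothing, no binormal fitting, no
  confidence bands on the curve itself.
- The two-study test compares two studies; many pairwise comparisons are
  left to the caller's multiplicity control.
- 3D rendering is a static projection (`persp`); no interactive device is
  used.
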