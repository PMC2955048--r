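---
title: "Error discovery rates from parallel negatives: model and methods"
author: "parallelEDR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error discovery rates from parallel negatives: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parallelEDR)
```

## The problem

A microarray (or any many-hypothesis expression screen) tests thousands of
genes at once. Classical multiplicity corrections — family-wise procedures
(Bonferroni, Holm, Hochberg, step-down Šidák) and false-discovery-rate
procedures (Benjamini–Hochberg, Benjamini–Yekutieli, Storey q-values) —
scale the per-gene error by the *total* number of tests $m$ (or an estimate
of the null count $m_0$). When only a handful of genes among tens of
thousands are truly changed, that scaling drives every adjusted value
toward 1 and the screen loses all power, which is why gene filtering
before correction became common practice despite being statistically
questionable.

The error discovery rate (EDR) implemented here takes a different census.
If the null p-values are uniform, the number of genes with $p \le t$
contributed by nulls is mirrored, in expectation, by the number of genes
with $p \ge 1 - t$ — the **parallel negatives**
$N'(t) = \#\{j : p_j \ge 1 - t\}$. The genes at the far tail are the ones
most likely to be genuine nulls, so the census is taken where the null
signal is cleanest, and it adapts to the realized p-value distribution
instead of to $m$.

## The model

With $R(t) = \#\{j : p_j \le t\}$ rejections at level $t$:

* **Global rate** $\mathrm{EDR}(t) = N'(t)\, t / R(t)$, the
  parallel-negative analogue of the FDR estimate $m_0 t / R(t)$.
  It is reported uncapped (it is a rate estimate), and is undefined
  (`NA` with a warning) when $R(t) = 0$. Under a pure null,
  $N'(t) \approx R(t)$, so the ratio $N'/R = \mathrm{EDR}(t)/t$
  concentrates at 1 — the calibration the test suite checks — and the
  rate itself concentrates at $t$.
* **Local, per-gene rate** $\mathrm{EDR}'_i = N'(p_i)\, p_i$: the census
  taken at the gene's own p-value. This is the path available when only a
  p-value vector is supplied (`edrFromPValues()`).
* **Reality factor** $\sigma_i = 1 / (x_i (f_i - 1))$, where $x_i$ is the
  gene's maximum group mean divided by the median of all expression
  values and $f_i \ge 1$ is the direction-folded fold change
  (largest over smallest group mean). Both are computed on the raw linear
  scale after percentile truncation. Low expression (small $x$) or a fold
  change near 1 inflates the error — encoding the bench reality that a
  tiny p-value earned by a minuscule variance at background intensity is
  not a reliable discovery, especially with few replicates.
* **Final per-gene rate** $\mathrm{EDR}_i = \min(1,\ N'_i\, p_i\,
  \sigma_i)$. Genes with $f_i = 1$ exactly, or with a nonpositive group
  mean after truncation, get $\mathrm{EDR}_i = 1$ (maximally unreliable)
  rather than an undefined value. Selection at level $\alpha$ keeps genes
  with $\mathrm{EDR}_i \le \alpha$, ordered by EDR, then raw p, then
  identifier. Because $\sigma_i$ varies per gene, the EDR ranking may
  legitimately invert the raw p-value ranking; the worked example below
  exhibits such an inversion and the tests assert it is preserved.

## Worked example

The package ships the published seven-probe-set table from a
hyperinsulinemia study (human skeletal muscle, 7129 probe sets; printed
inputs $p$, $x_i$, $f_i$, $N'$):

```{r}
tab <- hyperinsulinemiaExample()
tab$recomputed <- edrScore(tab$raw_p, tab$N_prime, tab$x_i, tab$f_i)
tab[, c("gene", "raw_p", "N_prime", "EDR", "recomputed")]
```

All seven recomputed values agree with the published column; the LTB4R
row demonstrates the cap (its raw product is about 8.6). At
$\alpha = 0.05$, five of the seven genes are selected.

## Preprocessing choices

* **Truncation** (`truncatePercentiles()`): values are clamped to the
  global 0.5% / 99.5% linear-interpolation (type 7) quantiles of the
  pooled matrix before any fold or ratio is taken, so single extreme
  intensities cannot fabricate huge folds. Pooling over all entries (not
  per gene) also makes the global median in $x_i$ well defined; the
  median is taken on the truncated matrix, since truncation is a
  preprocessing step that precedes all ratio work.
* **Testing scale** (`testPValues()`): test statistics use natural-log
  intensities by default (log values conform better to normality);
  $x$ and $f$ always use the raw truncated scale. Values $\le 0$ are
  raised to the smallest positive entry before logging.
* **Fold reading**: $f_i$ is the linear-scale ratio of extreme group
  means, folded to $\ge 1$ so up- and down-regulation are treated
  symmetrically. A log-scale reading of $f$ inside $\sigma$ was
  considered and rejected: only the linear reading reproduces the
  published worked table.
* **Degenerate tests**: a gene with zero within-group variance in every
  group gets $p = 1$ when the group means are equal and $p = 0$ (with a
  warning) when they differ — the limits of the t statistic.
* **Paired designs** are approximated by the two-sample test by default
  (matching the published reanalysis); a paired t option exists
  (`test = "t_paired"`).

## The census

$N'$ uses a closed boundary: ties at exactly $1 - t$ are counted in
("$1-t$ and above"). The census runs over *all* genes, positives
included — for any $t < 0.5$ a gene cannot simultaneously be rejected and
be its own parallel negative, and tied p-values always receive identical
$N'$ (the census depends on the value, not the rank). `runEDR()` computes
all $m$ censuses against the sorted p-vector (`findInterval`), and a test
verifies it against an independent linear scan.

## Classical comparisons

`adjustPValues()` exposes nine procedures behind one interface; the
sequential ones are expressed in adjusted-p form so `rejectAt()` is
uniform. Bonferroni, Holm, Hochberg, BH and BY delegate to
`stats::p.adjust`; the step-down Šidák, Storey q-value, PCER and PFER are
implemented in the package. Conventions:

* **q-value** uses the single-$\lambda$ plug-in
  $\hat\pi_0 = \#\{p_j > \lambda\} / (m(1-\lambda))$, capped at 1, with
  $\lambda = 0.5$ by default and exposed; the smoother variant is out of
  scope.
* **PCER** is the per-comparison (unadjusted) procedure. **PFER** reports
  $m p_i$, an expected error *count* compared against a user-chosen
  budget (default 1.0), not a probability.
* Every method, including the `p.adjust`-backed ones, is tested against
  an independent brute-force implementation of the textbook recursions on
  a randomized corpus of short p-vectors.

## Simulation design

`simulateExpression()` emulates a two-group, five-replicate microarray
study on the linear scale. Null genes share one mean
$m_i \sim U(10,\,10000)$ and one standard deviation
$sd_i \sim U(1,\,500)$ across both groups (a strict null with exactly
equal means). True DEGs — `round(m * s0)` of them — multiply or divide
(equal probability) the group-2 mean by a fold
$\sim U(1.5,\,3)$, and each DEG group's standard deviation is one-fifth
of its mean. Draws are normal, clipped from below at 0.01 so logs and
ratios stay defined. The mean and sd ranges stand in for the spread of a
real normalized data set and are fully configurable; nothing external is
ever downloaded.

What the generator deliberately does **not** emulate: inter-gene
correlation (clumpy pathway dependence), probe-level effects,
array-specific normalization artifacts, and heavy-tailed noise. Passing
tests therefore demonstrate calibration and ordering behavior under
independent, near-normal nulls — not performance on correlated real
arrays.

## Evaluation

`confusionCounts()`/`rates()` use the standard definitions
$TPR = TP/(TP+FN)$, $FPR = FP/(FP+TN)$, $Precision = TP/(TP+FP)$; a rate
with a zero denominator is `NA`, never silently 0. Curves sweep the
rejection threshold over the sorted unique score values, so tied genes
enter or leave together; the ROC is anchored at $(0,0)$ and $(1,1)$
(EDR's capped mass point at 1 forms a terminal tie block) with
trapezoidal AUC, while the PR curve uses the step-wise achievable-points
convention (linear interpolation in PR space is known to flatter a
classifier). PR is preferred when true negatives vastly outnumber
positives, which is exactly the small-`s0` regime of interest.

## Problem sizes and numerical tolerances

The test suite exercises calibration at $m = 10{,}000$ genes: 50
uniform-null replicates for the census (mean $N'(t)\,t$ within three
binomial standard errors of $m t^2$), and three simulation replicates per
DEG proportion $s_0 \in \{0.001, 0.005, 0.02\}$ for the power ordering
(parallel-negative EDR above Bonferroni everywhere; family-wise powers
flat in $s_0$; BH rising with $s_0$). These sizes give stable averages
while keeping the default suite fast on a laptop. Worked-table
reproduction is asserted to $5\times 10^{-7}$ absolute — the published
inputs are printed rounded to 6–8 decimals, so tighter agreement is not
meaningful.

## Known limitations

* The parallel census assumes approximately uniform null p-values;
  heavily discrete tests (small permutation sets) or strong dependence
  bend the far tail and bias $N'$.
* $\sigma_i$ is undefined at $f_i = 1$ and very aggressive just above it;
  the package maps that whole regime to EDR 1 rather than estimating a
  smooth penalty.
* The global rate $\mathrm{EDR}(t)$ is a ratio of two small counts at
  stringent $t$ and is reported uncapped and unsmoothed; per-gene EDR is
  the recommended quantity.
* Missing values are rejected, not imputed; probe-level condensation and
  normalization are upstream of this package.
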