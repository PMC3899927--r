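---
title: "Fold change rank ordering statistics: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fold change rank ordering statistics: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Given log2 expression values for $n$ genes in $m_1$ control and $m_2$ test
samples, we want to identify differentially expressed (DE) genes. Variance
based tests (the t-test family) can assign tiny p-values to genes whose fold
change is negligible but whose variance happens to be small, and large
p-values to genes with a large fold change and large variance; fold-change
based selections are more reproducible across platforms but classically come
without an error statement. FCROS (fold change rank ordering statistics)
keeps the fold change as the effect measure while attaching a probability to
each gene, and it does so with a single global model, so no per-gene
multiple-testing correction enters.

## The model

For $k \le m_1 m_2$ pairwise control/test sample comparisons we compute the
per-gene log2 fold change (the difference of log2 values), sort each
comparison's $n$ fold changes in increasing order, and record each gene's
rank, with ties getting midranks so every comparison's ranks sum to
$n(n+1)/2$. Gene $i$ thus has a vector $r_i$ of $k$ ranks. Its summary is a
trimmed mean: sort the $k$ ranks, drop $\lfloor k \cdot trim \rfloor$ from
each end, average the rest and divide by $n$, yielding the standardized
average of ranks $\bar r_i \in (0, 1]$.

If the ordered $\bar r_i$ were an equally spaced grid from $a$ to $b$ with
gap $\delta$, their population mean and variance would be $(a+b)/2$ and
$(n^2-1)\delta^2/12$, and as $k$ grows the central limit theorem makes the
ordered averages of ranks approximately normal. The fitted model therefore
takes the sample mean $\bar R$ and sample variance $\hat\sigma^2_R$ (divisor
$n-1$) of the $\bar r_i$ and assigns each gene the probability

$$f_i = \Phi\!\left(\frac{\bar r_i - \bar R}{\hat\sigma_R}\right),$$

its *f-value*: near 0 for down-regulated genes, near 0.5 for unchanged
genes, near 1 for up-regulated genes. Selection uses two thresholds
$0 < \alpha_1 < \alpha_2 < 1$ (down: $f \le \alpha_1$; up:
$f \ge \alpha_2$), and the expected error of the combined DE list is
$100(\alpha_1 + 1 - \alpha_2)$ percent — a single, analytic error statement
for the whole list.

The gap estimate $\hat\delta$ is the mean of consecutive differences of the
sorted $\bar r_i$, which telescopes to $(b-a)/(n-1)$ exactly; `fcrank`
stores it on the standardized scale and `summary()` also reports
$n\hat\delta$, the conventional diagnostic: values near 1 indicate the rank
means span nearly the whole ideal range (informative data), values drifting
toward 0.6–0.7 indicate rank instability, which is what randomized group
labels produce.

## Parameters

* `trim` (default 0.3): fraction of a gene's sorted ranks removed from
  *each* end before averaging, so `trim = 0.1` keeps 80% of the ranks.
  Trimming protects the rank mean from outlier samples. The default is the
  setting used throughout the method's published evaluations; with few
  comparisons (small $k$) the cut is $\lfloor k \cdot trim\rfloor$ and may
  be zero.
* `k` (default `"all"`): number of pairwise comparisons. More comparisons
  improve the normal approximation; the full $m_1 m_2$ grid is the default.
  When $k < m_1 m_2$ the first $k$ pairs of the deterministic control-major
  enumeration are used — the published procedure does not fix which pairs
  to take, and a canonical prefix keeps runs reproducible.
* `alpha1`, `alpha2` (defaults 0.025, 0.975): selection tails, chosen by
  the user against the acceptable list error $100(\alpha_1+1-\alpha_2)$.

## Numerical and design choices

* **Ties** get midranks — the unique symmetric scheme that preserves the
  column rank sum, which the rank-conservation invariant tests directly.
* **Sample vs theoretical moments.** The normal model could use the
  theoretical moments of the equally spaced grid; we follow the algorithm's
  prescription and use the sample moments of the observed $\bar r_i$, with
  the theoretical values exposed as diagnostics via
  `theoretical_moments()`. For well-behaved data the two converge (the
  sample variance of an exact grid exceeds the population form by the
  factor $n/(n-1)$).
* **Standardization.** Ranks are divided by $n$ before moment fitting, so
  all reported model parameters live on the $(0,1]$ scale.
* **Fold change report.** For one-color (log2-intensity) data the reported
  fold change is the ratio of arithmetic means of unlogged values, the
  classical definition (validated against a published two-gene worked
  example bundled as `two_gene_example()`); `fc.method = "geometric"` gives
  $2^{\overline{\Delta\log_2}}$ instead. For two-color (log2-ratio) data
  absolute intensities do not exist, so the geometric form is always used.
  Ranks — and therefore f-values — are identical under either choice.
* **Degenerate input.** If all rank means coincide the model variance is 0
  and f-values are undefined; `fit_rank_model()` raises an explicit error
  rather than returning NaN.
* **Extreme f-values** are clamped into the open interval $(0,1)$ at the
  floating-point boundary so downstream `log`/threshold arithmetic stays
  finite.
* **Two batches.** `fcros2()` forms pairwise comparisons within each batch
  only ($k = k_1 + k_2$ columns) and pools the rank matrix; since ranks are
  invariant to any batch-wide monotone shift, batch biases cancel with no
  inter-batch normalization. Its reported fold change is the geometric mean
  of the per-batch fold changes, because a cross-batch ratio of unlogged
  means would absorb the batch offset.

## The simulator

`simulate_dataset()` emulates a two-condition microarray simulation study:
uniform baselines on [4, 14] log2 units, a planted fraction `p_de` (default
0.02) of DE genes with signed |log2 FC| uniform in [0.6, 3] (up with
probability 0.5) added to the test group, and i.i.d. Gaussian noise of
standard deviation `sigma_n` on every observation. Defaults are the common
study design ($n = 10{,}000$, $m_1 = m_2 = 7$, an expected 200 DE genes);
`sigma_n` defaults to 0.4, the middle of the 0.2–0.6 range the noise
robustness analyses explore. The seed is a mandatory argument and the
caller's RNG stream is restored afterwards.

What it does *not* emulate: intensity-dependent variance (no
mean–variance trend), probe-level effects, correlated samples, or
non-uniform baseline shape. Passing recovery tests on these simulations
therefore demonstrate correctness of the statistic and its implementation
under additive Gaussian noise, not performance on any particular real
platform; the subsampling machinery in `subsample_score()` exists precisely
so users can measure stability on their own real data.

Test and acceptance problem sizes are deliberately modest — recovery is
checked at $n = 2000$ genes, $7+7$ samples, 10 seeds per noise level, where
the rank statistic's behaviour is already asymptotic for practical
purposes — keeping the default suite fast while exercising every code path
at realistic shapes.

## Evaluation protocols

* `confusion_counts()` — 2x2 counts of a selection against ground truth.
* `rank_auc()` — Mann–Whitney AUC with midrank ties: the probability that a
  true DE gene outranks a non-DE gene under the method's two-sided DE
  ordering. For f-values that ordering is $|f - 0.5|$ (`de_score()`),
  since a single ranking must merge the down and up tails.
* `subsample_score()` — the stability protocol: repeatedly subsample
  $m_1' + m_2'$ samples, select the top-$N$ genes, accumulate 0/1 scores
  per gene over runs. With `randomize_groups = TRUE` samples are drawn
  ignoring the biological groups, the null calibration whose maximum score
  suggests a dataset-specific threshold; the thresholds are deliberately
  user parameters, not constants, because they are data-derived.
  Ties in the top-$N$ cut are broken by gene order for determinism.
* `reproducibility_counts()` — the number of genes at or above given score
  thresholds (e.g. perfect 100, good >= 90).

## Known limitations

* The normal approximation needs a reasonable number of comparisons;
  with $m_1 = m_2 = 2$ and `trim = 0.3` a gene's rank mean rests on 4
  ranks and f-values get granular.
* FCROS orders genes by rank consistency, not effect size; users wanting a
  minimum fold change should filter the reported `fold_change` column in
  addition to the f-value tails.
* The error statement $100(\alpha_1+1-\alpha_2)$ is an expectation under
  the fitted global model, not a per-gene FDR; no BH/Bonferroni layer is
  provided, by design.

## A worked run

```{r, eval = FALSE}
library(fcrank)
sim <- simulate_dataset(n = 2000, m1 = 7, m2 = 7, p_de = 0.02,
                        sigma_n = 0.2, seed = 11)
fit <- fcros(sim$data)
summary(fit)
rank_auc(de_score(coef(fit)), seq_len(2000) %in% sim$de_indices)
```
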