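---
title: "Heterogeneity-aware outlier detection and consensus pathway analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterogeneity-aware outlier detection and consensus pathway analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(outlierDE)
```

## The model

Tumour cohorts are heterogeneous: an oncogenic feature is often shifted in
only a subpopulation of the tumour samples. Write the per-feature data as
control values $x_1,\dots,x_{n_1}$ and case values $y_1,\dots,y_{n_2}$ on
the log scale. The implicit data model is

$$ x_i \sim F, \qquad
   y_j \sim \begin{cases} F + \mu & j \in S \\ F & j \notin S \end{cases} $$

with an unknown shifted subset $S$ of size $\pi n_2$. When $\pi \ll 1$, the
mean difference underlying the t statistic is $\pi\mu$, while the tail of
the tumour distribution still moves by the full $\mu$ — which is why the
five outlier statistics (COPA, OS, ORT, MOST, LSOSS) examine the tumour
tail. Their precise definitions are in the help pages (`?copa_stat` etc.);
the numerical conventions they share are fixed below.

## Numerical conventions

* **Quantiles** are linearly interpolated between order statistics at
  1-based position $1 + (n-1)p$ (R's `type = 7`). The OS/ORT cutoff
  `q75 + IQR` depends on this choice, so it is fixed package-wide.
* **Robust scale** is the scaled MAD, $1.4826 \times
  \mathrm{median}|v - \mathrm{median}(v)|$ (normal-consistent). A feature
  whose MAD is zero falls back to $1.4826 \times \mathrm{mean}|v -
  \mathrm{median}(v)|$; if that is also zero the feature is flagged
  *degenerate* and scored 0 rather than producing infinities. Degenerate
  features are excluded from top-quantile selection (only for the method
  that flagged them).
* **Outlier membership** in OS/ORT uses strict inequality at the cutoff:
  ties at the cutoff are excluded.
* **LSOSS ties**: if several split positions attain the minimal
  within-subset sum of squares, the smallest $k$ is taken; the pooled
  variance uses $n_1 + n_2 - 3$ degrees of freedom, matching the
  two-means-within-tumour model (three fitted means overall).
* **MOST moments**: the null mean and SD of the sum of the $k$ largest of
  $n_2$ standard normals are estimated once by Monte Carlo
  (`precompute_order_moments()`, $B = 10{,}000$ by default, internal fixed
  seed) and cached; the caller's RNG stream is never disturbed, so
  pipeline results do not depend on evaluation order.
* **Direction**: the five outlier statistics are one-sided. By default
  (`direction_mode = "both"`) each is also evaluated on the negated matrix
  and, per feature, the direction with the larger score magnitude wins;
  down-direction scores are stored negative. Negating the matrix rather
  than mirroring each formula keeps a single code path that is symmetric
  by construction.

## Selection, consensus and ranking

Selection takes the top $\lceil q m \rceil$ features by $|score|$
($q = 0.05$ by default), not the features above the 95th percentile score
value: the count form guarantees equal-size, comparable selections across
methods and differs only at ties, which are broken by feature id for
determinism. Features selected by at least `k_methods = 3` of the methods
are *putative outliers*, and a method's *accuracy* is the percentage of its
selections that are putative — its agreement with the ensemble. Methods are
ranked by median accuracy across datasets, ties by smaller SD, then name;
median-first is a deliberate choice where the ordering between the two
criteria is otherwise open, and both values are reported in the ranking
table.

The best method's per-dataset selections feed the downstream stages. Two
cross-dataset consensus levels exist because they answer different
questions: the default **gene level** collects each dataset's target genes
(union over its selected miRNAs) and keeps genes present in at least
`k_datasets = 3` of them; the **miRNA level** intersects the selections
first (features shared by at least 3 datasets) and then maps to targets.
Gene-level is the default because partially overlapping probe panels make
miRNA-level agreement much rarer than functional (target-level) agreement;
the multiplicity report always satisfies the additivity
$|\{\ge k\}| = \sum_{j \ge k} |\{= j\}|$.

## Target maps and enrichment

Target prediction itself is out of scope: prediction tools' outputs are
consumed as two-column tables. `intersect_predictions()` keeps the pairs
present in *every* table — a high-precision, lower-recall consensus — and
`augment_target_map()` applies the hybrid rule: a primary (database) map
where available, the predictors' intersection for miRNAs the primary map
does not cover.

Enrichment is the standard upper-tail hypergeometric test
$P(X \ge k)$ (including $k$), with Benjamini–Hochberg step-up FDR. The
default threshold is 0.001 applied to the FDR; `threshold_type = "p"`
applies it to the raw p value instead (the convention differs between
pathway databases' reports). The gene universe defaults to the collection's
universe intersected with the genes reachable from the target map — the
background an enrichment server would implicitly use — and is configurable
because universe choice is the single most result-changing convention in
over-representation analysis.

## What the simulator emulates — and what it does not

`simulation_config()` defaults describe a four-platform miRNA cohort
collection: group sizes 16/60, 12/12, 28/113 and 20/20; 400 probes per
panel (the real platforms carry 373–847); pairwise panel overlap in
40–60%, realised by drawing each panel as a shared core plus a private
block (overlap $= |A \cap B| / \min(|A|,|B|)$ is then exactly the
mid-range by construction); baseline log-expression iid
$\mathcal N(0, \sigma^2)$ with $\sigma = 1$; 5% of features DE, each
shifted by $\mu = 2$ in a fraction $\pi = 0.2$ of tumour samples
($\max(1, \mathrm{round}(\pi n_2))$ samples, so tiny groups never get an
empty outlier set); DE directions split 50/50 up/down; half of each
panel's DE features drawn from a common cross-dataset core. Scenario-level
ground truth plants 4 true pathways among 20 gene sets of 60 genes over a
2000-gene universe; shared-DE miRNAs draw 30 targets with 80% purity from
the true-pathway union, all other miRNAs uniformly.

A mean-zero Gaussian baseline is a modelling choice, not an empirical
claim: the statistics are location/scale-based, so a realistic baseline
mean would only shift all scores identically. The simulator deliberately
omits probe effects, batch effects, normalization artefacts,
platform-specific dynamic ranges and correlated features. Passing tests
therefore demonstrate *algorithmic* correctness and the expected *relative*
power ordering under subset shifts — not performance on any particular real
cohort.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` use: 200 random small features
(3–12 samples per group) for oracle equivalence; 20 replicates of
$25+25$ samples $\times$ 1000 features (10% DE, $\pi = 0.2$, $\mu = 2$) for
the power comparison, plus the homogeneous case $\pi = 1$; 20 four-dataset
scenario replicates for method ranking; and 10 strong-signal scenario
replicates ($\mu = 3$, $\pi = 0.3$) for end-to-end pathway recovery. These
sizes give stable averages (binomial SE on a recall percentage is under 2
points at these counts) while keeping a full run in minutes on one CPU.

## Known limitations

* Scores are reported without p values or permutation nulls — selection is
  by quantile rank, matching the consensus framework, so score magnitudes
  are comparable within a method but not across methods.
* COPA and OS standardize by the *overall* median and MAD; when $\pi \to 1$
  the shift inflates both and their power collapses (visible in the
  homogeneous power check). ORT/MOST/LSOSS use group-aware scales and do
  not share this failure mode; this is a property of the original
  definitions, not a defect of the implementation.
* The consensus "accuracy" rewards agreement with the method ensemble; a
  method that alone found a true signal class would be penalised. It is an
  evaluation heuristic for method *selection*, not a validity measure.
* Cross-platform probe harmonisation is the caller's responsibility:
  features are matched by shared global identifiers, and identifiers
  private to one dataset (reported with a warning for file inputs) can
  never reach the cross-dataset consensus.
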