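---
title: "Methods: disease-guided discriminative gene signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disease-guided discriminative gene signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosig)
```

## Overview and assumptions

`dosig` searches for a small gene set that separates tumor from normal
samples in a *normalized* expression matrix. It assumes inputs are already
normalized (FPKM/RPKM-like linear values, or log2 values declared as
such); raw sequencing counts are out of scope — count noise calls for
negative-binomial models, not the rank/z statistics used here. The value
scale is declared by the user and never inferred, since a silently wrong
guess would corrupt every log2 fold change downstream.

The pipeline is a chain of four filters. Each is useful on its own; their
composition is the point: statistical evidence (stage 1), biological
anchoring (stage 2), multivariate parsimony (stage 3), and an explicit
predictive acceptance gate (stage 4).

## Stage 1: normality-gated differential expression

For each gene the two class vectors are tested with the Anderson–Darling
statistic (composite hypothesis, small-sample correction
$A^{*} = A^2(1 + 0.75/n + 2.25/n^2)$, case-based exponential p-value
approximation). When **both** classes are accepted as normal at level
0.05 and both have at least 8 samples, a two-sample z-test with plug-in
variances is used; otherwise the Mann–Whitney U test (exact when the
pooled size is ≤ 16 without ties, else tie-corrected normal approximation
with continuity correction). Requiring *both* classes to pass is the
conservative reading of a "U test or z-test" choice: any doubt routes to
the nonparametric branch. Samples of fewer than 8 values cannot be
assessed by the normality approximation at all, which is why the gate has
a hard size floor.

P-values are BH-adjusted across all genes. A gene qualifies with adjusted
p < `p_cut` (default 0.05) **and** $|\log_2 FC| \ge$ `fc_cut` (default
1.5). On the linear scale the fold change uses a pseudo-count
$\varepsilon = 0.25$ in both numerator and denominator so that zero means
do not produce infinities; 0.25 is small relative to typical FPKM
baselines yet keeps $\log_2$ bounded. The qualifying list is ranked by
adjusted p (ties: larger $|\log_2 FC|$, then gene id — fully
deterministic) and truncated to the input size `n_input` across both
directions combined; ranking by the significance criterion itself keeps
the truncation consistent with the selection rule. A per-direction
truncation would be an equally defensible reading; the combined list is
the default because nothing in the method requires balanced up/down
counts.

## Stage 2: disease-term over-representation filter

The DEG list is tested term-by-term against a disease→gene annotation map
with the one-sided hypergeometric upper tail
$P(X \ge k)$, BH-adjusted over all tested terms. Only DEGs carried by at
least one term with adjusted p < 0.05 continue. Choices a user should
know:

* **Universe.** Default is the intersection of dataset genes and
  annotated genes. An over-representation background must contain only
  genes that *could* have been in the query; unmeasured annotated genes
  inflate significance. `universe_mode = "annotated"` is available for
  compatibility with tools that test against the full annotation.
* **Propagation.** `is_a` ancestor propagation (each term inherits its
  descendants' genes) is off by default — curated annotation releases are
  usually already propagated — and can be switched on when the map is a
  raw direct-annotation export.
* **Minimum term size 2.** Singleton terms cannot be meaningfully
  over-represented and only inflate the BH correction burden.

## Stage 3: Wilks' lambda stepwise selection with niveau trimming

For a candidate matrix $X$ (samples × features) and two groups, Wilks'
lambda is $\Lambda = \det(W)/\det(W+B)$ with $W$ the pooled within-group
and $B$ the between-group cross-product; small $\Lambda$ means strong
separation. Greedy forward selection enters, at each step, the candidate
minimizing the overall $\Lambda$; the entry is tested by the partial-F
statistic
$F = \frac{1-\Lambda_p}{\Lambda_p}\cdot\frac{N-g-p+1}{g-1}$, with
$\Lambda_p$ the ratio of new to old $\Lambda$. Entry stops when the best
candidate's p exceeds the niveau, when the residual degrees of freedom
run out, or when candidates are exhausted.

The trimming loop starts at niveau 0.1 and lowers it by 0.01 per
iteration (at most six iterations, floor 0.05) until every entered
feature's inclusion p is ≤ 0.05. An arithmetic schedule was chosen for
transparency and a bounded iteration count; the wording "automatically
reduced" admits other schedules, and the step is configurable. Since
entry already requires p ≤ niveau, the floor pass always terminates the
loop. We implement reduce-and-reselect (rerunning selection at the lower
niveau) rather than post-hoc filtering of the entered set, because
deleting a feature invalidates the conditional p-values of every feature
entered after it.

Numerical details: $\Lambda$ is computed from log-determinants;
candidates whose addition makes $W$ numerically singular (collinear
features, constant genes) are skipped with a warning rather than aborting
the run; ties at equal $\Lambda$ resolve by larger partial F, then
lexicographic gene id, so reruns are identical. Only two-group problems
are supported.

A caveat the tests document: with a large pool of pure-noise candidates,
each entry step tests the *minimum* p over all remaining candidates, so
some noise feature clears the 0.05 entry level with probability about
$1 - 0.95^{m}$ for $m$ remaining nulls. Stepwise selection therefore
cannot by itself deliver a noise-free set from dozens of null candidates;
in the pipeline the enrichment filter shrinks the pool first, which is
where signature precision comes from.

## Stage 4: RBF-SVM acceptance gate

Samples are split per class with `round(0.8 · class size)` into training
and test. On the training set, gamma (one point per decade over
$10^{-6}..10^{6}$) and cost ($10^{-5}..10^{5}$) are tuned by stratified
10-fold cross-validation; ties go to the smaller cost, then the smaller
gamma (preferring the smoother model). Features are standardized with
training-set mean/SD before the RBF kernel — on FPKM scales the kernel
distance is otherwise dominated by the single highest-expressed gene.
The held-out confusion matrix (tumor = positive) must clear kappa > 0.80,
specificity > 0.80, and an exact one-sided binomial test of accuracy
against the no-information rate at p < 0.05. ROC-AUC is computed by the
midrank (Mann–Whitney) formulation on signed decision values — no
probability calibration — and the PCA diagnostic reports the variance
fraction captured by the top components (gate at 80%). A failing gate
does not abort the pipeline; the signature and its report are returned
with `accepted = FALSE` so the user can inspect why.

All randomness (split, fold assignment) derives from the single
configuration seed through a fixed linear-congruential step, so one
integer reproduces the entire run; the RNG state of the calling session
is saved and restored around every internal draw.

## Prognostic screen

Each signature gene is screened individually: samples with survival
records are split at the median expression (ties at the median go to
"low"), the two groups are compared by the log-rank test (hypergeometric
variance at each distinct event time; events precede censorings at tied
times), and the hazard ratio is the Pike estimator
$(O_{hi}/E_{hi})/(O_{lo}/E_{lo})$. The Pike ratio was preferred to a Cox
fit because it is closed-form, iteration-free, and adequate for a
screening read-out; a Cox option is future work. Genes whose split
leaves fewer than two samples on a side are skipped with a warning.
"Prognostic index" dichotomization for single genes is under-specified in
general; the median split is the standard convention for Kaplan–Meier
gene screens and the quantile is the natural extension point.

## What the synthetic generator emulates — and what it does not

`generate_fixture()` draws per-gene baselines from Uniform(3, 8) on the
log2 scale and adds Normal noise (SD 0.5 by default), exponentiating for
linear output — a log-normal expression model matching the positive skew
of FPKM-like data. Planted differential genes receive a ±2 log2 shift in
tumor samples (alternating sign, so both directions occur). One
annotation term covers 80% of the planted genes plus ~2% background
genes; remaining terms are random draws. Survival times are exponential
with log2-hazard linear in the standardized expression of one designated
planted gene (slope 0.625 ≈ two-fold rate ratio between median-split
halves, the canonical power scenario for a log-rank screen), with
independent exponential censoring targeting a 30% censor fraction.

The defaults (1000 genes, 30+30 samples, 15 planted genes, shift 2.0,
noise 0.5) constitute the reference study condition of the test suite.
Real data differ in ways the generator deliberately ignores: gene–gene
correlation, batch and platform effects, count-level sequencing noise,
annotation redundancy across related disease terms, and non-proportional
hazards. Passing tests therefore demonstrate correctness of the
machinery and calibration under the model's assumptions — not performance
on any particular cohort.

Problem sizes in the suite (20 pipeline seeds at the reference condition,
50 screening seeds at 200 survival subjects, 1000–1200 genes in the null
calibrations) were chosen as the smallest sizes at which the binomial
noise bands around the checked rates are informative.

## Known limitations

* Two classes only; no multi-class discriminant extension.
* No class-imbalance correction beyond stratified splitting; heavily
  imbalanced cohorts will inflate the no-information rate and make the
  binomial gate the binding constraint.
* The BH q-value is not idempotent (re-adjusting adjusted p-values can
  inflate plateaus); downstream code treats adjusted values as final and
  never re-adjusts.
* The z-branch uses plug-in variances (a true z-test, not Welch's t);
  with class sizes near the gate floor of 8 it is mildly anti-conservative,
  which the calibration tests bound.
* Survival screening is univariate; no multivariable or time-dependent
  modeling.
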