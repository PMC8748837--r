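---
title: "Interpretable cross-study classification of gut metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable cross-study classification of gut metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microebm)
```

## Scope and model

`microebm` classifies colorectal-cancer status from per-sample abundance
profiles of gut metagenomes and, more importantly, audits the
*explanations* that classifier produces: which features it selects, how it
ranks them, how stable both are under resampling, and whether the learned
probability behaves like a risk score on lesion stages it never saw during
training.

The classifier is a generalized additive model on the logit link,
$\mathrm{logit}\,P(\mathrm{crc}\mid x) = \beta_0 + \sum_i f_i(x_i)$, with
each shape function $f_i$ learned by cyclic gradient boosting — an
explainable boosting machine. Because the pipeline discretizes features
before the model (equal-frequency bins), the per-feature weak learner of
each boosting step reduces exactly to a depth-1 regressor on a categorical:
the per-bin mean of the current log-loss gradient residuals $(y - p)$. One
epoch visits every feature once; each fit is shrunk by the learning rate
and folded into the running scores before the next feature is visited, so
every learner sees the current model. After training, each graph is
re-centered to zero training-distribution-weighted mean (shifts move into
$\beta_0$), which makes the global relevance scores — mean absolute local
attribution over the training set — comparable across features.

Properties that follow by construction, and that the test suite asserts:

* the additive decomposition is exact to machine precision
  (`logit = β₀ + Σ contributions`);
* in the single-feature limit the graph converges to the per-bin empirical
  log-odds (the closed-form MLE);
* duplicated (perfectly collinear) features receive near-identical graphs,
  because the round-robin cycling at a small rate splits the residual
  between them symmetrically.

## Pipeline stages and their parameters

| stage | default | notes |
|---|---|---|
| transform | `log(1+x)` | abundances are nonnegative; tames skew |
| selection | ANOVA F + BH FDR, α = 0.05 | per-feature one-way F by explicit sums of squares; constant features get p = 1 |
| discretization | 2 bins (taxonomic), 20 (functional) | training-quantile edges; tied quantiles collapse; out-of-range values clamp to the terminal bins; a value equal to an edge goes to the upper bin |
| EBM | learning rate 0.01, 2000 epochs, no bagging | bagging available (`n_bags`); the positive class is always `crc` |

The learning rate and epoch count were chosen for desk-scale convergence
of the per-bin log-odds limit (the error of the single-feature fixed point
contracts roughly like $e^{-\eta\,\bar{p}(1-\bar{p})\,T}$, which at
$\eta = 0.01$ needs a few thousand epochs); both are configurable.

Two deliberate policy choices:

* **Empty selection.** If no feature survives FDR the pipeline *raises*
  rather than silently falling back, because a silent fallback would
  corrupt selection-stability statistics. Evaluation drivers that must
  produce a prediction for every fold can opt in to the fallback
  explicitly with `on_empty = "all"`.
* **o-LOPO.** The out-of-training feature mask (computed on the pooled
  projects or supplied as a consensus-signature support) is an intentional,
  documented information leak that exists to make the model comparable to
  reference meta-analysis methodology; `olopo()` never recomputes selection
  inside the loop.

## Stability estimators

**Selection stability.** Selected-feature subsets across $M$ resampling
splits form a binary matrix $Z$; the stability score is
$\hat S = 1 - \overline{s_f^2} \,/\, (\bar k/d)(1-\bar k/d)$ with
$s_f^2 = \frac{M}{M-1}\hat p_f(1-\hat p_f)$. It is 1 for identical subsets
and 0 at the level of random guessing; 0.4 and 0.7 are the conventional
"bad" / "near perfect" reporting thresholds. The confidence interval uses
the estimator's asymptotic normality with influence terms
$\phi_i = \frac1v\left(\tfrac1d\sum_f z_{if}\hat p_f - \tfrac{k_i\bar k}{d^2}
+ \tfrac{\hat S}{2}\big(\tfrac{2k_i\bar k}{d^2} - \tfrac{k_i}{d} -
\tfrac{\bar k}{d} + 1\big)\right)$ and
$\widehat{\mathrm{Var}} = \tfrac{4}{M^2}\sum_i(\phi_i-\bar\phi)^2$.
The score is undefined (an explicit error) when every split selects
nothing or everything.

**Rank stability.** Pairs of per-split relevance vectors are compared with
the hyperbolic-weighted Kendall tau: each item pair is weighted additively
by $w(r) = 1/(1+r)$ of the items' 0-based ranks, so disagreements near the
top of the ranking cost more. Conventions chosen here (the statistic's tie
handling is not canonical, so they are stated explicitly): ranks are
midranks in decreasing order, tied items take the weight of their average
rank; the statistic is symmetrized by averaging over which of the two
vectors supplies the weights; normalization is tau-b style, so
self-comparison is exactly 1 and exact reversal exactly −1. Features
removed by selection enter with relevance 0 and share the tail.

Two splitting schemas feed both estimators: RSSS (random stability
sub-sampling: 100 class-stratified half-samples) and the training sets of
a 20×10-fold stratified CV.

## Consensus signature and permutation significance

Each LOPO run contributes a relevance vector over the full feature space
(zeros for unselected features). Per run the vector is min–max rescaled to
[0, 1] — with nonnegative relevances and a typical minimum of zero this
coincides with max-division, which is why min–max was chosen as the
canonical reading. The consensus score of feature $i$ is
$\sum_{\text{runs}} \tilde r_i \,/\, (p - nz(i) + 1)$, where $p$ is the
number of projects and $nz(i)$ counts runs with strictly positive
relevance; the divisor rewards features recurring across runs. Scores
therefore range from 0 to $p$.

Significance of the validated score on the fixed signature support uses
label permutations with the add-one estimator
$p = (\#\{\text{perm} \ge \text{obs}\} + 1)/(B+1)$ — the only reading
consistent with the attainable extremes 1 and $1/101 \approx 0.0099$ at
$B = 100$. "Greater or equal" (not strictly greater) keeps the estimator
valid under ties. The score inside the test defaults to repeated k-fold CV
on the pooled samples with the feature set fixed (10×10 by default for desk
runtime; the repeat count is a parameter), with an o-LOPO-scored variant
available (`mode = "olopo"`) since the source material is ambiguous about
which of the two was rescored.

Metabolite-level scores are plain sums of the consensus scores of the KOs
a user-supplied compound→KO map assigns to each compound; KOs absent from
the signature contribute 0.

## The adenoma risk-ordering test

Non-comorbid healthy and CRC samples form the training pool, split
stratified 0.7/0.3 into learning and validation; everything else —
adenomas, small adenomas, other conditions, comorbid healthy/CRC — is the
test set. The pipeline fits on learning only; healthy and CRC probability
distributions are read from validation (unseen but in-distribution), the
lesion groups from test. Each comparison is a one-sided Mann–Whitney test
that the lesser group's predicted probabilities are stochastically
smaller; repeated over 100 re-partitions, the hit ratio is the fraction of
repeats with $p < 0.05$. The Mann–Whitney p-value is computed by exact
enumeration of group assignments for combined sizes up to 12 (exact under
ties, where the classical exact tables are not) and by the normal
approximation with tie and continuity correction otherwise.

The default comparison set follows the radar labels A<T, H<A, H<S, S<A,
H<T. The direction of the small-adenoma-versus-healthy comparison is
stated inconsistently in the source material (healthy < small adenoma
versus small adenoma < healthy), so it is an explicit argument of
`default_comparisons()` rather than a silent choice.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` draws
$a_{ij} = B_{ij}\, s\, \delta_{p(i)} \exp\big(\mu_j + b_{p(i)j} +
\log e_{c(i)j} + \varepsilon_{ij}\big)$ with feature baselines
$\mu_j \sim N(0, 1)$, project batch offsets $b \sim N(0, 0.4)$, sample
noise $\varepsilon \sim N(0, 1)$, dropout mask
$B \sim \mathrm{Bernoulli}(1 - \pi_0)$, a global abundance scale
$s = 50$, and a per-project depth factor $\delta$. Defaults (chosen once
as the package's study conditions, with the reasoning below):

* **7 projects × (25 healthy, 25 CRC, 5 adenoma, 5 small adenoma)**,
  500 features of which 30 carry signal — small enough that every
  downstream design (20×10 CV per project, LOPO, 100-repeat hit ratios)
  runs in minutes on one CPU; the test suite states these sizes where it
  uses them.
* **Abundance scale 50**: length-normalized read-count profiles live on a
  count scale, not around 1; the scale keeps `log(1+x)` in its logarithmic
  regime as on real data.
* **Dropout 0.1 (functional) / 0.25 (taxonomic)**: core gene functions are
  observed in nearly every deeply sequenced sample, whereas taxa are
  sparser. Dropout is condition-independent — presence/absence itself
  carries no signal, only intensity does.
* **Condition multipliers** 1 / 1.7 / 2.8 / 6 (healthy / small adenoma /
  adenoma / CRC) in functional mode — a conservative stand-in for the
  10–100× fold changes reported for top CRC biomarkers — and 1 / 1 / 1 / 6
  in taxonomic mode. The signal set is shared across conditions (nested
  signal), so adenoma is a weakened CRC signature: exactly the structure
  the risk-ordering test requires. Taxonomic mode instead shifts only CRC,
  reproducing the "taxa change late" contrast.
* **Low-depth cohort**: project 1 is scaled by 0.25 with dropout raised by
  0.15, emulating a shallow-sequenced study; it shows up, as intended, as
  the least stable and worst-transferring project rather than as an
  adversarial one.

Not emulated, hence not demonstrated by passing tests: compositional
(sum-to-one) coupling between features, read-level sampling noise
(the zero mask and log-normal jitter are a smooth surrogate for a negative
binomial), phylogenetic or pathway correlation between features, and
metadata heterogeneity across cohorts (inputs must already use the fixed
condition vocabulary). Conclusions about real cohorts require real
cohorts; the synthetic conditions only establish that the machinery
recovers what was planted.

## Numerical conventions and degenerate inputs

* Binary labels: `crc` = 1 everywhere; probabilities are P(crc).
* AUROC is the Mann–Whitney statistic (ties half); cells whose test
  project lacks one class are reported as `NaN`, never imputed as 0.5.
* Discretizer edges strictly increase; an edge at the training minimum is
  dropped (it would split nothing under the upper-bin tie rule), so a
  constant feature yields a single bin.
* Unseen bin indices at prediction time clamp to the nearest realized bin.
* JSON reports carry a schema version; `NaN` serializes as `null` and is
  restored as `NaN`.
* All stochastic procedures take explicit integer seeds; per-repeat seeds
  are derived additively from the base seed.

## Known limitations

The EBM here is deliberately minimal: no pairwise interaction terms, no
multiclass link, no inner bagging by default (available behind `n_bags`).
Hyperparameters of the reference EBM generation are not restated by the
source material, so the defaults are the package's own and are all
configurable. The permutation test refits the full pipeline per
permutation and is the most expensive stage at its canonical B = 100;
the `repeats` parameter of the inner CV is the intended lever for desk
runtime. Dense matrix storage bounds practical problem sizes to a few
thousand features, which matches the intended profile scale.
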