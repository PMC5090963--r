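---
title: "Ranking drug indications from chemical-protein interactome profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking drug indications from chemical-protein interactome profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpirank)
```

## The problem

A chemical-protein interactome (CPI) profile is the vector of in-silico
docking scores of one small molecule against a fixed panel of protein
structures (units kcal/mol; more negative means stronger predicted
binding).  Because therapeutic effects are often mediated by unexpected
on- and off-target binding, such a profile carries a usable signal about
which diseases a molecule might treat — and, unlike expression or
side-effect data, it can be computed for an early-pipeline candidate from
the structure alone.

`cpirank` turns a drugs-by-targets CPI score matrix plus a table of known
drug-indication pairs (ICD-9 coded) into a bank of per-disease classifiers,
and turns a new molecule's profile into a ranked, hierarchically grouped
list of candidate indications.

## Endpoints

Each classification task ("endpoint") is one binary question: does this
drug treat this ICD-9 code?  Endpoints exist at two tiers:

* **disease tier** — individual codes such as `250.10`;
* **family tier** — the 3-digit rubric obtained by truncating at the
  decimal point (`250.10 -> 250`), where a drug is positive for a family
  iff it is positive for at least one member code (union rollup).

Two filters are applied after rollup at the respective tier: families
780-999 (symptoms, injuries, poisoning) are removed, and endpoints with
fewer than `min_positives = 5` treating drugs are removed (too few
positives to learn from).  V- and E-codes are dropped by default because
the numeric range rule does not apply to them; `keep_ve = TRUE` retains
them.  The filters commute and the construction is idempotent, which the
test suite checks by property.

## The per-endpoint model

For endpoint $j$ with labels $y_{dj} \in \{0,1\}$ over drugs $d$ and
standardized features $x_d$ (per-target z-scores fitted on the training
split: docking scores share units but differ in location and spread per
target, and a penalized model needs comparable scales), we fit ridge
logistic regression

$$\min_{w_j, b_j}\; -\frac{1}{n}\sum_d \log p(y_{dj} \mid x_d)
  \;+\; \frac{1}{2\,C\,n}\lVert w_j \rVert_2^2 ,$$

with probability $p = \mathrm{logit}^{-1}(b_j + w_j^\top x_d)$.  The solver
is `glmnet` (alpha 0, a single ridge penalty, coordinate descent run to a
1e-14 convergence threshold so that symmetric inputs produce symmetric
weights).  Zero-variance features get a standard-deviation sentinel of 1
and therefore weight zero.

**Choice of the inverse penalty `C`.**  The default is `C = 0.1`.
Endpoints here are rare-event problems: with the 5-positive admission floor
and feature panels of tens to hundreds of targets, events-per-variable is
far below the classical comfort zone, and a light penalty lets noise
dominate the weights.  At the package's reference benchmark (300 drugs, 50
targets, roughly 30 positives per endpoint) `C = 0.1` gives materially
better cross-validated discrimination than `C = 1`.  `C` remains a plain
argument for users who want weaker shrinkage on richer data.

**Degenerate training splits.**  With 5-positive endpoints under 10-fold
cross-validation some training splits will hold fewer than two positives.
The model for that split degrades to predicting the training prevalence (a
constant); this is counted and reported rather than hidden.

## Cross-validation and metrics

`cross_validate()` draws, per repeat, one random drug-level partition into
`k` folds (sizes differ by at most one) shared by all endpoints.  A shared
partition is what makes pooled "global" metrics well defined: every
(drug, endpoint) cell receives exactly one out-of-fold score per repeat.
Per-endpoint stratified folds are available behind a flag.  All randomness
descends from one seed; repeat $r$ uses `seed + r`.

Three aggregation protocols are implemented:

* **global** — pool all cells into one score vector;
* **drug-centric** — per-drug metrics, averaged over drugs;
* **disease-centric** — per-endpoint metrics, averaged over endpoints.

Entity averages report mean and population standard deviation (divisor
$n$); entities whose metrics are undefined (single-class label vectors) are
skipped and counted, never imputed.

AUROC is the Mann-Whitney statistic
$P(s_+ > s_-) + \tfrac12 P(s_+ = s_-)$ computed from midranks.  AUPR is
average precision (step-wise; no trapezoidal interpolation, which is
optimistically biased).  The decision threshold for the confusion metrics
is the smallest candidate attaining the maximal F-score, candidates being
midpoints between consecutive distinct scores plus sentinels below the
minimum and above the maximum; prediction is positive at score
$\ge$ threshold, and F-ties resolve toward the smaller threshold (higher
sensitivity).  By default one global threshold is selected on the pooled
out-of-fold scores; a per-endpoint mode exists.

## Empirical-Bayes score normalization

Raw probabilities are not comparable across endpoints (each model has its
own base rate and calibration), so for ranking within one drug they are
mapped to posterior confidences.  Split a drug's endpoints into group
$G_1$ (treated) and $G_0$ (not treated); for a raw score $y_j$,

$$P(G_1 \mid y_j) = \frac{P(y_j \mid G_1)\,P(G_1)}
  {P(y_j \mid G_1)\,P(G_1) + P(y_j \mid G_0)\,P(G_0)},$$

with $P(G_1)$ the training proportion of treated endpoints and the two
conditional densities estimated from the empirical score distributions of
the groups.

Numerical and estimation choices:

* **Density estimator** — Gaussian KDE with Silverman's bandwidth
  (`bw.nrd0`).  A group with fewer than 5 samples falls back to a single
  Gaussian at the group mean with the pooled-sample bandwidth; per-drug
  $G_1$ groups are often tiny, so this small-sample policy is mandatory,
  not cosmetic.
* **Log-space evaluation** — the posterior is formed from the log
  likelihood ratio (`log f1 - log f0` via log-sum-exp).  Far outside the
  fitted support both densities underflow double precision while their
  ratio is still perfectly well defined; evaluating on the raw density
  scale would collapse extreme scores to the prior.  Densities supplied by
  the user without a log form are floored at `1e-12` before the ratio.
* **Source distributions** — for novel drugs the default is *pooled*: all
  training (drug, endpoint) score pairs split by label, prior equal to the
  pooled prevalence.  A *per-drug* mode, using only one training drug's row
  and its own prevalence, is retained for training drugs.  The package fits
  these on mean out-of-fold cross-validation scores rather than on
  in-sample scores of the final models, which would be optimistically
  shifted.

When the two density estimates agree at $y$, the posterior equals the
prior; the test suite checks this identity, a hand-computed Bayes example,
and agreement with a discrete (histogram) Bayes oracle.

## The ranked report

A new profile is scored by every disease-tier and every family-tier model
independently; the family confidence comes from the family-level model and
is never an aggregate of its members (the two tiers are trained on
different rollups of the labels and routinely disagree — the report
carries both without reconciliation).  Families are ordered by family
confidence descending, ties broken by ascending code; members within a
family likewise.  Ordering is a total order, so permuting the input never
changes the report.  `floor` and `top_n` subset the families shown.

## Structural-leakage filter

When a validation set may contain close analogues of training drugs,
`filter_leakage()` removes every validation drug whose maximum Tanimoto
similarity ($|A \cap B| / |A \cup B|$ on fingerprint bitsets) towards any
training drug strictly exceeds 0.7; a maximum of exactly 0.7 is retained.
Two empty fingerprints compare as 0 (with a warning): 0/0 is undefined and
"not similar" is the conservative reading.  The filter is
fingerprint-agnostic; the caller chooses the fingerprint type.

## The synthetic benchmark generator

Real CPI matrices and curated indication tables are large external
artifacts; the generator provides data with *known* planted structure so
every stage is testable.

Per target $t$ a baseline $\mu_t \sim U(-9, -5)$ kcal/mol (typical docking
scores for drug-like binders).  Drug $d$'s latent binding boost is
$b_{dt} \sim |N(0,1)|$ kcal/mol and the observed score is
$s_{dt} = \mu_t - b_{dt} + \varepsilon_{dt}$,
$\varepsilon \sim N(0, 0.1)$ — boosts subtract because more negative means
stronger binding, and 0.1 kcal/mol reflects the run-to-run reproducibility
of converged docking.  Each disease draws `causal_per_disease = 3` causal
targets; labels follow

$$y_{dj} \sim \mathrm{Bernoulli}\!\left(\mathrm{logit}^{-1}\!\big(
  \alpha_j + \beta \cdot \overline{z}_{dj}\big)\right),$$

where $\overline{z}_{dj}$ is the mean *standardized* boost over the causal
targets ($z = (b - \sqrt{2/\pi})/\sqrt{1 - 2/\pi}$, unit variance).
Standardizing the latent strength gives $\beta$ the usual
log-odds-per-standard-deviation reading, so `effect = 3` is a strong,
recoverable signal rather than an arbitrary rescaling of a half-normal.
$\alpha_j$ is solved by bisection on the empirical drug sample until the
expected prevalence is within $10^{-4}$ of the target (default 0.1).
Disease codes are spread one-per-family over families 100-699; an optional
decoy block adds codes in the excluded 780-999 range to exercise the
endpoint filter.

What the generator does *not* emulate: chemistry (no real molecules or
poses), correlated targets (binding boosts are independent across
targets), multi-code families (one code per family by default; family
rollup is exercised by hand-built label fixtures in the tests), label
noise in the indication table, and the heavy-tailed prevalence spectrum of
real indication data.  Passing tests on this generator demonstrate that
the machinery recovers planted linear-logistic signal; they do not certify
performance on real docking data.

## Null calibration

The null control permutes drug identities within each endpoint's label
column (`permute_labels()`), preserving every endpoint's positive count.
One subtlety drives the test design: conditional on a single fixed label
matrix, the mean pooled AUROC over repeated cross-validation runs
fluctuates a few hundredths around 0.5 from dataset-level randomness that
CV repetition cannot average away.  The calibration check therefore draws
a *fresh permutation per replicate* (20 replicates of permute-then-CV),
the standard permutation-test design, whose mean is tightly centred on
0.5.

## Problem sizes

The reference benchmark used throughout the tests and the acceptance
script is 300 drugs x 50 targets x 20 diseases at prevalence 0.1 —
large enough that every endpoint clears the 5-positive floor with ~30
positives and that pooled metrics are stable, small enough to
cross-validate in seconds.  Under these conditions the planted-signal
benchmark reaches a pooled cross-validated AUROC near 0.78-0.80, the
permutation null sits within 0.01 of 0.5, and causal targets out-weigh
non-causal targets in essentially all diseases.

## Known limitations

* The classifiers are linear in docking scores; interactions between
  targets are not modelled.
* The empirical-Bayes map is shared across endpoints (pooled mode) and is
  not constrained to be monotone; with little training data the KDE ratio
  can locally reorder raw scores.
* ICD-9 only; no ICD-10 mapping, and code meaning (descriptions) is the
  user's lookup table.
* The package consumes precomputed docking scores and fingerprints; it
  neither docks nor computes fingerprints.
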