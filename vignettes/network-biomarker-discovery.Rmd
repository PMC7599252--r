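---
title: "Network-proximity biomarker discovery: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-proximity biomarker discovery: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Drug-response biomarkers discovered by regressing patient outcomes on
whole-transcriptome features tend to be unstable: with tens of thousands of
genes and a few dozen screened samples, almost any signature can fit the
training data. `proximarker` implements a framework that constrains the
feature space *before* any response data is touched, using the topology of a
protein-protein interaction (PPI) network: only biological pathways whose
genes sit unusually close to the drug's protein targets are allowed to enter
the model. Pathway activity in pharmacogenomically screened organoids then
trains a small regression against IC50, and the resulting coefficients
transfer to patient cohorts as a predicted drug-resistance score that can be
validated against overall survival, isogenic resistant cell lines, and known
mutation biomarkers.

## The model, stage by stage

### Closest network distance and the degree-matched null

For a drug with target gene set $T$ and a pathway gene set $S$ on an
unweighted PPI network, the closest distance is

$$d_c(T, S) = \frac{1}{|T|}\sum_{t \in T} \min_{s \in S} d(s, t),$$

the average over targets of the hop count to the nearest pathway gene
(`closest_distance()`). The measure is asymmetric by design: averaging runs
over the targets only. Edge confidence scores are used solely to threshold
edges when the network is read (strictly greater than the cutoff, 700 by
default for STRING-style scores); distances are plain hop counts, because
there is no principled conversion from a confidence score to an edge length.

Raw $d_c$ values are incomparable across pathways: hub-rich gene sets are
close to everything. Significance is therefore judged against a
degree-preserving random null. Nodes are grouped into contiguous-degree bins
of at least `min_bin_size` members (`build_degree_bins()`), and each of
`n_iter` iterations replaces the union of $T$ and $S$ with one joint
degree-matched draw, computing $d_c$ on the replacement sets. The joint draw
— rather than two independent draws — is deliberate: it preserves the
overlap structure between targets and pathway. If the observed sets are
disjoint the random sets are disjoint; if a target is itself a pathway
member (contributing a zero term to $d_c$), the corresponding random gene is
shared too. Independent draws would let disjoint sets collide at random,
injecting spurious zero terms into the null and, on dense graphs, turning a
perfectly degenerate null into a noisy one.

The z-score is $z = (d_c - \mu_{null})/\sigma_{null}$, and a pathway is
*proximal* when $z \le \Phi^{-1}(\alpha)$ — at the default
$\alpha = 0.10$, the familiar $-1.2816$. The threshold is computed from the
normal quantile rather than hard-coded, so $\alpha$ is tunable; an
exact-empirical-quantile mode was considered and rejected as the default
because at 1000 iterations the 10th-percentile order statistic is noticeably
noisier than the normal approximation on the bell-shaped nulls we observe.
When the null is degenerate ($\sigma_{null} = 0$, e.g. on a complete graph)
the z-score is defined as 0 and the pathway is not proximal: a graph whose
random distances never vary carries no proximity signal.

### Pathway activity: single-sample GSEA

Gene-level expression becomes per-sample pathway activity via ssGSEA. Within
a sample, genes are ranked by expression (descending; ties broken by
descending gene label so results never depend on storage order) and given
rank values $n, n-1, \ldots, 1$. For a gene set, the enrichment score is the
sum over the ranked list of the difference between the weighted in-set
cumulative distribution (rank values raised to the conventional exponent
0.25, normalized to sum 1 over in-set genes) and the uniform out-of-set
cumulative distribution. Enrichment scores are normalized to NES by the
global ES range across the call, the common ssGSEA convention; a per-sample
normalization is available behind a flag. Because the score depends on
expression only through ranks, it is invariant to any strictly monotone
transform of a sample — the `log2(x+1)` input transform matters for
interpretability, not for the scores.

Activities (and gene-level features, where used) are z-standardized per
feature across the samples of one dataset using the population (n) standard
deviation. Population rather than sample sd makes the three-point example
`[1, 2, 3] -> [-1.2247, 0, 1.2247]` exact and matches the default of common
machine-learning scalers; every downstream consumer is either scale-free
(median split) or refit per dataset, so the choice is inert scientifically.
Organoid, patient, and cell-line matrices are standardized separately —
within-dataset standardization is the framework's entire batch-effect
handling, and deliberately so.

### Training and ranking

Organoid IC50 is regressed on the proximal pathways' activities in one
joint multivariate fit (`fit_model()`). Ridge regression is the primary
model, in the "penalty added to the Gram matrix" parametrization
$\hat\beta = (X^\top X + \alpha I)^{-1} X^\top y$ with centered data and an
always-fitted intercept; $\alpha$ is chosen over the grid 0.1 to 1.0 in
steps of 0.1 by 3-fold cross-validated mean squared error with a seeded
fold assignment. Ordinary least squares and linear-kernel support vector
regression (C = 1, default $\varepsilon$) are available as alternatives.
Features are ranked by coefficient magnitude — rank 1 is the biomarker —
with ties broken lexicographically. A per-pathway univariate mode was
considered and not implemented: the coefficient-magnitude ranking is defined
by the joint fit, and a univariate variant would answer a different question
(marginal association) while doubling the surface to validate.

IC50 enters untransformed by default; a `log10_ic50` switch exists because
real panels span decades. Out-of-sample ability is measured by
`evaluate_split()`: a 60/10/30 train/validation/test split (floor rule for
train and validation, remainder to test), $\alpha$ tuned by validation RMSE,
and the squared Pearson correlation between observed and predicted IC50 on
the test partition reported as $R^2$.

### Patient scoring and validation

A patient's predicted drug-resistance score is the sum over the top-$N$
ranked pathways of standardized patient activity times the organoid
coefficient,
$\mathrm{Score} = \sum_{p=1}^{N} \mathrm{Exp}_{p} \cdot \beta_{p}$
(default $N = 1$). Since $\beta$ maps activity to IC50, higher scores mean
predicted resistance. Each cohort is median-split: scores at or below the
median are responders. Ties at the median go to the responder class — the
split itself is standard, the tie rule is ours and documented; the midpoint
median is used and no patient is dropped. Patient activity is standardized
with patient-cohort statistics only, which affects the score scale but not
any within-cohort ordering, hence nothing downstream of the split.

Validation runs the unweighted two-group log-rank test (hypergeometric
variance, 1 df, two-sided) between responder classes on the drug-treated
cohort, and on an untreated cohort as a negative control where no
separation is expected; Kaplan-Meier curves accompany both. Events are
processed before censorings at tied times. Isogenic sensitive/resistant
cell lines are compared on the biomarker's activity with a pooled-variance
two-sample t-test, reporting which group is higher so direction can be
checked against $\mathrm{sign}(\beta)$. Concordance with a mutation
biomarker uses a one-sided Mann-Whitney U test (direction configurable for
sensitizing mutations), exact when the combined sample is at most 20 with
no ties, otherwise the tie-corrected normal approximation with continuity
correction — exactness where it is cheap, the standard approximation where
ties make exact enumeration moot.

### Bootstrap significance and robustness

The bootstrap asks whether proximity-based selection beats arbitrary
selection. Each iteration draws the same number of pathways uniformly
(without degree matching — arbitrariness is the point), retrains the
regression, and walks the coefficient ranking for the first pathway that (i)
separates survival in the treated cohort at p < 0.05 and (ii) separates the
isogenic lines at p < 0.05 in the direction consistent with its coefficient
sign. The empirical p is the fraction of iterations whose best rank is at
least as good as (numerically no larger than) the observed one; iterations
with no qualifying pathway contribute "absent" and never count. Both
criteria are applied jointly by default, with `require_isogenic = FALSE` to
relax to survival only. Zero successes are reported as "< 1/n_iter"
alongside the raw 0, since the estimator is a count over N. Note a floor
effect inherent to the design: random draws can contain the true biomarker
itself, so on a small collection the empirical p cannot fall much below
k/|collection|.

`leave_out_robustness()` enumerates all subsets with up to `k_max` organoids
removed (capped at 10,000 subsets), retrains, rescores, and reports the
fraction of subsets in which the mutation-concordance test stays
significant.

## The synthetic study generator

All inputs are generated by `simulate_scenario()` with the statistical
structure the framework assumes:

* **Network**: a 1000-node preferential-attachment graph (3 edges per new
  node), giving the heavy-tailed degree distribution that makes
  degree-matched nulls meaningful; an Erdos-Renyi alternative exists.
* **Pathways**: 50 gene sets of 10-20 genes. One planted pathway is drawn
  from within `planted_pathway_distance` (default 1) hops of the 5 drug
  targets, with one member from each target's own neighborhood so the
  closest distance is bounded by construction; the 49 decoys are drawn
  uniformly.
* **Expression**: a latent-factor model — pathway activities are i.i.d.
  standard normal per sample, a gene's latent log-expression is the sum of
  its pathways' activities plus N(0, 0.5) noise, and raw expression is
  `2^(8+z)` (FPKM-like magnitudes, strictly monotone in the latent value so
  rank-based scoring sees the factors).
* **Organoid IC50**: a latent response correlated with the planted pathway's
  activity at `biomarker_effect` (default -0.9: high activity sensitizes),
  mapped to a linear positive concentration scale (10 +/- 2 units). The
  linear scale is deliberate: the planted correlation is then realized on
  the scale the untransformed-IC50 regression is fit on, rather than being
  attenuated through an exponential link.
* **Patients**: 114 treated and 298 untreated; exponential survival with
  baseline hazard 1/365 per day, multiplied by `hazard_ratio` (default 3)
  for the resistance-direction half of the treated cohort only; untreated
  survival is independent of all activities. Censoring is independent: with
  probability `censoring_rate` (default 0.3) an observation is censored at
  a uniform time before its event. A mutation marker is drawn with
  probability `plogis(-2 + 1.5 * resistance latent)`, giving a ~15-20%
  carrier rate concentrated among predicted-resistant patients.
* **Isogenic lines**: 3 sensitive vs 9 resistant; resistant lines shift the
  planted pathway's member genes by `isogenic_shift_sd` (default 2) standard
  deviations in the resistance direction.

All generators derive independent sub-seeds from one master seed and are
bit-reproducible. What the generator does *not* emulate: real microarray or
RNA-seq noise spectra, batch structure beyond what per-dataset
standardization absorbs, gene-length or GC biases, correlated pathway
memberships from shared biology, or informative censoring. Passing tests
therefore demonstrate that the pipeline recovers the signal it is designed
to detect under its own modeling assumptions — not that those assumptions
hold for any particular real dataset.

## Numerical choices and degenerate inputs

* Edge threshold is strict (`score > cutoff`); self-loops are dropped and
  symmetric duplicates collapsed on read.
* Largest-component ties break by the lexicographically smallest member
  node; real interactomes have a unique giant component, so this only
  matters on toy graphs.
* `min_bin_size` defaults to 100, lowered to `max(3, n/10)` below 1000
  nodes so small graphs still bin; a final undersized bin merges into its
  predecessor. Degree-matched draws are without replacement within a draw;
  requesting more genes than a bin holds is an error that names the remedy.
* Constant expression rows are dropped (with a warning) before
  standardization; rows with missing values are dropped at load time with a
  count. Constant-zero samples and single-column matrices are errors.
* All tie-breaks (expression ranks, coefficient ranks, centrality top-k)
  are lexicographic and therefore deterministic.
* An all-identical score vector cannot be median-split and errors rather
  than silently assigning everyone to one class; a cohort with no events
  makes the log-rank test error rather than return a number.

## Problem sizes in the shipped test suite

The suite exercises the full default scenario (1000 genes, 50 pathways, 20
organoids, effect -0.9) across 100 simulated studies for end-to-end
recovery, with 200 proximity-null iterations per pathway — at the observed
planted-pathway z-scores of -2 to -7, the null moments are already stable
well below the 1000-iteration production default. Calibration suites use
1000 draws for the proximity self-null, 1000 replicates for log-rank type-I
error, and 120 repetitions of a 120-iteration bootstrap for the self-null
uniformity check, the latter under the survival-only criterion because the
joint criterion concentrates the null almost entirely on "no predictive
pathway", leaving no support on which uniformity could be observed. The
uniformity tolerance (0.25 on the sup-distance over the attainable support)
pre-combines the two stacked empirical-CDF errors at their ~1% KS bounds.

## Known limitations

* Distances ignore edge weights; a confidence-weighted variant is
  deliberately out of scope.
* Only the closest-distance proximity measure is implemented; shortest,
  kernel, and centre variants from the proximity literature are not.
* The score-based stratification is a binary median split; no
  continuous-risk survival modeling (e.g. Cox on the score) is provided.
* The bootstrap's empirical p is floored by the biomarker-redraw
  probability on small collections, as noted above.
* ssGSEA normalization conventions differ between implementations; the
  cross-check in the test suite is a rank correlation against an
  independent reference, not value equality.
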