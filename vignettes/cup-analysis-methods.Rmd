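---
title: "Methods: tissue-of-origin classification and outlier analysis for CUP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-of-origin classification and outlier analysis for CUP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuporigin)
```

## The problem

A cancer of unknown primary (CUP) is a biopsy-proven metastasis whose
primary site cannot be established by conventional diagnostic work-up.
Expression profiling offers two complementary handles on such tumours: a
multi-class classifier that predicts the most likely tissue of origin, and a
density-based *outlier score* that quantifies how unlike every known tumour
class the sample is. Around these, this package implements the downstream
questions a CUP study asks: what distinguishes CUPs from metastases of known
origin (MOKO) transcriptionally, which gene sets those differences enrich,
and whether CUPs carry an elevated chromosomal-instability (CIN) signature
that correlates with their outlier behaviour.

## The model

### Gaussian discriminant classification

The classifier models the class-conditional density of an expression vector
$x$ (log2 scale, RMA-like normalization) as Gaussian, $p(x \mid c) =
\mathcal N(x; \mu_c, \Sigma_c)$, fitted by maximum likelihood per class,
with class priors $\pi_c$ equal to the class frequencies. Prediction is
Bayes' theorem:

$$p(c \mid x) = \frac{p(x \mid c)\,\pi_c}{p(x)}, \qquad
  p(x) = \sum_c p(x \mid c)\,\pi_c .$$

LDA shares one covariance across classes; QDA fits one per class. With
hundreds of probes and a few dozen samples per class, a full per-class
covariance is singular, so the default covariance is **diagonal**
(probe-wise variances, pooled for LDA, per class for QDA) with a variance
floor `eps = 1e-6`; a full covariance with shrinkage toward a scaled
identity (`lambda`, default 0.1) is available for low-dimensional use. All
density arithmetic is carried out in log space — at several hundred
features the densities themselves underflow double precision.

For sex-informative predictions, the priors of classes that cannot occur in
the patient's sex (ovary, cervix, prostate in the conventional map) are set
to zero and the remainder renormalized; the posterior over the allowed
classes is then exactly the conditional renormalization of the unmasked
posterior.

### Feature selection and cross-validation

Probes are selected by the one-way ANOVA F test across classes. The p-value
cut-off is chosen by a grid search (default grid $10^{-2}, \dots,
10^{-12}$) over leave-one-out cross-validated accuracy, with **selection
repeated inside every split** so the reported accuracy is not inflated by
selection bias. Ties favour the stricter cut-off (fewer probes).

Two properties of this procedure deserve explicit note, because they shape
what its numbers mean:

* **Priors are estimated once on the full cohort and held fixed across
  splits.** If priors are re-estimated inside each split, the left-out
  sample's class is always the rarest class in training ($n_k - 1$ against
  $n_k$), which systematically biases leave-one-out accuracy downward — on
  a no-signal cohort with few selected features the bias drives accuracy
  to zero. Fixing the priors (the convention of `MASS::lda`'s built-in CV)
  removes the bias; on zero-effect cohorts the accuracy is then centred on
  chance.
* **Null-cohort LOOCV accuracy is over-dispersed relative to binomial
  sampling.** All $n$ splits share almost all of the data, so the same
  chance-selected probes recur across splits and the per-sample correctness
  indicators are correlated. Empirically the spread of null accuracy is
  roughly 2–3 times the binomial standard error, and the best-over-grid
  accuracy is additionally biased upward by max-selection. Chance-level
  tests on single cohorts should be read with that in mind.

### Outlier score

The outlier score of a sample is the negative log marginal density under
the fitted class mixture,

$$\mathrm{OS}(x) = -\log p(x) = -\log \sum_c p(x \mid c)\,\pi_c,$$

computed with natural logarithms via log-sum-exp. QDA (per-class
covariance) is used for scoring: a class with genuinely larger spread should
absorb distant samples, which a shared covariance cannot express. Scores for
labelled samples are computed leave-one-out, so no sample contributes to the
density it is scored against. The absolute scale of OS depends on the
number of probes and the cohort, so only comparisons within one analysis
are meaningful; the error-rate curve (below) is the calibrated translation.

Samples are ranked by OS into equal-frequency bins (default 10; remainders
go to the lowest bins), each bin contributing its misclassification rate at
its median OS; a least-squares polynomial (default degree 2, evaluations
clipped to $[0,1]$) turns a new sample's OS into an expected error rate.
Normal-tissue samples are excluded from binning — a pooled "normal" class
mixes many tissues and its scores are not comparable to tumour classes.

### Paired differential expression

CUP-vs-MOKO differential expression must not be confounded by
tissue-of-origin composition, so every probe is fitted with the additive
two-factor model

$$y = \text{class effect} + \text{group effect} + \varepsilon,$$

where class is the (predicted) tumour class and group is CUP/MOKO; the
group coefficient is t-tested on $n - K - 1$ residual degrees of freedom.
Classes lacking either group carry no within-class contrast and are dropped
with a notice. Variances are probe-wise ordinary least squares — no
moderation or pooling — and unbalanced groups are handled by the normal
equations without weighting. Adding any per-class constant changes no
p-value, which is the operational meaning of "eliminating class
differences". The core set is the probes passing `p < 1e-8`, split by the
sign of the group effect and translated to deduplicated gene symbols.

Benjamini–Hochberg is used for FDR control; the procedure behind a
published q-value is rarely stated, and BH is the conservative default that
matches the step-up convention in this field.

### Gene-set enrichment

Two complementary tests are provided. The *overlap test* is the upper-tail
hypergeometric probability of the observed intersection between a gene list
and each set, with the universe taken as all annotated genes on the
filtered matrix (a web tool's internal universe is not reproducible; using
the analysis universe is the documented choice here). *GSEA* ranks genes by
the signal-to-noise ratio between two groups (each group's SD floored at
0.2 of the absolute mean, the convention of the reference implementation),
walks the weighted Kolmogorov–Smirnov running sum (weight 1), and
calibrates the enrichment score against group-label permutations (gene-set
permutation below 7 samples per group, with a notice). The normalized
score divides ES by the mean magnitude of same-sign permuted scores; the
p-value is the same-sign tail fraction. Probes collapse to genes by the
highest-mean probe. Note that the weight-0 score is invariant to monotone
transformations of the ranking statistic; the default weight-1 score uses
the statistic's magnitudes and is not.

### Instability score

A chromosomal-instability signature is scored per sample as the mean of the
signature probes after two steps: keep the top 50% of the signature's
probes by across-sample variance (discarding redundant probes that do not
respond), then standardize each retained probe to mean 0, variance 1. The
score is therefore centred at 0 across the cohort and invariant to
probe-level constant shifts. The outlier–instability association is the
Pearson correlation between each tumour sample's OS and instability score,
with a two-sided p-value from the t transform.

## The synthetic cohort generator

Every stage is exercised against cohorts with known ground truth, generated
by `simulate_cohort()`. The generator emulates the statistical shape of a
multi-class tumour study — it makes no attempt to mimic real probe-level
correlation structure:

* Expression is Gaussian per probe on the log2 scale, with a per-probe
  baseline drawn from $\mathcal N(7, 0.5^2)$ (RMA output is approximately
  Gaussian per probe, and 7 is a typical log2 intensity midpoint).
* Each of the (default 5) classes elevates its own 30 signature probes by
  `class_effect` (default 2.0 log2 units — a strong, recoverable tissue
  signature); noise SD is 1.0.
* Metastases add `metastasis_effect` (0.5) on their class signature;
  CUPs are generated **from a known class as metastases** whose truth label
  the classifier should recover — the model is that a CUP is a metastasis
  with a divergent phenotype.
* CUP divergence has two knobs: the noise SD multiplier
  `cup_dispersion_factor` (default 2.0) and an up-shift
  `instability_effect` (default 1.0) on a dedicated instability-signature
  stratum (40 probes). Metastases of known origin receive half the
  instability shift by default, placing them between primaries and CUPs on
  the instability axis. No quantitative magnitudes for these are published
  anywhere; the defaults are set so the CUP-versus-MOKO outlier-score gap
  is qualitatively unmistakable rather than numerically matched to any
  reported range.
* Probes map to gene symbols 1–2 per gene (every third gene carries two
  probes), so probe/gene translation is exercised; signature, instability
  and null strata never share genes.
* Sex-restricted classes, when configured, are drawn only in the eligible
  sex; other samples are female with probability `sex_fraction_female`.

`simulate_gene_sets()` derives the matched collection: one set per class
signature, the instability set, and uniform random decoy sets from the
null-gene pool.

What the generator deliberately does **not** emulate: probe-probe
correlation, batch and platform effects, heavy-tailed intensities, class
imbalance of real registries, and any systematic outlier-score difference
between metastases and primaries (metastasis shifts are symmetric around
the pooled class mean, so OS(MET) ≈ OS(PRIM) by construction; only the CUP
group is displaced). Tests passing on these cohorts therefore demonstrate
the statistical machinery, not performance on real arrays.

## Numerical and design choices

* IQR filtering retains probes with across-sample interquartile range at
  least 0.8 log2 units by default; quartiles interpolate linearly between
  order statistics (R's type 7). Zero-variance probes pass silently through
  the filter (their IQR of 0 removes them at any positive threshold) but
  are an explicit error in standardization.
* UPGMA (average-linkage) clustering uses Euclidean distance on
  standardized values by default, correlation distance optionally;
  dendrograms serialize as Newick text.
* Posterior ties break toward the earlier class level with a message;
  grid-search ties toward the stricter cut-off; a split in which no probe
  passes the cut-off falls back to the highest-prior class.
* Variance floors: `eps = 1e-6` on all diagonal covariance entries. QDA
  covariance regularization is exposed (`cov_mode`, `lambda`, `eps`) since
  per-class full covariance is singular whenever probes outnumber class
  samples.
* The CUP outlier score is computed against all labelled tumour classes;
  whether normals join the reference mixture is the caller's choice (the
  pipeline excludes them from binning but keeps "normal" as a class during
  classification).

## Problem sizes used in the tests

The bundled checks run on cohorts of 5 classes with 40 primaries and 40
metastases per class (400 labelled samples, 1000 probes) for classification
and outlier checks; DE calibration uses 40 CUP + 160 MOKO over 2250 probes
(2000 of them null); enrichment calibration uses 200 decoy sets of 40 genes
against a ~1500-gene null pool, sizes chosen so the discrete
hypergeometric test's achievable size at 0.05 (exactly 0.028 for these
sizes) sits inside the expected false-positive band. These sizes keep the
whole suite fast while leaving every statistic in its asymptotic regime;
they are the package's reference study conditions, not limits of the
implementation.

## Known limitations

* Diagonal covariance ignores probe-probe correlation; on real arrays the
  outlier score scale and the error curve would shift accordingly.
* Ordinary least-squares DE without variance moderation loses power at very
  small group sizes compared to empirical-Bayes approaches — a deliberate
  scope choice, since moderation changes the published statistic.
* The equal-variance group test is anti-conservative when one group is
  substantially over-dispersed (as CUPs are, by design, at dispersion
  factor 2); calibration claims therefore refer to equal-dispersion
  configurations.
* GSEA p-values conditioned on the enrichment-score sign are granular at
  small permutation counts; at the default 1000 permutations the
  granularity is 2/1000 per sign.
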