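---
title: "Models and methods behind emospace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind emospace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emospace)
```

# The data and the model

`emospace` analyses bounded-slider ratings of emotion experiences. The raw
unit is a trial: one participant, in one session, rates one stimulus (a
narrative, a short video, or a moment of everyday life) on one scale, with a
slider anchored at 1 and 7. Sessions assign each rater a single scale, with a
small number of retest trials re-presenting stimuli already rated. After
exclusions, evoked-domain trials are averaged across raters into a
stimulus-by-scale matrix; real-life instances are single-rater rows and are
never averaged.

All multivariate stages treat the stimulus-by-scale matrix as noisy
realizations of an oblique common-factor model,

$$\Sigma = \Lambda \Phi \Lambda^\top + \Psi,$$

with loadings $\Lambda$ (scales by k), factor correlations $\Phi$ (unit
diagonal, positive definite) and diagonal unique variances $\Psi$. The
pipeline asks, in order: which scales are reliable enough to keep; whether
the scale-by-scale correlation structure is shared across stimulus domains;
how many factors to retain; what the factors are and how stable they remain
under decimation of stimuli and scales; whether independent reduction methods
(PCA, a linear autoencoder, principal preserved components) agree; how the
instances are distributed (continuous gradients versus discrete clusters);
and whether participant traits are associated with mean ratings.

# The synthetic-data generator

Because the methods are validated by recovery, the package ships a generator
with a fully known truth (`truth_model()`):

* factor scores $F \sim \mathcal N(0, \Phi)$ per stimulus, latent profiles
  $F\Lambda^\top + E$ with $E \sim \mathcal N(0, \Psi)$;
* a slider map `rating = 4 + gain * latent`, clipped to [1, 7]. The default
  gain of 1 with unit-variance scales leaves more than 99% of draws
  unclipped, so the bounded slider is emulated without rejection sampling
  and with limited censoring distortion;
* a rater model: each rater rates every stimulus on one scale with a
  constant personal bias (SD 0.5) plus trial noise (SD 1), and 8 uniformly
  chosen stimuli are re-presented as retest trials with fresh noise.
  Reaction times are log-normal and attention failures rare, so the
  exclusion rules have realistic material to act on;
* optional planted categories: factor scores are drawn around `separation *
  centroid` with the unclustered distribution as within-category spread, so
  `separation = 0` reduces the generator, bitwise under a fixed seed, to the
  unclustered case. Default centroids are the signed factor axes; with two
  categories this is the positive/negative pole of valence;
* optional participants with planted trait effects: a trait-scale pair with
  effect $r$ makes the participant's mean rating on that scale correlate $r$
  with the trait in the population; all other pairs are independent, so both
  power and family-wise error of the association screen can be calibrated.

The default truth has k = 3 correlated factors (pairwise $\Phi_{ij} = 0.2$)
with a valence/arousal/generalizability loading pattern over the 23-scale
roster, 150 stimuli and 20 raters per scale — the narrative-arm geometry;
presets scale this to the video arm (998 stimuli) and the single-rater
real-life arm (12,861 instances, 18 scales). The default pattern is
simple-structured — each scale loads exactly one factor: a ground truth
used as a recovery benchmark must be unambiguously representable by the
pipeline's own 0.2-cutoff loading patterns. Secondary loadings near the
cutoff plant structure that cross-validated retention genuinely cannot
attribute to k or k + 1 factors (benchmarks with such truths reproduce the
2-vs-3 / 3-vs-4 ambiguity typical of real rating data, and can be built by
passing a custom `lambda`).

What the generator does *not* emulate: ordinal slider discretization (it
treats sliders as continuous), stimulus-set heterogeneity across sessions,
participant attrition over longitudinal waves, non-Gaussian heavy-tailed
rating distributions, and any semantic content of the scales. Passing
recovery tests therefore shows the estimators are correct and well
calibrated under the stated model — not that real rating data satisfy that
model.

# Scale quality

Within-subject test-retest reliability is the Pearson correlation between
main and retest ratings per session; sessions with fewer than 3 pairs or
zero variance are *undefined* and are skipped by the medians (not treated as
zero — a constant rater carries no evidence either way). Between-subject
split-half reliability splits each scale's rater cohort in half at random,
correlates the per-stimulus mean vectors of the halves, and repeats 50
times. For means of $m$ raters with noise-to-signal variance ratio
$\sigma^2$, the expected split-half correlation is $1/(1 + \sigma^2/m)$, a
closed form the test-suite checks against simulation.

Readability of scale definitions is the Flesch–Kincaid grade,
$0.39\,(\text{words}/\text{sentences}) + 11.8\,(\text{syllables}/\text{words})
- 15.59$, with a dictionary-free syllable counter (maximal `aeiouy` groups,
minus one for a silent `-e`/`-es`/`-ed` ending, floored at one). Readability
is reported and correlated with reliability but never gates exclusions. The
canonical five low-reliability scales are an explicit roster
(`flag_low_quality()`); a numeric threshold rule is exposed for new data
because no published cutoff exists.

# Representational similarity

Scale-by-scale Pearson matrices are compared across domains by vectorizing
the lower triangles over the 18 shared scales, Fisher z-transforming (a
monotone map, so the subsequent Spearman correlation is unchanged by it; it
is applied so the vectorized entries are on a comparable scale) and taking
the Spearman rank correlation. Significance uses a joint row/column
permutation of one matrix (the same permutation for rows and columns, which
preserves symmetry), 10,000 draws by default, with the add-one correction
$p = (1 + \#\{\rho_\pi \ge \rho\})/(n+1)$ so p is never exactly zero.

# Factor retention

Six scree- or structure-based criteria are implemented on the
principal-component eigenvalues of the correlation matrix:

* **Parallel analysis** retains the leading run of eigenvalues exceeding the
  rank-wise 95th percentile of eigenvalues of same-sized random normal data.
  The percentile convention (rather than the mean) is deliberate: it keeps
  the false-retention rate on pure noise near 5%, which the test-suite
  checks by null simulation; a mean option is exposed.
* **Optimal coordinate**: leading run of eigenvalues above their linear
  extrapolation from the next eigenvalue and the last one.
* **Acceleration factor**: one less than the position of the largest second
  difference of the scree, floored at 1.
* **VSS (complexity 1)**: keep each item's largest absolute loading, score
  $1 - SS_{resid}/SS_R$ on the off-diagonals, maximize over k.
* **Velicer's MAP**: mean squared partial correlation after partialling k
  principal components, minimized over k; on a no-structure matrix the
  reported convention is 1.
* **Empirical BIC**: $\chi^2 - df\,\log N$ of the k-factor maximum
  likelihood solution, minimized over k.

The decisive, data-driven procedure is EFA-to-CFA cross-validation
(`cv_retention()`): stimuli are split in half; the EFA half yields explained
variance and an item-to-factor assignment (every factor whose absolute
pattern loading exceeds 0.2 — an item crossing several keeps them all, with
those cross-loadings free in the CFA; an item crossing none is assigned to
its largest-loading factor so the model stays identified); the CFA half is
fitted by maximum likelihood with free factor correlations, and RMSEA
$=\sqrt{\max(\chi^2 - df, 0)/(df\,(N-1))}$ is recorded. Iterations with an
empty factor or a failed fit are invalid and excluded from the means; a k
is only eligible for selection when at least three quarters of its
iterations are valid, because validity is not random — the half-splits
that keep a too-large model convergent are those that happened to support
the extra factor, so a mean over a filtered minority is biased toward good
fit. The
chosen k is the largest whose mean RMSEA improves on the best value at any
smaller k by more than 0.01 (an explicit elbow tolerance standing in for
by-eye inspection). Measuring the improvement against the running minimum
rather than against k−1 matters at finite iteration counts: a Monte-Carlo
spike at k−1 would otherwise promote a k that fits no better than an
earlier, simpler solution.

The CFA is estimated by `nlminb` on the multivariate-normal discrepancy with
analytic gradients; $\Phi$ is parametrized by a row-normalized Cholesky
factor (always positive definite, unit diagonal) and uniquenesses on the log
scale. Non-convergence invalidates the iteration rather than being imputed.

# Factor models

EFA uses minres extraction — uniquenesses chosen (by `nlminb` from squared
multiple correlation starts) to minimize the sum of squared off-diagonal
residuals, with loadings from the leading eigenvectors of the reduced
matrix — followed by oblimin rotation at $\gamma = 0$ (direct quartimin),
computed by gradient projection and restarted from random orthonormal bases
(10 by default; 3 inside cross-validation loops) to avoid local minima.
Factors are ordered by explained common variance and sign-aligned. Factor
scores use the ten Berge correlation-preserving estimator, so the score
correlations reproduce $\Phi$ exactly (a property the tests assert at
`1e-8`). Communalities above 1 (Heywood cases) are capped and flagged.
Per-factor variance shares use the structure-loading convention
$SS(\Lambda\Phi)$ normalized across retained factors.

PCA extracts correlation-matrix components, varimax-rotated, with
regression-estimated standardized scores, in the same container as EFA so
the two can be compared by Tucker congruence after orthogonal Procrustes
alignment (`tucker_congruence()`; alignment makes the coefficient invariant
to column order and sign).

Robustness is assessed two ways: random stimulus decimation (re-fit on
subsets, report per-factor congruence with the full-set solution; presets
remove 5/25/250 stimuli per step for the three arms, 20 randomizations per
size) and redundancy-ordered scale decimation (repeatedly drop the scale
with the highest mean correlation with the rest, ties broken
alphabetically; re-fit and correlate factor scores with the full-set
solution, factors matched greedily by maximal absolute correlation — a
permutation, sign-aligned).

The linear autoencoder (one hidden layer, width k, linear activations) is
fitted by alternating exact least squares from a random start; at
convergence its training reconstruction equals the projection onto the
top-k principal subspace, which the tests verify numerically rather than
assume. Raters are split in half within each scale (so every cell stays
covered), the model is trained on one half's aggregate and tested on the
other, and decoder weights are compared to EFA loadings by congruence.

# Principal preserved components

For two datasets $X, Y$ on the same stimuli and scales, PPCA
eigen-decomposes the symmetrized cross-covariance $(X^\top Y + Y^\top X)/2$
after column centering within each dataset (centering is required for
covariance semantics; each split half is centered on its own means).
Components with large positive eigenvalues capture structure *preserved*
across datasets; $Y = X$ reduces exactly to PCA. The significance procedure
splits each scale's raters in half, holds out one stimulus at a time, fits
PPCA on the rest, projects the held-out row in both halves, and correlates
the concatenated held-out scores across halves, partialling out all previous
components by least-squares residualization on each side. Twenty such
repetitions feed a one-tailed Wilcoxon signed-rank test per component at the
Bonferroni level $\alpha/m$ ($0.05/23 \approx 0.00217$ at the default
roster). The reported count is the contiguous leading run of significant
components (a total count is also returned); the leading-run convention is
the conservative reading of a single reported dimensionality.

# Embedding, clusters and unimodality

The 2-D embedding is UMAP (via `uwot`, single-threaded so a seed fixes the
result). The neighborhood size is chosen by cross-validation: rows are split
in half ten times, the model fitted on one half, the held-out half mapped
through it, and two metrics computed on the held-out half — trustworthiness
(local neighborhood preservation, penalizing intruders by their
original-space rank; neighborhood size 5 by default) and the Spearman
correlation of pairwise Euclidean distances (global). The chosen size
maximizes the rank-sum of the two mean metrics, an explicit stand-in for
choosing by inspection of both curves.

Clustering uses Euclidean distances on the raw 1–7 profiles without
rescaling — the shared bounded range makes per-scale variance informative —
with Ward linkage for the hierarchy and K-means (10 restarts, best inertia)
for category recovery, scored by the adjusted Rand index and adjusted mutual
information (chance-corrected under the hypergeometric model; the AMI uses
the arithmetic-mean normalization). Unimodality of the pairwise-distance
distribution is tested with Hartigan's dip statistic, implemented in C++
(the gcm/lcm squeezing algorithm) and validated in the test-suite against a
brute-force linear-programming oracle that minimizes the supremum distance
to a unimodal cdf directly from the definition. P-values come from a
uniform-null bootstrap (2000 replicates by default); distance vectors larger
than 10,000 are uniformly subsampled first, which leaves the test's
calibration intact while bounding the bootstrap cost.

Basic-emotion instances are selected on the six basic-emotion scales only: a
candidate needs a rating strictly above 6 on its own scale and is ranked by
Euclidean distance to the perfect profile (7 on its scale, 1 elsewhere), up
to 5 per category, ties broken by instance id.

# Stimulus sampling

Subset size is chosen by the PCA-plateau procedure: for each candidate size,
100 random subsets are drawn and the mean number of components needed for
80% cumulative variance recorded; the plateau is the smallest size within
0.5 components of the full-set value (a tolerance standing in for visual
judgment). Maximum-variation selection then grows a subset greedily —
each new stimulus maximizes the summed Euclidean distance to those already
selected — restarted from every possible initialization, keeping the run
with the largest total pairwise distance; all ties break lexicographically
by id so the output is deterministic. A max-min variant is exposed but off
by default. On small instances the greedy-over-all-starts objective is
within 5% of the exhaustive optimum (checked against brute force).

# Individual differences

Evoked ratings are first centered on their per-stimulus, per-scale
cross-participant means, so a participant's session mean isolates their
rating bias from the stimuli they saw; centering is idempotent and singleton
cells center to zero. Real-life means are computed per participant across
waves, restricted to participants with complete data from all 15 waves, and
can be corrected by subtracting the participant's evoked bias. The screen
tests every (scale, variable) pair — Pearson for continuous traits, Welch's
t for two-level groups, oriented first level minus second — with Bonferroni
correction over the whole displayed grid (a per-variable family option
exists via subsetting).

# Numerical choices and edge cases

* Exclusion thresholds (400 ms, 1 of 3 attention checks, mean − 3 SD cohort
  reliability, 10% invalid trials, 3 invalid sessions) are configuration
  with those defaults; the reliability screen treats its bound strictly and
  iterates to a fixed point within one call, making the whole exclusion
  pass idempotent. Raters with fewer than 3 valid retest pairs are screened
  only by the invalid-trial rule, since a Pearson correlation on fewer
  pairs is not meaningful.
* Correlations on degenerate input (zero variance, fewer than 3 pairs)
  return `NA` and are excluded from aggregates, never coerced to 0.
* Fisher z-transforms clamp |r| = 1 at `1 - 1e-12` with a warning.
* The permutation and bootstrap p-values use add-one corrections.
* All randomized procedures take explicit seeds; child seeds are derived
  arithmetically and stay within the 32-bit integer range.

# Problem sizes used in the shipped checks

The test-suite and the acceptance script run the recovery studies at the
narrative-arm geometry (150 stimuli, 23 scales, 20 raters, 20 seeds for
recovery and retention; 5 datasets for the PPCA certification and 20 null
runs; 200 repetitions for permutation-null and family-wise-error
calibration; dip bootstraps of 500 inside simulations and 2000 as the
single-test default). Retention cross-validation keeps its full 20
half-splits per dataset: at a handful of splits the Monte-Carlo error of
the mean RMSEA is on the order of the elbow tolerance and model choice
becomes unstable. These sizes keep each study's Monte-Carlo error small
relative to the property being asserted while completing in minutes on one
core.

# Known limitations

* The split-half PPCA certification reuses one dataset across its 20
  repetitions (as the procedure prescribes), so the repetitions are
  dependent: when the realized rater noise of a dataset happens to be
  over-dispersed in some direction, both rater halves inherit it in every
  repetition and the leading component is selected on exactly that
  direction. Null simulations in this package put the resulting
  false-certification rate near 12–15% rather than at the nominal
  Bonferroni level; reported component counts should be read with that
  dataset-level optimism in mind.

* Minres and ML factor solutions assume linear factor structure;
  slider clipping induces mild attenuation that the recovery tests absorb
  but heavy censoring (large gain) would not.
* The CFA assumes multivariate normality for its $\chi^2$; RMSEA values on
  clipped data are interpreted comparatively (across k), not absolutely.
* The dip test's uniform null is the classical least-favorable choice;
  p-values for strongly skewed unimodal alternatives are conservative.
* UMAP embeddings are for visualization and neighborhood diagnostics;
  distances in the embedded plane are not calibrated.
* The greedy maximum-variation sampler is near-optimal but carries no
  global optimality guarantee beyond the exhaustive checks at small n.
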