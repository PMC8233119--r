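---
title: "Methods: twin-based heritability and fingerprinting of functional connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin-based heritability and fingerprinting of functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`twinconn` analyses resting-state functional connectomes of twin cohorts.
It covers three linked questions:

1. **Fingerprinting** — can an individual (or their twin) be identified by
   correlating vectorized connectivity matrices across scanning sessions?
2. **Effect sizes** — how separated are the similarity-score distributions
   of same-individual, monozygotic (MZ), dizygotic (DZ) and unrelated (UN)
   pairs, measured nonparametrically by Cliff's delta?
3. **Heritability** — what fraction of edge-wise connectivity variance is
   attributable to additive genetic factors, estimated by a bootstrapped
   multivariate ACE variance decomposition with a zygosity-shuffled null?

Real twin fMRI datasets of this kind are access-restricted, so the package
ships a synthetic-data module that generates twin cohorts and edge
phenotypes with *known* variance structure. Every downstream stage is
validated against that ground truth.

# Data model and conventions

A **cohort** table lists subjects with pair membership, zygosity (MZ/DZ),
age and sex; each pair id occurs exactly twice with one zygosity. A
**parcellation** maps nodes to named functional networks (an
`"unassigned"` label is allowed and excluded from network-level analyses).
Connectivity lives either as symmetric node-by-node correlation matrices
(unit diagonal, entries in $[-1, 1]$) or as a subjects-by-edges table.

Edges follow one canonical order everywhere: lower-triangle node pairs
$(i, j)$ with $i > j$, row-major over $i$, using 1-based node indices as is
natural in R. For $n$ nodes there are $n(n-1)/2$ edges (35,778 for a
268-node parcellation, 55,278 for 333 nodes). Files are tab-separated text
with header rows: diffable, round-trip exact, and free of binary-format
coupling.

Matrix symmetry is enforced up to $10^{-8}$ and then restored by averaging
with the transpose, which absorbs write/read rounding without hiding real
asymmetry.

# The synthetic twin generator

`generate_cohort()` draws pair ages uniformly over 22–36 years (shared
within pair, matching the young-adult range typical of large twin fMRI
samples) and assigns sex as an independent fair coin per subject; the
default cohort size used throughout the tests is 123 MZ + 67 DZ pairs (380
subjects), the composition of the motivating study population.

`simulate_edge_phenotypes()` realizes, per edge with fractions
$(a^2, c^2, e^2)$ and total variance $v$:

$$y = \mu_0 + \beta_{age}\,\mathrm{age} + \beta_{sex}\,[\mathrm{sex}=M]
      + \sqrt{a^2 v}\,G + \sqrt{c^2 v}\,C + \sqrt{e^2 v}\,E$$

where $G$ is identical for MZ co-twins and, for DZ co-twins, split as
$\sqrt{1/2}$ pair-common plus $\sqrt{1/2}$ twin-unique so that the genetic
correlation is exactly $1/2$ by construction; $C$ is identical within every
pair; $E$ is independent. Consequently the within-pair correlations
converge to $a^2 + c^2$ (MZ) and $a^2/2 + c^2$ (DZ), which the tests check
by Monte Carlo at 2,000 + 2,000 pairs. Fractions may vary by edge
(`ace_truth_by_network()`) to emulate network-wise heritability
differences.

`simulate_sessions()` wraps the stable subject-level connectome in
independent Gaussian session noise, emulating a two-day REST1/REST2
design; `simulate_roi_timeseries()` generates time series with a target
correlation structure to exercise the correlation-matrix path.

All components are Gaussian. The generator makes no claim of matching the
marginal distribution of empirical edge weights, head-motion artifacts, or
heritable motion confounds; a green test suite therefore demonstrates
correctness of the *estimators* under the model, not robustness to every
property of real fMRI data.

# Fingerprinting

For target connectome $T_i$ and database connectome $D_N$ the similarity
is the Pearson correlation over their $e$ common edges. Individual
identification predicts the database argmax per target (correct when it is
the target itself); twin identification first masks the same-individual
cell, and a prediction is correct when it names the pair partner. Exact
argmax ties are measure-zero on real-valued data but possible on small
fixtures; they are broken by first database index with a warning.

Individual accuracy is averaged over the two cross-session combinations
and twin accuracy over all four session combinations, with the SD taken
across combinations. Statistical significance of twin identification comes
from a permutation test that shuffles the target-to-twin assignment among
the analysed targets (a derangement is not enforced), keeping the argmax
predictions fixed; the p-value uses the add-one estimator
$(1 + \#\{\mathrm{perm} \ge \mathrm{obs}\})/(1 + n_{perm})$, which never
returns 0 and is consistent with reporting $p < 0.001$ at 1,000
permutations. Accuracy as a function of the number of edges is traced over
random subsets (default sizes 10, 50, 100, 500, 1,000, 5,000, 10,000;
drawn without replacement within a draw, independently across draws).

Note that with very small subsets (2 or 3 edges) the Pearson correlation
between short vectors degenerates (2-point vectors correlate at $\pm 1$),
producing genuine argmax ties; the tie warning is informative there.

# Effect size

Cliff's delta between samples $x_1$ and $x_2$ is

$$d = \frac{\#\{x_1 > x_2\} - \#\{x_1 < x_2\}}{n_1 n_2}$$

over all $n_1 n_2$ cross-sample pairs, with ties contributing zero. The
default implementation counts wins and losses by binary search on the
sorted second sample in $O((n_1+n_2)\log n_2)$ — necessary because the UN
group of a 380-subject cohort holds 143,640 scores — and a literal
$O(n_1 n_2)$ implementation is retained (`method = "brute"`) and tested for
exact agreement, along with the rank-statistic identity
$d = 2U/(n_1 n_2) - 1$.

Scores are grouped over the *ordered* cells of one REST1-by-REST2
similarity matrix (not symmetrized), so a twin pair contributes two cells;
this matches the natural counts 380 SI, 246 MZ, 134 DZ and 143,640 UN on
the reference cohort composition.

# The multivariate ACE model

For $p$ phenotypes per subject, a twin pair stacks into a $2p$-vector with
model-implied covariance

$$\Sigma_z = \begin{pmatrix} V & R_z \\ R_z & V \end{pmatrix},\qquad
  V = A + C + E,\qquad R_{MZ} = A + C,\qquad R_{DZ} = \tfrac12 A + C,$$

where $A$, $C$, $E$ are symmetric variance-component matrices for additive
genetics, shared environment and unique environment/error. The Gaussian
likelihood with a single mean vector shared across twins and zygosity
groups (data are residualized first, so means are near 0 but remain
estimated) is maximized over $\mu$ and the free elements of $A$, $C$, $E$.

Numerical choices:

* **Direct variance parameterization.** Diagonal entries of the components
  are *unbounded*, not Cholesky-constrained. This matches
  variance-component model semantics and is essential for the null
  analysis: a positivity-constrained parameterization would bias the
  zygosity-shuffled null of $h^2$ upward, whereas the unbounded
  parameterization leaves it centered at 0.
* **Sufficient statistics + analytic gradients.** The likelihood is
  computed from per-group means and scatter matrices; the gradient with
  respect to $\mu$ and each component follows from the standard matrix
  derivative of the Gaussian log-density, folded onto the unique elements.
  A per-pair summation path is retained as an independent oracle and
  verified against the sufficient-statistic path to $10^{-8}$.
* **Optimization.** L-BFGS-B from the start value $A = C = E = S/3$ ($S$
  the pooled phenotypic covariance) with a relative-tolerance stopping rule
  (`factr = 1e4`, i.e. ~$10^{-12}$ relative) and one jittered restart on
  failure; non-convergence is flagged, never silently accepted.
* **Non-positive-definite proposals** are handled by a smooth eigenvalue
  penalty (finite and differentiable almost everywhere) rather than an
  infinite barrier, so quasi-Newton steps remain well defined. The
  reported log-likelihood contract still treats non-PD covariances as
  $-\infty$.

Standardization divides each component diagonal by the total variance:
$h^2_i = A_{ii}/V_{ii}$ etc., summing to 1 per phenotype. Falconer's
closed form $a^2 = 2(r_{MZ} - r_{DZ})$, $c^2 = 2r_{DZ} - r_{MZ}$,
$e^2 = 1 - r_{MZ}$ serves as an independent large-sample check of the
univariate fit. AE/CE submodels, likelihood-ratio comparisons and
common-pathway models are out of scope, and genetic correlations
(component off-diagonals) are estimated but not summarized.

# The bootstrapped heritability pipeline

The pipeline averages the two sessions, residualizes age and sex by
ordinary least squares per edge over the pooled sample, and then, per
iteration, draws 10 distinct edges uniformly at random (draws independent
across iterations, so edges recur), fits the multivariate ACE model, and
records the mean of each component's standardized diagonal. The default
iteration count is the smallest multiple of 1,000 such that
`iterations x subset_size` covers every edge twice in expectation (floor
1,000): 8,000 for a 35,778-edge whole-brain analysis, 12,000 for 55,278
edges, 1,000 for typical networks.

The null distribution repeats the identical procedure but permutes MZ/DZ
labels across *pairs* (pairs stay intact, preserving the 123/67 group
sizes and the pair likelihood structure) before every fit, destroying the
genetic contrast; its mean $h^2$ sits at 0 under the unbounded
parameterization. Estimate and null halves draw fresh edges from
independent seed streams. Non-converged fits trigger a redraw (logged);
more than 10% failures aborts with diagnostics. Estimate-vs-null
separation is summarized by a Welch two-sample $t$ test on the
per-iteration mean $h^2$ — bootstrap iterations are not independent
samples, so this mirrors the field's usage and should be read
descriptively, not inferentially. Summaries add 2.5/97.5 bootstrap
percentile intervals, chosen as the plainest distribution-based interval.

No Fisher z-transform is applied to edge values anywhere in the pipeline;
edge phenotypes enter the ACE model on their observed scale.

# Problem sizes used in the tests

The test-suite and acceptance scenarios run at desk scale, chosen so each
property is measurable with comfortable Monte-Carlo margins: univariate
parameter recovery at 2,000 + 2,000 pairs (sampling SE of $h^2$ about
0.02), the bootstrap pipeline at the reference cohort size of 123 + 67
pairs with 200 edges and 300 iterations per half, fingerprinting
properties over 20–30 replicate cohorts of 10–20 pairs, and the
multivariate-vs-univariate agreement over 60 edges. Self-consistency fits
on model-implied moments recover parameters to $10^{-4}$, independent of
sample size.

# Known limitations

* The generator's Gaussian edge phenotypes ignore the bounded, skewed
  nature of empirical correlation-derived edges; heritability estimators
  are validated for unbiasedness under the generative model only.
* Opposite-sex DZ pairs are permitted in the cohort type; sex enters only
  through the pre-fit residualization, with no further sex-limitation
  modeling.
* The Welch test on bootstrap distributions inherits the dependence caveat
  above.
* Whole-brain runs at published scale (8,000 + 8,000 fits over 35,778
  edges) are supported but take correspondingly longer than the
  desk-scale examples; iteration counts scale linearly.
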