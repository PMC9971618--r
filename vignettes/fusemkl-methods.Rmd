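---
title: "Multi-omics fusion and gene-signature detection with fusemkl"
author: "fusemkl maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics fusion and gene-signature detection with fusemkl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusemkl)
```

# The problem

Tumour cohorts are routinely profiled on several molecular platforms at
once — gene expression, DNA methylation, exon expression, pathway activity,
copy number — over a shared set of patients carrying a clinical class label
(e.g. favorable / intermediate / poor cytogenetic risk in acute myeloid
leukemia). Each layer sees the same biology through a different, noisy lens.
`fusemkl` fuses such layers into one latent representation, asks which binary
grouping of the clinical classes is most learnable from the fused data, finds
co-expression modules among the screened genes in that grouping, and elects
the most internally coherent module as a gene signature whose predictive
value is then quantified by an independent classifier.

The pipeline is a cascade of six stages, each exposed as ordinary functions
and orchestrated by the single fitting call `fusemkl()`, which returns a
classed object with `print`, `summary`, `plot` and `predict` methods.

# Stage 1: empirical-Bayes screening

Each layer is zero-mean normalized per feature, $x' = (x - \mu)/\sigma$,
with the *population* standard deviation (divide by $n$): the normalization
is a per-row rescaling and no inferential use is made of $\sigma$ itself, so
the Bessel correction is a matter of convention; the choice is exposed via
`zero_mean_normalize(bessel =)`. Features with any missing value are dropped
first (`drop_missing_features()`), mirroring how methylation-array probes
with failed beads are handled in practice.

Screening uses the moderated $t$/$F$ framework: with per-feature pooled
within-group variance $s^2$ on $d$ degrees of freedom, an inverse-chi-square
prior $(d_0, s_0^2)$ is fitted across features by matching the first two
moments of $\log s^2$ (the trigamma equation is inverted by Newton
iteration), and each feature's variance is replaced by the posterior blend

$$\tilde s^2 = \frac{d_0 s_0^2 + d\, s^2}{d_0 + d},$$

a convex combination of $s^2$ and $s_0^2$. Two classes give the moderated
$t = \hat\beta / (\tilde s \sqrt{1/m_1 + 1/m_2})$ on $d_0 + d$ degrees of
freedom; $m > 2$ classes give a moderated one-way $F$ on
$(m-1,\, d_0 + d)$ degrees of freedom, which coincides with combining the
pairwise moderated contrasts through an orthonormal basis and reduces to
$t^2$ at $m = 2$. The estimator keeps $d_0$ finite (capped at $10^6$): on
data whose log-variances are underdispersed relative to the chi-square the
cap is active and $\tilde s^2 \approx s_0^2$; the test suite cross-checks
the finite-$d_0$ regime against an independent reference implementation at
machine precision.

Features with $p < \alpha$ (raw $p$, $\alpha = 0.05$ by default; a
Benjamini-Hochberg option sits behind `adjust =`) are kept; within a gene,
the minimum-$p$ probe represents it, ties broken by lexicographic feature
id for determinism. The per-layer gene sets are unioned (sorted, unique)
into the screened universe that all later stages use.

# Stage 2: relational fusion by penalized tri-factorization

The layers are arranged as a relational block system over object types
(genes, samples, and one feature space per multi-probe layer). A gene-keyed
layer occupies the single (gene, sample) relation slot when free; a
multi-probe layer contributes a binary (gene, feature) membership relation
and a (feature, sample) data relation. Because the factorization is
non-negative, each z-scored data block is shifted by its minimum (the shift
is recorded and invertible); missing entries are zero-filled and flagged in
an observed mask — the zero-fill treats an absent measurement as an
uninformative relation rather than excluding it, which keeps the update
rules exactly monotone.

The fit minimizes

$$\sum_{(i,j)} \lVert R_{ij} - G_i S_{ij} G_j^{\top} \rVert_F^2
  + \sum_p \operatorname{tr}(G_p^{\top} \tau_p G_p), \qquad G_p \ge 0,$$

by block-coordinate descent: each latent relation $S_{ij}$ is the exact
least-squares solution
$(G_i^{\top}G_i)^{+} G_i^{\top} R_{ij} G_j (G_j^{\top}G_j)^{+}$ (pseudo
inverses via SVD with a relative tolerance of $10^{-10}$), and each
non-negative factor $G_p$ takes a multiplicative update with
positive/negative splitting of the gradient (the $\tau_p$ penalty split as
$\tau^+ - \tau^-$), the semi-NMF scheme whose auxiliary function guarantees
a non-increasing objective. The objective trace is recorded every sweep and
an increase beyond $10^{-9}$ relative aborts the fit — it would indicate an
implementation bug, not a data problem. Types are visited in name order so
the result does not depend on assembly order.

Defaults: ranks $r_p = \min(\lceil n_p/10\rceil, 50)$ (the input never
specifies ranks; a tenth of the object count is a common low-rank rule of
thumb), $\tau_p = 0$ (the penalty content is user-supplied when wanted),
initialization $|N(0,1)|$ scaled to the data mean with a per-type seed
derived from a hash of the type name (making results invariant to type
order), `tol = 1e-6` relative, `max_iter` 500 for standalone fits and 300
inside the pipeline. Multiplicative updates converge linearly and can need
thousands of sweeps to drive a planted exact factorization below
$10^{-6}$ relative error; the planted-recovery test runs 15000 sweeps on a
30 x 20 system in a few seconds. Like all NMF-type objectives the problem
is non-convex and a given start can end in a local minimum; restarting with
another seed is the standard remedy.

# Stage 3: kernels from reconstructions

Each fitted (feature-space, sample) relation is reconstructed as
$\hat R = G_i S_{ij} G_j^{\top}$ and turned into a sample-by-sample kernel
$K = \hat R^{\top} \hat R$ (samples on rows first). Kernels are
cosine-normalized, $K'(a,b) = K(a,b)/\sqrt{K(a,a)K(b,b)}$, then smoothed
with a 2-D uniform box filter (default window 3, edge-replicated; window 1
disables smoothing; `smooth_first =` swaps the order for users who prefer
smoothing the raw kernel). Smoothing does not preserve positive
semidefiniteness, so the matrix is symmetrized and its negative eigenvalues
clipped to zero. The box filter is the simplest 2-D linear filter; the
window is deliberately small because sample ordering is lexicographic, not
biological, and heavy smoothing would blur class structure.

# Stage 4: soft-margin multiple kernel learning

Given $P$ base kernels with binary labels, the model maximizes a target
margin $\theta$ while charging each kernel a hinge-loss slack,

$$\min \; -\theta + \pi \sum_{p=1}^{P} \zeta_p
  \quad \text{s.t.} \quad D_{SVM}(K_p, \alpha) \ge \theta - \zeta_p,
  \; \zeta_p \ge 0,$$

where $D_{SVM}(K,\alpha) = \sum_n \alpha_n - \tfrac12 \sum_{n,m}
\alpha_n\alpha_m y_n y_m K_{nm}$ is the SVM dual value of a shared dual
vector. The trade-off must satisfy $\pi \ge 1/P$ (below it the subproblem
is unbounded and the fit refuses to run). The program specifies no solver;
the implementation alternates:

1. solve the single-kernel SVM dual on $K_\mu = \sum_p \mu_p K_p$ for
   $\alpha$ (a box- and equality-constrained QP, solved by an interior
   point method with a small diagonal ridge of $10^{-6}$ times the mean
   kernel diagonal — the reconstructed kernels are low-rank — escalated a
   thousandfold on the rare numerically singular subproblem);
2. given the per-kernel values $D_p$, set $\theta$ to the
   $\lceil 1/\pi \rceil$-th smallest $D_p$, the exact minimizer of the
   piecewise-linear subproblem, and $\zeta_p = \max(0, \theta - D_p)$;
3. move the weights multiplicatively toward kernels with a large quadratic
   form $(\alpha y)^{\top} K_p (\alpha y)$ — kernels aligned with the
   learned discriminant — with a halving backtracking step accepted only if
   the traced objective does not increase.

At $\pi = 1$ all slacks are zero and the objective is $-\min_p D_p$; one
kernel degenerates to a plain SVM with unit weight; identical kernels keep
equal weights by symmetry. The box constraint $C$ (default 1, the program's
dual omits it) supplies per-sample slack, without which noisy samples would
make the dual unbounded. Decision scores use the combined kernel with the
offset $b$ from the KKT conditions (mean over margin support vectors, or
the midpoint rule for a hard-margin solution).

# Stage 5: class-label combination search

With $m$ classes, all one-vs-one pairs plus all one-vs-rest splits are
enumerated ($m = 3$ gives the canonical six). Each combination restricts
the samples to its two sides, assigns left = positive, and is scored by
seeded stratified $k$-fold cross-validation of the MKL classifier on the
fused kernels (an alternative backend runs the nearest-shrunken-centroids
classifier on the collapsed expression matrix, `classifier = "pam"`; the
source method description is ambiguous about which classifier performs this
step, so both are provided and the kernel-native one is the default).
Out-of-fold decision scores are pooled — not averaged per fold — because at
these sample sizes per-fold AUCs are high-variance; the AUC uses the rank
(Mann-Whitney) formula, which equals the concordant-pair count with ties at
one half, and threshold-zero confusion metrics accompany it. The argmax-AUC
combination wins, ties broken by accuracy then name.

# Stage 6: modules and the signature

On the winning combination's samples, the expression layer (collapsed to
one minimum-$p$ probe per gene, restricted to the screened union) yields an
unsigned weighted adjacency $X = |\mathrm{PCC}|^{\beta}$. The power
$\beta$ is the smallest candidate whose scale-free topology fit $R^2$
(regression of $\log p(k)$ on $\log k$ over ten connectivity bins) reaches
0.8, falling back to the maximizer when no candidate reaches it — on
block-structured synthetic data the scale-free regime is typically never
reached and the fallback fires; this is expected and harmless because the
downstream cut is scale-free in $\beta$ (see below). The topological
overlap

$$\mathrm{TOM}(i,j) = \frac{\sum_{v \ne i,j} X_{iv}X_{jv} + X_{ij}}
 {\min\!\big(\sum_{v\ne i} X_{iv}, \sum_{v\ne j} X_{jv}\big) - X_{ij} + 1}$$

is evaluated verbatim for arbitrary $X \in [0,1]$ — the formula is written
for Boolean adjacencies but is well-defined for weighted ones, which are
the default; a booleanization threshold is available (`mode = "boolean"`).
Self-edges are excluded from all sums; the diagonal is 1 and
$\mathrm{dissTOM} = 1 - \mathrm{TOM}$ feeds average-linkage (UPGMA)
clustering.

The dynamic tree-style cut splits a branch at the largest jump in its
sorted merge heights whenever the jump exceeds a fraction (`gap`, default
0.2) of the dendrogram's total height range — measuring the gap relative to
the range makes the cut invariant to the compression of dissimilarities
that high soft powers cause — and recurses into the components; pieces
smaller than `min_module_size` (default 20) fall into the grey pool, and a
branch whose best split would produce only undersized pieces is kept whole.
Average linkage chains weakly connected genes onto dense branches one leaf
at a time, producing height continua that no height criterion can cut, so
accepted modules are then pruned by membership: a gene whose mean
topological overlap with the other members falls below half the module's
median membership is returned to the pool (two passes; the analogue of
eigengene-based membership filtering in weighted co-expression practice).
Modules are named by the conventional size-ordered colour palette
(turquoise, blue, brown, ...), grey reserved for unassigned genes.

Cluster validity is reported as the Dunn index and mean silhouette width on
dissTOM (both undefined and reported as `NA` when a single module remains)
together with the standard weighted network concepts of the full adjacency:
density, centralization, heterogeneity (coefficient of variation of
connectivity), mean scaled connectivity, mean clustering coefficient and
mean maximum adjacency ratio.

Each module's quality is its mean pairwise Pearson correlation over the
selected samples; the maximal-mean module is elected the signature (ties to
the larger module, then the lexicographically smaller colour; grey never
competes). The signature is evaluated with a from-scratch
nearest-shrunken-centroids (PAM) classifier: centroid differences
standardized by $m_k (s_g + s_0)$ with $s_0$ the median pooled
within-class standard deviation, soft-thresholded at $\Delta$ chosen by an
inner 5-fold cross-validation over a 30-point grid from 0 to the largest
standardized difference (minimum error, ties to the strongest shrinkage);
at $\Delta = 0$ the classifier is exactly diagonal-covariance
nearest-centroid classification, which the tests verify against a
brute-force oracle. Evaluation is 10 repeats of seeded stratified 10-fold
cross-validation (folds reduced with a warning when a class is smaller);
per repeat, pooled out-of-fold predictions give sensitivity, specificity,
precision, NPV and accuracy at the posterior-0.5 threshold and pooled
posterior scores give the AUC; the report carries means and standard
deviations over repeats. Pooling per repeat (rather than averaging
per-fold AUCs) was chosen for stability at small $n$; the alternative is a
one-line change in `pam_cv_evaluate()`.

# The synthetic study design

`sim_config()` describes the data-generating process used throughout the
tests and the acceptance run; its defaults *are* the study conditions:

* three classes of 40 samples each (120 total), echoing a mid-sized
  clinical cohort split into favorable / intermediate / poor risk;
* 1000 genes, of which three planted modules of sizes 60, 60, 50 with
  within-module equicorrelations $\rho$ = 0.7, 0.5, 0.4 — each module gene
  is $\sqrt{\rho}\,f + \sqrt{1-\rho}\,\varepsilon$ for a shared factor
  $f$, so the target correlation is exact in expectation; remaining genes
  are independent noise;
* the first (tightest) module is the signature: its genes receive a mean
  shift $\delta = 2$ (two noise standard deviations) in the last class,
  making them differential and the module detectable;
* two observation layers: an expression layer (one feature per gene, noise
  sd 0.5) and a methylation-like layer (two features per gene, noise sd
  0.7) whose features map to genes many-to-one; each feature views the
  latent gene value through a uniform(0.5, 1.5) loading plus Gaussian
  noise;
* the methylation-like layer carries 0.2% missing entries. The rate is
  deliberately per-entry and small: with 120 samples a probe survives
  complete-case filtering with probability $0.998^{120} \approx 0.79$, so
  roughly a fifth of probes are lost — the order of magnitude seen when
  complete-case filtering is applied to array data. A rate of a few
  percent per entry would annihilate nearly every probe at this sample
  size, which is not what the filtering step is meant to model.

What the generator does *not* emulate: beta-distributed methylation values,
copy-number segmentation, count noise, batch effects, or correlated
missingness. Passing tests on this generator therefore demonstrate that the
pipeline recovers planted linear-Gaussian structure through the full
cascade — screening, fusion, kernels, label search, modules, signature —
not that it is robust to every artefact of real multi-omics data.

All randomness flows through explicit integer seeds: the generator restores
the caller's RNG state, fold assignments and factorization initializations
are seeded, and the per-type initialization seed is derived from a hash of
the type name so that object-type ordering cannot change results.

# Numerical choices and degenerate inputs

* Constant features are dropped (normalization) or rejected with the gene
  named (adjacency); an all-missing layer errors.
* The trigamma inversion returns the $10^6$ cap when log-variances are
  underdispersed; $d_0 = 0$ reproduces the classical pooled statistics
  exactly.
* The tri-factorization guards its own monotonicity ($10^{-9}$ relative)
  and rejects ranks above the object size.
* Kernel normalization refuses non-positive diagonals naming the sample;
  eigenvalue clipping tolerates $-10^{-8}$ asymmetry.
* The MKL weight loop stops when all quadratic forms are equal (uniform
  weights by symmetry), when backtracking cannot improve the objective, or
  at `max_outer`.
* AUC with an empty class errors; stratified folds are reduced with a
  warning when a side is smaller than the fold count.
* All argmax selections (probes, combinations, modules) carry explicit
  deterministic tie-breaks.

# Problem sizes used by the shipped checks

The test-suite fixtures use 30 x 20 planted factorizations (15000 sweeps),
one hundred random systems of up to 20 x 20 for monotonicity, TOM oracles
up to 15 genes, a 100-120-sample planted kernel set, 120-gene planted
module fixtures, and the default 1000-gene / 120-sample end-to-end study;
these sizes keep every property sharp while a full run of the suite and the
acceptance script stays in the minutes range on a single core. They are the
package's chosen reference conditions, and scale linearly upward for users
with larger cohorts.

# Known limitations

* Non-convexity: tri-factorization and MKL both alternate between convex
  subproblems; different seeds can reach different local optima. The
  objective traces are exposed for inspection.
* The label search refits the MKL classifier per fold per combination;
  with many classes the $O(m^2)$ combinations dominate runtime.
* The tree cut plus membership pruning handles chained noise well in the
  tested regimes but, like every dendrogram-based cut, cannot resolve
  overlapping modules.
* Survival analysis, enrichment analysis and downloading of public
  cohorts are out of scope; the package consumes delimited matrices.
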