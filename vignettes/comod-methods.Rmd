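---
title: "Methods: differential co-expression modules via HO-GSVD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential co-expression modules via HO-GSVD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comod)
```

This vignette is the package's account of its model, its numerical choices,
and the places where the design was genuinely open. It states no empirical
result that the test suite and `scripts/acceptance.R` do not themselves
compute.

## The model

Given expression matrices `D_t` (samples × genes, one per condition, sharing
one ordered gene panel), the workflow looks for groups of genes whose
coordinated expression is a recurring feature of the panel. The joint
factorization is

$$D_t = U_t \Sigma_t V^{\mathsf T}, \qquad t = 1, \dots, T,$$

with one shared right basis $V$. $V$ is defined as the eigenvector matrix of

$$S = \frac{1}{T(T-1)} \sum_{t<r} \left(E_t E_r^{-1} + E_r E_t^{-1}\right),
\qquad E_t = D_t^{\mathsf T} D_t,$$

the pairwise-averaged product of co-expression matrices and their inverses.
Two exact properties anchor the implementation and its tests: when all
$E_t$ coincide, every pair contributes $2I$ and $S = I$; and for
symmetric-positive-definite $E_t$ the eigenvalues of $S$ are real and at
least 1 (for $T = 2$, a generalized eigenpair $E_1 v = \mu E_2 v$ maps to an
$S$-eigenvalue $(\mu + 1/\mu)/2 \ge 1$). Large eigenvalues mark directions
whose co-expression strength differs across conditions; eigenvalue 1 is the
floor shared by directions of equal strength everywhere.

Top eigenvectors of $S$ are then screened for modules: a small minority of
genes with coherent extreme loadings against a diffuse bulk. Each
eigenvector's loadings are standardized and decomposed into a two-component
Gaussian mixture — a large-weight empirical null and a small-weight
component for the co-expressed minority — and each gene receives a
tail-area false-discovery q-value. Genes with $q \le 0.001$ form the
module.

## Centering: the covariance reading

Whether to center genes before forming $E_t = D_t^{\mathsf T} D_t$ is
genuinely open: the formula as written is a cross-product, but the object it
denotes is a covariance matrix, and the uncentered cross-product of
log-scale expression data is dominated by one direction — the shared
mean-expression profile — plus, in the ridged genes≫samples regime,
ridge-amplified discrepancies between per-condition rowspaces. Both bury
co-expression structure. The package therefore defaults to
`center = "gene"` (subtract each gene's mean within a condition), which is
the covariance reading and the only variant under which the planted-module
benchmark below is recoverable; `center = "none"` remains available for the
literal cross-product.

## Rank deficiency and the ridge

With more genes than samples, $E_t$ is singular and $E_r^{-1}$ undefined.
The fix is a relative ridge: $E_t \leftarrow E_t + \varepsilon\,
(\operatorname{trace}(E_t)/p)\, I$ with $\varepsilon = 10^{-6}$ by default.
The scaling by the mean diagonal makes $\varepsilon$ unitless, and the
absolute amount actually added is recorded in the decomposition
diagnostics. The ridge floor has a structural consequence: directions
outside every condition's rowspace sit at eigenvalue ≈ 1, while directions
inside one condition's rowspace but not another's are amplified by the
ratio of signal to ridge. The top of the spectrum is therefore populated by
the strongest per-condition variance directions — which is exactly where
planted module structure surfaces.

In this regime the eigenvalue-1 eigenspace is massively degenerate, and the
eigenvector matrix of the non-normal $S$ is numerically singular, so the
left bases $U_t$ and singular values $\Sigma_t$ (which require solving with
$V$) are not meaningful. `hogsvd(..., compute_u = FALSE)` computes only the
spectrum and right basis — all that module calling needs. With full-rank
panels (samples > genes) the complete factorization is computed, the
reconstruction residual $\|D_t - U_t \Sigma_t V^{\mathsf T}\|_F / \|D_t\|_F$
is reported (tests require < 1e−8), and a condition number of $V$ above
1e12 is an error advising a larger ridge.

Other numerical conventions: inverses are realized as Cholesky solves,
never explicit inversion; eigenvalues are sorted descending with ties
broken by original index; each eigenvector is unit-norm with its
largest-magnitude entry oriented positive (so downstream calls are
invariant to solver sign flips); an exactly diagonal $S$ returns the
coordinate basis ordered by the diagonal; relative imaginary leakage above
1e−8 is an error signalling non-SPD inputs.

## Mixture fit and tail-area FDR

Eigenvector scale is arbitrary (unit-norm columns make a typical loading
$\sim p^{-1/2}$), so loadings are standardized to zero median and unit MAD
before fitting. EM on the signed standardized loadings fits two Gaussian
components, from 10 initializations (5 quantile-spread, 5 random under the
caller's seed), keeping the best log-likelihood; tolerance 1e−8 on the
log-likelihood, at most 500 iterations, and restarts whose weights or
standard deviations collapse are discarded (an error if all collapse). The
null component is the one with the larger weight.

With null parameters $(\mu_0, \sigma_0, w_0)$ and score
$s = |x - \mu_0| / \sigma_0$, the tail-area FDR is

$$q(x) = \frac{w_0 \cdot 2\,(1 - \Phi(s))}
{\max(\widehat F(s),\, 1/p)},$$

where $\widehat F(s)$ is the empirical fraction of genes at least as
extreme. The estimate is clipped to $[0, 1]$ and monotonized (a cumulative
maximum from the most extreme gene downward) so that $q$ never increases
with $s$; the $1/p$ floor stops the single most extreme gene from dividing
by its own rarity. At the null mean the formula gives $q = w_0$ (the tail
fraction is 1), which is its natural maximum. This estimator is
self-contained and deterministic by construction; it follows the
GMM-then-tail-area recipe rather than reproducing any particular package's
density estimator.

Two calibration facts are asserted by the tests: on a 95/5 mixture of
N(0, 0.05²) and N(0.8, 0.05²) with 1000 genes the weights are recovered to
±0.02 and the 50 planted genes receive the 50 smallest q-values, all below
0.001; and on pure Gaussian loadings the module is empty at $q \le 0.001$
in at least 95% of 100 seeds.

## Coherence refinement of module calls

The top eigenvalues of $S$ typically arrive in near-degenerate clusters
(several contrast directions per underlying module, with overlapping
magnitudes across modules). Eigenvectors of a non-normal matrix within such
clusters mix the underlying subspaces, so the bare per-eigenvector call —
every gene with $q \le 0.001$ — frequently returns the *union* of several
modules on each of several eigenvectors. The calls are correct as a set
(planted genes in, background out) but not separated.

`call_all_modules()` therefore refines by default: the union of called
genes is partitioned by average-linkage hierarchical clustering on
$1 - \bar{|\rho|}$, where $\bar{|\rho|}$ is the mean across conditions of
the absolute expression correlation, cut so that groups maintain mean
$|\rho| \ge 0.5$; coherent groups are then matched to the calling
eigenvectors greedily by mean standardized loading score, one group per
eigenvector until every group is used once (reuse afterwards). The
refinement is deterministic, uses only quantities the pipeline already has,
and reduces to the bare calls when they are already coherent;
`refine = FALSE` disables it, and the raw calls plus their pairwise overlap
statistics are always kept as attributes. Its single tunable,
`coherence_cut = 0.5`, sits in a wide margin: planted modules have within-
module $|\rho| \approx 0.85$ under the reference conditions versus
$\approx 0.07$ between unrelated genes.

## Patient grouping for survival

NMF (rank k, Lee–Seung multiplicative updates, 20 restarts, best Frobenius
objective kept; the objective trajectory is recorded and asserted
non-increasing) represents the module-gene × patient matrix, shifted
non-negative by subtracting its minimum since log-scale expression can be
negative. Patients are then clustered by k-means on their metagene
coefficient vectors — the columns of $H$, scaled by the norms of the
matching $W$ columns to resolve the factorization's scale ambiguity. A raw
arg-max over metagene coefficients is not scale-identifiable: when one
metagene captures the shared expression profile (the dominant direction of
min-subtracted log data), every patient's largest coefficient is that
shared metagene and the grouping collapses, while the coefficient *vectors*
still separate cleanly. Single-gene modules skip NMF for k-means on the
gene's values. The default k = 2 is the minimal two-group Kaplan–Meier
comparison; the rank-selection question (consensus clustering, cophenetic
criteria) is deliberately out of scope.

Group survival differences use the standard k-group log-rank chi-square;
per-gene prognostic scans use univariate Cox proportional-hazards models
with Efron tie handling and the raw (uncorrected) Wald p, flagging
non-converged fits as NA rather than dropping them. Patients present in
only one of the expression/survival tables are dropped with a count, never
imputed, and patients with repeated samples are excluded entirely at load
time.

## The synthetic benchmark: what it does and does not emulate

The generators produce the reference study conditions asserted by the
acceptance tests:

* **Counts** (DE stage): 8 conditions, 20 tumor vs 20 normal samples, 200
  genes; gene means log-normal (meanlog = log 100, sdlog = 1), NB
  dispersion 0.1; 40 planted DE genes at log2 fold-change 2, each affecting
  a random subset of ≥ 4 conditions. The 200-gene panel keeps the rank-sum
  backend's 3,200-test sweep fast while leaving ~80% of genes null.
* **log2-FPKM** (decomposition stage): 4 conditions × 80 tumor samples ×
  1000 genes; per-gene baselines Uniform(2, 8) — a realistic log2-FPKM
  range — shared across conditions; background noise sd 0.3; two planted
  modules of 40 and 30 genes with loadings Uniform(0.6, 1) fixed across
  conditions and per-sample factors N(0, 1) drawn independently per
  condition. The shared object is the loading *pattern*, matching the
  shared-V / distinct-U structure of the factorization. Pure-noise
  calibration panels use the same shape at 400 genes — enough for the
  empirical-null machinery while keeping 20 replicates inside the test
  budget.
* **Survival**: exponential event times with hazard
  $h_0 \exp(\beta \cdot \text{metagene})$, $h_0 = 0.01/\text{day}$,
  $\beta = 1$; the metagene is the mean expression of the hazard-driving
  module's genes, centered across each condition's samples so that $h_0$ is
  the hazard of an average patient (without centering the baseline would be
  scaled by an arbitrary $e^{\beta \cdot 5}$). Censoring times are
  Uniform(0, u) with u solved numerically for a ~30% censored fraction.
* **Edge lists**: planted modules wired as noisy cliques (within-module
  edge retention 0.8) over an Erdős–Rényi background (edge probability
  0.002).

What the generators deliberately do not emulate: library-size and batch
effects, tumor purity, correlated background co-expression, per-condition
sample-size imbalance, non-proportional hazards, and gene-level dependence
of NB dispersion. Passing the benchmark therefore shows the machinery is
correct and calibrated under its own model; it does not certify performance
on real tumor panels, where the module signal is weaker and confounded.

## Problem sizes and determinism

The test suite runs the module-recovery benchmark at 5 fixed seeds and the
noise calibration at 20, the log-rank permutation calibration at 1000
permutations of a 200-patient cohort, and the Cox null calibration at 500
genes — sizes chosen so the full suite completes in a few minutes while the
binomial margins stay meaningful. Every random stage takes an explicit
seed; `run_pipeline()` derives all stage seeds from one master seed, and
reruns are byte-identical in every gene list and report (the manifest
additionally records wall times, which are not part of the determinism
contract).

## Known limitations

* The refinement step assumes modules are internally correlated in the
  *data*; a "module" defined only by loadings with no expression coherence
  (not producible by this generator) would not be separated.
* With exactly one selected eigenvector (`k = 1`) superposed modules cannot
  be demixed by profile information; the coherent group most aligned with
  the eigenvector is returned, which is the strongest module under the
  reference conditions.
* The greedy-modularity sub-module clustering is a deterministic stand-in
  for interaction-network plugins whose algorithms are unspecified;
  partitions agree with exhaustive modularity maximization on small graphs
  but carry the usual resolution limits of modularity on large ones.
* The NMF rank and the number of patient groups are user choices (default
  2); no model-selection machinery is provided.
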