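# comod

Differential co-expression gene modules across many conditions via a
higher-order generalized singular value decomposition (HO-GSVD), with
module-based survival stratification.

## The problem

Most co-expression analyses look at one condition at a time. When the same
genes are profiled across many conditions — say bulk RNA-seq of several
cancer types — the interesting structure is often *shared*: groups of genes
whose coordinated expression recurs across conditions, and whose expression
level stratifies patient survival. `comod` implements a complete workflow
for finding such modules and testing their prognostic value:

1. **Consensus differential expression.** Candidate genes are selected by a
   three-step rule: a gene must be significantly differentially expressed
   (adjusted p < 0.05) in at least *m* of *T* conditions under one method;
   the per-method sets are intersected across methods; redundant gene IDs
   are mapped and de-duplicated. A built-in rank-sum backend makes the
   pipeline self-contained; tables from external tools (limma, edgeR, DESeq,
   SAMseq) are imported through an adapter.
2. **HO-GSVD.** The T gene-aligned matrices `D_t` (samples × genes) are
   jointly factorized as `D_t = U_t Σ_t Vᵀ` with one shared right basis V.
   V solves the eigensystem of

   ```
   S = 1/(T(T−1)) Σ_{t<r} (E_t E_r⁻¹ + E_r E_t⁻¹),   E_t = D_tᵀ D_t
   ```

   where `E_t` is the gene × gene co-expression (covariance) matrix of
   condition t. For SPD inputs every eigenvalue of S is real and ≥ 1, and S
   is exactly the identity when all `E_t` coincide. In the usual regime with
   many more genes than samples, `E_t` is singular; a relative ridge
   `ε·(trace(E)/p)·I` (default ε = 1e−6) keeps the eigensystem well-posed.
3. **Module calling.** Loadings of each top eigenvector of S are
   standardized (median/MAD), decomposed into a two-component Gaussian
   mixture (a large-weight empirical null plus a small-weight co-expressed
   component), and converted to tail-area false-discovery q-values; genes
   with q ≤ 0.001 form the module. Because near-degenerate top eigenvalues
   of the non-normal S mix module subspaces, called genes are additionally
   partitioned into coherent co-expression groups and matched back to
   eigenvectors (see the methods vignette).
4. **Network dissection.** Modules are projected onto a user-supplied
   functional-interaction edge list, optionally extended with linker genes,
   clustered into sub-modules by greedy modularity, and scanned for hub
   genes (≥ 10 neighbors).
5. **Survival analysis.** Tumor patients are grouped by module-gene
   expression via non-negative matrix factorization (k-means for single-gene
   modules), groups are compared with the Kaplan–Meier log-rank test, and
   each gene gets a univariate Cox proportional-hazards Wald p-value.

A fully seeded synthetic-data generator produces every input with known
ground truth (planted DE genes, planted latent-factor modules, module-driven
hazards, module-wired interaction networks), so the whole pipeline is
testable end to end.

## Worked example

The demo simulates the reference study conditions (8 cancer-like conditions
of 20 tumor / 20 normal NB count samples for the DE stage; 4 conditions of
80 samples over 1000 genes with two planted modules of 40 and 30 genes for
the decomposition; module-1-driven exponential survival with ~30%
censoring), then runs every stage:

```r
library(comod)
res <- run_demo(out_dir = "demo_run", seed = 1)
#> DE consensus Jaccard vs truth: 1
#> Module recovery (Jaccard per planted module): 1, 1
#> Connected fraction of best module in FI network: 1
#> Median log-rank p, eigenvector_01: 3.49e-05
#> Median log-rank p, eigenvector_02: 0.575
#> Median log-rank p, random_control: 0.289
```

Reading the output: the consensus DE stage recovered exactly the planted
shared-DE genes (Jaccard 1); both planted co-expression modules were
recovered perfectly from the top eigenvectors (Jaccard 1 and 1); every gene
of the best module is connected in the synthetic interaction network; and
NMF grouping on the hazard-driving module separates patients with a median
log-rank p of 3.5e−05 across the four conditions, while the second
(hazard-neutral) module and a size-matched random gene set stay
non-significant — the stratification signal is specific, not an artifact of
grouping.

Individual stages compose with the pipe:

```r
cfg   <- module_sim_config(seed = 7)
panel <- simulate_fpkm_panel(cfg)
fit   <- hogsvd(panel$matrices, ridge = 1e-6, center = "gene", compute_u = FALSE)
tidy(fit)          # eigenvalue spectrum as a tibble
mods  <- call_all_modules(fit, panel$matrices, k = 10, q_cutoff = 0.001, seed = 1)
tidy(mods)         # one row per (eigenvector, gene) with loading and q
```

`autoplot()` methods exist for `hogsvd` fits (scree plot), module sets
(loading/q plots), sub-module partitions and prognosis reports.

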