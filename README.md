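# fusemkl

Multi-omics data fusion and gene-signature detection for cohorts profiled on
several molecular platforms (gene expression, DNA methylation, exon
expression, pathway activity, copy number) over a shared, class-labelled
sample set. The package is aimed at computational biologists who want a
single reproducible cascade from raw per-layer matrices to an evaluated gene
signature, with every stage also usable on its own.

## What it computes

Given layers X^(1), ..., X^(L) (features x samples) and class labels:

1. **Screening** — per-layer empirical-Bayes moderated statistics: pooled
   variance s² is shrunk to the posterior s̃² = (d₀s₀² + d s²)/(d₀ + d)
   with (d₀, s₀²) fitted by moment matching on log s²; moderated t (2
   classes) or moderated F (m > 2) p-values below α keep a feature, the
   minimum-p probe represents each gene, and the per-layer gene sets are
   unioned.
2. **Fusion** — the layers become a relational block system over object
   types (genes, samples, per-layer feature spaces) fitted by penalized
   non-negative tri-factorization, minimizing
   Σ ||R_ij − G_i S_ij G_jᵀ||² + Σ_p tr(G_pᵀ τ_p G_p) with G_p ≥ 0, via
   exact least-squares updates for S and monotone multiplicative updates
   for G.
3. **Kernels** — each reconstructed relation R̂ = G_i S_ij G_jᵀ gives a
   sample kernel K = R̂ᵀR̂, cosine-normalized, box-smoothed and projected
   back to positive semidefinite.
4. **MKL** — a hinge-loss soft-margin multiple kernel learning classifier:
   maximize the margin θ subject to D_SVM(K_p, α) ≥ θ − ζ_p, paying
   π·Σζ_p for kernel-wise slack (feasible for π ≥ 1/P).
5. **Label search** — all one-vs-one and one-vs-rest class combinations
   are scored by cross-validated Mann-Whitney AUC of the MKL classifier;
   the argmax combination is kept.
6. **Modules and signature** — on the winning two-group sub-data:
   adjacency |PCC|^β (β from the scale-free topology fit), topological
   overlap TOM(i,j) = (Σ_v X_iv X_jv + X_ij)/(min(k_i, k_j) − X_ij + 1),
   average-linkage clustering with a dynamic tree-style cut plus
   membership pruning; the module with maximal mean pairwise Pearson
   correlation is elected the signature and evaluated by a
   nearest-shrunken-centroids (PAM) classifier under 10 x 10-fold
   stratified cross-validation.

A seeded synthetic generator (`sim_config()` / `simulate_multiomics()`)
plants equicorrelated gene modules, a class-shifted signature module and
multi-probe noisy observation layers with known ground truth, so the entire
cascade is testable without external data.

## Worked example

```r
library(fusemkl)

sim <- simulate_multiomics(sim_config(), seed = 1)   # 2 layers, 3 classes
fit <- fusemkl(sim$layers, sim$annot, seed = 1)
print(fit)
```

```
Multi-omics fusion fit (fusemkl)
  layers: expression, methylation 
  screened gene union: 156 genes
  best combination: favorable vs poor (AUC = 1.0000) 
  modules: 1 | signature: turquoise (60 genes, mean PCC = 0.7455) 
  PAM mean AUC: 0.9441 
```

The screened union keeps the 60 planted signature genes plus the expected
α-level false positives; the label search identifies the favorable-vs-poor
contrast (the planted shift separates exactly those classes, so its pooled
out-of-fold AUC reaches 1); the tree cut recovers the planted module as the
turquoise signature, whose mean within-module correlation 0.7455 reflects
the planted equicorrelation 0.7 plus the class shift. `summary(fit)` prints
the full combination table, module table, validity indices and the PAM
means with standard deviations over repeats:

```
PAM cross-validated evaluation:
      metric   mean       sd
 sensitivity 0.9425 0.012076
 specificity 0.8475 0.007906
   precision 0.8607 0.007088
         npv 0.9366 0.012707
    accuracy 0.8950 0.008740
         auc 0.9441 0.006543
```

`predict(fit, newexpr)` classifies new samples from their signature-gene
expression; `plot(fit)` shows the factorization objective trace, the
scale-free fit curve, module sizes and per-combination AUCs;
`run_report(fit, "report.json")` writes the machine-readable run report.

A thin command-line wrapper over the same functions lives in
`inst/scripts/run_pipeline.R` for delimited on-disk matrices:

```sh
Rscript inst/scripts/run_pipeline.R \
    --layers expr.tsv,meth.tsv --mappings none,meth_map.tsv \
    --annot classes.tsv --out results/ --seed 1
```

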