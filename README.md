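# iscclust

Information-incorporated sparse convex clustering for disease subtyping
from multi-omics data.

## The problem

Clustering patients into disease subtypes from omics matrices faces two
obstacles: only a minority of features carry the disease-relevant
structure, and the data usually contain *secondary* cluster patterns
driven by non-disease biology that pull ordinary methods toward the
wrong partition. `iscclust` implements a convex clustering procedure
that (i) selects features while clustering and (ii) encodes prior
literature evidence — how often each feature is co-mentioned with the
disease in published abstracts — as per-feature penalty weights, so that
well-supported features are cheaper to keep.

## The model

Standardized omics blocks are concatenated into X (n samples x p
features) and a center matrix U is estimated by minimizing

    1/2 Σ_j ||x_j − u_j||²
      + γ₁ Σ_{(i₁,i₂)∈E} w_l ||U_{i₁·} − U_{i₂·}||₂      (fusion)
      + γ₂ Σ_j z_j ||u_j||₂                              (selection)

* E is the union k-nearest-neighbour graph with Gaussian kernel weights
  `w_l = exp(−φ · ||X_{i₁·} − X_{i₂·}||² / p)` (φ = 0.5, d = 5 by
  default); coinciding rows of U define clusters.
* `z_j ∈ {0.5, 1}` are the prior weights: 0.5 when the feature's
  publication co-occurrence count exceeds the 90th percentile of all
  counts, 1 otherwise. Setting every `z_j = 1` recovers plain sparse
  convex clustering (SCC).
* The objective is convex: the solution is unique and
  initialization-free. It is minimized by AMA dual ascent with exact
  group soft-thresholding (features are removed by exact zeros).
* (γ₁, γ₂) are tuned by an alternating search against known
  cluster/feature counts, or by cluster- and feature-level BIC when the
  counts are unknown.

The package also ships the reference simulation designs (S1/S2/S3:
spherical clusters and interlocking half-moons, each with an embedded
confounding "noisy" cluster pattern), controlled corruption of the prior
weights, replicate study drivers, and the evaluation metrics (adjusted
Rand index, FNR, FPR, Matthews correlation coefficient).

## Worked example

```r
library(iscclust)

# one simulated S1 dataset: 80 samples, 4 subtypes, two omics blocks,
# 60 informative / 40 confounder / 200 background features
sim <- simulate_dataset(simulation_spec("S1", seed = 1))
cd  <- concatenate_blocks(lapply(sim$blocks, standardize_block,
                                 scale = "feature"))
E   <- build_edge_set(cd, d = 5, phi = 0.5)

# tune against the known counts (K = 4 clusters, 60 informative features)
tr <- tune_iscc(cd, E, sim$z_given,
                gamma1_grid = default_gamma1_grid(cd, 10),
                gamma2_grid = default_gamma2_grid(cd, 10),
                mode = "known", K = 4, p_target = 60,
                control = solver_config(max_iter = 1500, tol = 1e-4))
tr
#> iscc_tune (known): gamma1 = 2.724, gamma2 = 8.944 after 4 round(s)
#> iscc_fit: gamma1 = 2.724, gamma2 = 8.944 | 7 clusters, 60/300 features
#>   selected | converged in 761 iterations

adjusted_rand_index(tr$fit$labels, sim$true_labels)
#> [1] 0.9520599
sm <- selection_metrics(tr$fit$selected, sim$informative_mask)
unlist(sm[c("fnr", "fpr", "mcc")])
#> fnr fpr mcc
#>   0   0   1
```

The tuned fit recovers the four subtypes (ARI 0.95 on this replicate;
the seven reported clusters are the four subtypes plus three stray
singletons, which the tuning's cluster count discounts) and selects
exactly the 60 informative features (FNR = FPR = 0, MCC = 1). With all
weights forced to 1 (plain SCC) the same pipeline is pulled toward the
confounder's coarse partition (ARI ≈ 0.71 on average).

A command-line interface wrapping the same functions (subcommands
`weights`, `fit`, `tune`, `simulate`, `evaluate`) is installed at
`inst/cli/iscc`; see `?iscc_main`.

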