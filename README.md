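# gtomnet

Gene coexpression network analysis for two-group tumor cohorts:
eigenvalue-shrinkage denoising (RECODE), thresholded TF correlation
networks, generalized topological overlap (GTOM), Ward module detection
with a composite core/bridge total score, and per-module patient-network
separation scoring.

## What problem this solves

When two disease states of the same tissue — the motivating case is
metastatic stage-4 neuroblastoma versus its spontaneously regressing 4S
variant — show no reproducible single-gene differences, the discriminating
signal may sit in the *topology* of the transcription-factor coexpression
network. Finding it requires (i) noise control that does not simply discard
low-expression genes, and (ii) a node-similarity measure that looks beyond
direct network neighbors. This package implements that pipeline end to end,
together with a planted-module synthetic generator so that every stage can
be validated against ground truth.

## The statistics at the core

**Denoising.** For a genes-by-samples matrix with PCA spectrum
λ₁ ≥ … ≥ λ_D (D = min(n−1, d)), the retained eigenvalues are reduced by
their trailing means, the rest zeroed:

    λ̃ᵢ = λᵢ − (1/(D−i+1)) Σⱼ₌ᵢ₊₁..D λⱼ   (i ≤ ℓ),     λ̃ᵢ = 0   (i > ℓ),

and each principal direction rescaled by √(λ̃ᵢ/λᵢ). Means are preserved
exactly; total variance can only shrink.

**GTOM(k).** With N(i) the set of nodes reachable from i within k+1 steps,

    tᵢⱼ = ( |N(i) ∩ N(j)| + aᵢⱼ ) / ( min(|N(i)|, |N(j)|) + 1 − aᵢⱼ ),

so nodes sharing multi-step neighborhoods score high even without a direct
edge. Modules are cut from the dissimilarity 1 − t by Ward linkage.

**Scores.** `gtom_score` is the mean overlap between two node groups;
`gtom_diff(A, B)` the within-A minus cross score; the total score
S = (1/d_C) Σ_{i<j} rᵢrⱼ { Gᵢᵢ Gⱼⱼ (1−Gᵢⱼ) + Gᵢᵢ (1−Gⱼⱼ) Gᵢⱼ } rewards
partitions with several distinct cores plus weakly self-connected
subnetworks attached to a core, and — together with the SD of cluster
sizes — selects the correlation cutoff and GTOM order.

**Patient separation.** For each TF module, a Spearman correlation network
*between patients* is thresholded, and the group-4 within-density minus the
cross-density quantifies how well the module separates the groups, as a
curve over the cutoff.

## Worked example

```r
library(gtomnet)

sim <- generate_planted_expression(synthetic_spec(seed = 1))
res <- run_full_pipeline(run_config(
  sim$expression, recode = TRUE, cutoff = 0.7, k = 2, n_clusters = 5,
  groups = sim$truth$patient_group_labels,
  patient_cutoffs = seq(0.5, 0.95, 0.05)))
print(res)
#> gtomnet pipeline result
#>   genes x samples: 1500 x 148
#>   RECODE ell: 146
#>   cutoff: 0.7  GTOM order: 2
#>   clusters: C1=610, C2=394, C3=291, C4=204, C5=1
#>   total score: 0.009221  size SD: 201.8

round(res$cluster_scores, 3)
#>       C1 C2    C3 C4 C5
#> C1 0.999  0 0.873  0  0
#> C2 0.000  0 0.000  0  0
#> C3 0.873  0 0.998  0  0
#> C4 0.000  0 0.000  1  0
#> C5 0.000  0 0.000  0  1

sapply(res$separation[!sapply(res$separation, is.null)],
       function(cv) max(cv$separation, na.rm = TRUE))
#>    C1    C2    C3    C4
#> 0.071 0.098 1.000 0.002
```

Reading the output: `C1` and `C4` are the two strongly self-connected cores
(within-cluster overlap 0.999 and 1), `C3` is a weakly bridging module
strongly attached to `C1` (cross overlap 0.873), and `C2` is the pool of
unconnected TFs (overlap 0). The separation peaks show that only `C3` — the
module planted as group-differential — separates the two patient groups
(score 1.0, i.e. the stage-4 patients are fully interconnected at a cutoff
where no stage-4-to-4S edges survive); cores and the isolated pool hover
near 0. Against the planted labels this partition has an adjusted Rand
index of 0.92.

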