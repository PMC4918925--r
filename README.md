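# tractnet

Structural brain-network analysis from diffusion tractography, built for
two-group connectome studies — the motivating design is poorly controlled
type 2 diabetes versus matched healthy controls, where the question is
whether chronic hyperglycemia degrades the *integration* of the white
matter network (global efficiency, characteristic path length) while
leaving its *segregation* (clustering, modularity) intact, and whether
glycemic markers (HbA1c, fasting plasma glucose) track the network
measures.

The package covers the full pipeline:

1. **Diffusion tensors** — log-linear least-squares fit of
   S_k = S0·exp(−b·gᵀDg); scalar maps FA, MD, AD, RD from the eigenvalues
   (`fit_tensor()`, `tensor_scalars()`).
2. **Deterministic tractography** — 20 random seeds per voxel,
   nearest-neighbour principal-eigenvector Euler tracking with FA > 0.2
   and per-step turns < 30° (`track_all()`); TRK and TSV streamline IO.
3. **Connectome construction** — streamline counts per region pair,
   pairs with < 3 streamlines discarded, fiber-density weights
   (count / whole-brain total), a 144×144 weighted symmetric matrix
   (`build_connectome()`).
4. **Graph measures** — weighted clustering (Onnela), Louvain modularity
   Q, characteristic path length L and global efficiency E over
   d = 1/w distances; γ = C/⟨C_null⟩, λ = L/⟨L_null⟩ and small-worldness
   σ = γ/λ against degree- and weight-preserving Maslov–Sneppen null
   ensembles (`network_metrics()`, `normalize_metrics()`).
5. **Statistics** — 10,000-permutation two-sample tests with BH-FDR
   across the five global measures, and partial correlations of each
   measure with HbA1c/FPG controlling age, sex, connection count and
   strength (`analyze_cohort()`).
6. **Synthetic cohorts** — a calibrated Watts–Strogatz-style generator
   (`generate_cohort()`) reproducing the study's printed group summaries
   (E = 0.63/0.59 ×10⁻³, λ = 1.41/1.52) and injected glycemia
   correlations, so every stage is testable without imaging data.

Everything is tibble-first: cohorts are tibbles with a `connectome`
list-column, results carry `tidy()`/`glance()` methods and `autoplot()`
figures, and `run_pipeline()` plus a thin CLI
(`inst/pipeline/tractnet-cli.R`) orchestrate YAML-configured runs.

## Worked example

```r
library(tractnet)

cohort   <- generate_cohort(cohort_config(), seed = 7)   # 20 + 20 subjects
metrics  <- compute_network_metrics(cohort, n_null = 100, seed = 7)
analysis <- analyze_cohort(metrics, n_perm = 10000, seed = 7)
analysis
```

```
Group comparisons:
  measure mean_control sd_control mean_patient sd_patient difference         p
1 gamma       8.49      0.220         8.72      0.178     -0.231     0.00150
2 Q           0.709     0.0119        0.719     0.00739   -0.0104    0.00170
3 lambda      1.42      0.0768        1.52      0.0805    -0.102     0.000300
4 E           0.000631  0.0000288     0.000587  0.0000238  0.0000444 0.0001000
5 sigma       6.00      0.256         5.75      0.282      0.246     0.00600

Partial correlations (controlling age, sex, n_edges, total_strength):
   measure covariate       r       p     n       q
 3 lambda  hba1c      0.471  0.00376    40 0.00939
 4 E       hba1c     -0.516  0.00126    40 0.00632
 8 lambda  fpg        0.437  0.00770    40 0.0174
 9 E       fpg       -0.422  0.0104     40 0.0174
 ...
```

Reading it: the patient group shows the integration deficit the design
targets — global efficiency is lower (0.587 vs 0.631 ×10⁻³, permutation
p = 1×10⁻⁴) and the normalized path length longer (1.52 vs 1.42,
p = 3×10⁻⁴) — while both groups stay in the small-world regime
(σ ≈ 5.7–6.0, i.e. γ ≫ 1 with λ ≈ 1.4). Higher HbA1c goes with lower
efficiency (partial r = −0.52) and longer paths (r = +0.47) after
adjusting for age, sex and connection count/strength. This cohort is
synthetic: the group effect and the HbA1c/FPG–efficiency correlations are
injected at the calibrated defaults, so the run demonstrates that the
pipeline *recovers* what was put in at the study's scale (see the methods
vignette, `vignettes/network-methods.Rmd`, for what that does and does
not establish).

`autoplot(analysis$group_comparisons)` and
`autoplot(analysis$correlations)` draw the per-measure box plots and the
measure–glycemia scatter grid.

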