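---
title: "Structural brain-network analysis: models, calibration and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural brain-network analysis: models, calibration and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tractnet)
```

tractnet implements a complete structural connectome analysis for a
two-group diffusion-MRI study design — poorly controlled type 2 diabetes
versus matched healthy controls — from diffusion tensors through
deterministic tractography, weighted connectome construction,
graph-theoretic global measures with null-model normalization, and finally
permutation group tests and glycemia–network partial correlations. Because
no subject-level imaging data are available, a calibrated synthetic-cohort
generator stands in for the MRI cohort; this vignette explains each model,
the tunable parameters, the calibration, and what the synthetic results do
and do not establish about real data.

## The diffusion model

Each voxel carries a symmetric diffusion tensor $D$ (mm²/s). Signals follow
the monoexponential model $S_k = S_0\,e^{-b_k\,g_k^{\top} D\, g_k}$, and
`fit_tensor()` estimates the seven unknowns $(\ln S_0, D)$ by ordinary
least squares on $\ln S_k$ — the conventional log-linear baseline, chosen
because no more elaborate estimator is needed for the pipeline's purposes.
Requirements: at least seven measurements including one $b=0$; voxels with
non-positive signals are flagged invalid rather than fitted. From the
eigenvalues $\lambda_1 \ge \lambda_2 \ge \lambda_3$ (negatives from noisy
fits clamped to zero, with a flag), `tensor_scalars()` computes

* MD $= (\lambda_1+\lambda_2+\lambda_3)/3$ (mean diffusivity),
* AD $= \lambda_1$ and RD $= (\lambda_2+\lambda_3)/2$,
* FA $= \sqrt{3/2}\,\sqrt{\sum_i(\lambda_i-\text{MD})^2}\big/\sqrt{\sum_i \lambda_i^2} \in [0,1]$,
  defined as 0 for an all-zero tensor.

## Tractography

`track_all()` performs whole-volume deterministic tracking: 20 random
seeds per masked voxel, bidirectional Euler integration along the
principal eigenvector of the *nearest-neighbour* voxel tensor, with the
eigenvector sign chosen to continue the previous heading. Propagation
stops when local FA drops to 0.2 or below, when a single step turns by 30°
or more, or at the volume boundary; streamlines shorter than two steps are
discarded. Numerical choices, all testable by construction: the step is
half the smallest voxel edge; the turn threshold is applied per step
(whether the original tool applies it per step or cumulatively is not
documented; per-step is the implemented reading); nearest-neighbour lookup
keeps the geometry exactly analysable on piecewise-constant phantoms.

## Connectome construction

With a parcellation of $N = 144$ regions, an edge's streamline count is
the number of streamlines whose two *terminal* voxels fall in the two
regions (background or same-region terminals are discarded). Pairs with
fewer than 3 streamlines are zeroed — the standard guard against
false-positive connections — and surviving counts are divided by the total
streamline count of the whole-brain set, *including* streamlines later
discarded, giving fiber-density weights. That denominator follows the
literal reading of "number of whole fiber tracts in the brain" and is
stated explicitly so tests can be exact.

## Global network measures

All measures operate on the weighted matrix with the distance transform
$d_{ij} = 1/w_{ij}$ (the Brain Connectivity Toolbox convention for
fiber-density weights; fiber densities are used as-is, which is why
efficiencies come out at the $10^{-3}$ scale):

* **Global efficiency** $E$: mean over ordered pairs of $1/d_{ij}$ with
  $1/\infty = 0$; robust to disconnected pairs and linear in the weights,
  $E(sW) = sE(W)$.
* **Characteristic path length** $L$: mean over *reachable* pairs;
  unreachable pairs are excluded and counted.
* **Clustering** $C$: Onnela's weighted per-node coefficient (geometric
  mean of triangle weights, max-normalized), averaged over nodes. Chosen
  as the weighted default of the reference toolbox so the normalized
  $\gamma$ is reproducible; invariant to uniform weight scaling.
* **Modularity** $Q$: weighted Newman modularity maximized by Louvain with
  100 seeded restarts on permuted vertex orders, best-of, ties to the
  first found.

Normalized measures divide by null means over degree-preserving
Maslov–Sneppen rewired graphs in which weights travel with edges, so node
count, degree sequence and the weight multiset are preserved exactly:
$\gamma = C/\langle C_{\text{null}}\rangle$,
$\lambda = L/\langle L_{\text{null}}\rangle$, small-worldness
$\sigma = \gamma/\lambda$ (an identity held to machine precision). The
reference analysis used 1000 nulls per subject; tractnet defaults to 100,
which estimates the null means to about 1% (their coefficient of variation
is ~1%, so the standard error at 100 nulls is ~0.1%) — negligible against
between-subject spread. Each subject gets an independent null ensemble
with a seed derived from the cohort seed and subject index, so results do
not depend on evaluation order. Ten swap attempts per edge is the standard
mixing heuristic.

## Statistics

Group differences use two-sample permutation tests on the difference of
group means: 10,000 uniform label permutations, two-sided, with add-one
smoothing $p = (1 + \#\{|d^*| \ge |d|\})/(1 + n_{\text{perm}})$ so $p$ is
never zero. Benjamini–Hochberg FDR correction is applied across the family
of five global measures ($\gamma$, $Q$, $\lambda$, $E$, $\sigma$).
Associations with HbA1c and FPG are partial correlations: both variables
are residualized by least squares on an intercept, age, sex, the number of
connections, and total connection strength; $t = r\sqrt{(n-2-k)/(1-r^2)}$
on $n-2-k$ df, two-sided, with BH-FDR within each glucose variable's
family of five measures. Correlations default to the whole cohort (both
groups), switchable by a `subset` argument. Tests are two-sided throughout
since the reported findings are directional but no sidedness is stated.

## The synthetic cohort and its calibration

`generate_cohort()` emulates the study conditions: two groups of 20
subjects, 144-node weighted symmetric connectomes, ages uniform on 50–59
years (matching the tightly matched mid-50s cohort), 9 males per group of
20. Each connectome is a Watts–Strogatz-style weighted graph: a ring
lattice with 12 neighbours per node, each edge independently rewired to a
random shortcut with a group-specific probability; integer streamline
counts are log-normal (meanlog $\log 30$, sigma 1 — whole-brain totals in
the tens of thousands, and a natural tail below the ≥3-count threshold so
the edge filter is genuinely exercised; the count distribution is a
modeling choice, as no real distribution is documented), converted to
fiber densities and multiplied by a group weight scale.

Two analytic/numerical calibrations pin the generator to the published
group summaries:

* `calibrate_weight_scale()` uses the exact linearity $E(sW) = sE(W)$:
  $s = E_{\text{target}}/E_{\text{base}}$.
* `calibrate_shortcut_prob()` bisects the rewiring probability until the
  probe-ensemble mean $\lambda$ hits its target, evaluating $\lambda$ with
  a deliberately independent coarse oracle (R Floyd–Warshall distances and
  plain R edge swaps) so the calibration cannot simply confirm the
  production metric path.

The shipped defaults were fixed by this procedure once: shortcut
probabilities 0.043 (control) and 0.0305 (patient) give ensemble
$\lambda \approx 1.41$ and $1.52$; weight scales 1.156 and 1.123 give
ensemble $E \approx 0.63\times10^{-3}$ and $0.59\times10^{-3}$. Emergent,
uncalibrated properties land close to the published segregation values
($\gamma \approx 8$, $Q \approx 0.7$, $\sigma \approx 5.8$), which is a
pleasant property of the lattice-with-shortcuts family rather than a fit.

Glucose covariates are injected with `generate_covariate()`:
$g = \rho\,z(m) + \sqrt{1-\rho^2}\,z(\varepsilon)$, rescaled to the
requested mean and sd (HbA1c 8.3 ± 2.5%, FPG 7.6 ± 2.5 mmol/L — pooled
two-group scales). When confounds are supplied, metric and noise are first
residualized on them, so the *partial* correlation the analysis reports is
the targeted quantity; otherwise the strong efficiency–strength coupling
would shrink recovered partial correlations below target. Cohort defaults
inject HbA1c at $\rho = -0.53$ and FPG at $-0.41$ against per-subject
efficiency; the positive HbA1c–$\lambda$ association then emerges through
the negative E–$\lambda$ coupling rather than a second injection.

## Problem sizes used by the test suite and acceptance script

Oracle-equivalence checks run 200 random graphs of ≤12 nodes against
Floyd–Warshall, triangle-enumeration and exhaustive-partition oracles.
Calibration recovery re-derives the control calibration with the coarse
oracle (30 nulls × 6 probes per bisection step) and verifies 20-subject
ensembles with 100 nulls per subject. Correlation recovery averages 200
replicates of 40 subjects; for the λ-based target the 200 replicates are
structured as 25 independent cohorts × 8 independent covariate injections,
because per-subject λ normalization dominates the cost — the mean
recovered r estimates the same quantity either way. These sizes estimate
each reported mean to well within the between-replicate spread.

## Degenerate inputs and numerical corner cases

Edgeless graphs: modularity errors; all-zero matrices: $E = 0$, $C = 0$,
path length errors (no finite pair). Triangle-free graphs leave
$\langle C_{\text{null}}\rangle = 0$ and $\gamma$ undefined — an error, with
`compute_network_metrics(normalize = FALSE)` available for such toys.
Graphs with no legal double-edge swap (e.g. a triangle) are returned
unchanged with a warning. Noise-free degenerate cohorts (zero metric
variance) draw glucose covariates independently instead of failing.
Negative fitted eigenvalues are clamped to zero and flagged so FA stays in
$[0,1]$.

## What passing tests do and do not show

The generator reproduces the *statistical skeleton* of the study — group
sizes, measure means and spreads, covariate associations, small-world
regime — not brain anatomy. Real connectomes have heterogeneous degree and
strength profiles, community structure aligned with anatomy, and
measurement noise from registration and tractography biases; none of that
is modeled (no scanner artifacts, motion, eddy currents, or T1
segmentation). One known coupling: group-specific shortcut probabilities
also shift weighted clustering, so the calibrated defaults produce a small
group difference in $\gamma$ (absent from the published segregation
results, and in the opposite direction); segregation neutrality holds, and
is tested, when clustering parameters are equal across groups.
Consequently, passing tests establish that the *methods* — metrics, nulls,
calibration, statistics — behave correctly at the study's scale, not that
the generator is a substitute for diffusion MRI data.
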