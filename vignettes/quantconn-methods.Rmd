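---
title: "Quantitative connectome analysis with quantconn: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative connectome analysis with quantconn: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantconn)
```

`quantconn` implements a complete desk-scale pipeline for comparing
structural and functional brain connectomes between a patient group and
healthy controls (HC), and for relating network damage to cognition. This
vignette explains the models behind each stage, the tunable parameters
and their defaults, what the synthetic cohort generator does and does not
emulate, and the numerical conventions adopted where the methods
literature leaves choices open.

## 1. Microstructure-informed streamline weighting

Tractography alone counts streamlines; it does not say how much axonal
signal each one carries. The decomposition implemented in
`build_operator()` / `fit_commit()` assigns each streamline a
non-negative intra-axonal signal fraction by expressing the diffusion-MRI
signal as a linear forward model with two compartments:

* a **stick** for intra-axonal water, attenuating as
  $e^{-b\,d_\parallel (\mathbf{g}\cdot\mathbf{u})^2}$ with axial
  diffusivity $d_\parallel = 1.7\times10^{-3}\,\mathrm{mm^2/s}$ and zero
  perpendicular diffusivity;
* two isotropic **balls** per voxel, attenuating as $e^{-b\,d}$ with
  $d = 1.7\times10^{-3}$ and $3.0\times10^{-3}\,\mathrm{mm^2/s}$
  (hindered and free water).

A streamline's weight is constant along its whole trajectory, while the
isotropic fractions are voxel-specific. Stacking voxels × volumes gives a
linear operator whose streamline column holds segment length × stick
attenuation on the voxels the streamline traverses; the fit is plain
non-negative least squares (Lawson–Hanson, via `pracma::lsqnonneg`),
with no regularisation term — the base formulation of this family of
methods is unpenalised, and adding a penalty would bias the noiseless
recovery property the tests rely on.

Numerical conventions: the local tangent in a voxel is the normalised
segment direction in that voxel; signals are normalised so that the
b = 0 signal equals the total compartment fraction (no absolute $S_0$
estimation); both ball compartments are present in every voxel rather
than being restricted by tissue masks, which at toy scale have no
analogue. The default gradient table is 9 b = 0 volumes plus 64
directions at $b = 1000\,\mathrm{s/mm^2}$ on a deterministic Fibonacci
sphere.

The quantitative **edge weight** of a bundle of $N_{ij}$ streamlines
with weights $x^k_{ij}$ and lengths $l_k$ is the length-weighted total
signal fraction divided by the mean bundle length:

$$a_{ij} = \frac{\sum_k x^k_{ij} l_k}{\sum_k l_k / N_{ij}}.$$

Bundles with no streamlines yield *no* edge (absence), which the
streamline-count matrix keeps distinct from a zero-weight bundle.

## 2. Connectome construction

**Nodes.** The 116-region automated anatomical labelling parcellation is
reduced to 100 nodes before analysis: all vermis subdivisions collapse to
a single vermis node and each left/right pair of cerebellar hemisphere
regions merges into one node (`merge_cerebellar()`), reflecting the
limited spatial resolution of echo-planar images in the cerebellum.
Node ids are 1-based throughout; written files carry node names in
headers so indexing is never ambiguous.

**Structural thresholding.** Spurious low-prevalence connections are
removed by `prevalence_filter()`: an edge is kept only if it is nonzero
in at least half of the controls, and the control-derived mask is applied
to every subject. "Less than half" is read literally: with an odd number
$N$ of controls an edge is removed when its presence count is strictly
below $N/2$, i.e. count $\le \lfloor N/2 \rfloor$ (with 49 controls, 24
is removed and 25 kept); this boundary is tested explicitly.

**Functional edges.** Node time series are residualised on a confound
matrix (always including an intercept) and band-pass filtered to
0.008–0.09 Hz by ideal Fourier masking (`clean_series()`); the filter
zeroes the DC bin, so outputs are mean-zero. Convolution with a
haemodynamic response function is deliberately *not* applied: the
synthetic series are not neural-event trains, so there is no event
structure for an HRF to act on. Edges are Fisher-z transformed Pearson
correlations (`fisher_connectome()`); matrices are then absolutised
(anticorrelations carry information and most weighted metrics require
non-negative weights) and proportionally thresholded to a fixed density
of 0.20 (`absolutize_and_threshold()`), keeping exactly
$\lfloor 0.20\, n(n-1)/2 \rfloor$ of the largest-magnitude edges.
Ties are broken deterministically (larger magnitude, then lexicographic
node pair). Surviving edges retain their continuous weights — a binary
mask would degenerate the weighted graph metrics. Downstream functional
*deviation* indices use unthresholded absolute weights by default, since
thresholding would zero exactly the weak edges whose deviation is of
interest.

## 3. Global graph metrics

Five global metrics per connectome (`graph_metrics()`):

* **density** — fraction of possible edges present;
* **mean strength** — average nodal sum of incident weights;
* **global efficiency** — mean inverse shortest-path length over node
  pairs, with edge length $1/w$ (the standard connectomics mapping) and
  disconnected pairs contributing 0 (reading $1/\infty = 0$ rather than
  excluding them);
* **clustering coefficient** — Onnela's weighted form: the geometric
  mean of triangle weights normalised by the network maximum, averaged
  over nodes, with degree-< 2 nodes contributing 0 (the reference
  toolbox's convention);
* **modularity** $Q$ — Newman's spectral method: recursive leading-
  eigenvector bisection of the modularity matrix
  $B = W - \mathbf{k}\mathbf{k}^\top/2m$ with Kernighan–Lin-style
  single-node fine-tuning after each split and resolution $\gamma = 1$.
  Determinism is enforced by orienting each eigenvector so its first
  nonzero component is positive and breaking fine-tuning ties toward the
  lowest node index. On all 8-node graphs the returned $Q$ is checked
  against exhaustive search over every partition; the spectral value
  never exceeds the optimum and attains it on well-separated planted
  modules.

## 4. Network-based statistics

`nbs_test()` implements the four-step component-level permutation
procedure: (i) an ordinary linear model at every edge with group plus
nuisance covariates (mass-univariate t-statistics, vectorised across
edges); (ii) primary thresholding of the t-map; (iii) connected
components among supra-threshold edges; (iv) a family-wise
error-corrected p-value per component from the permutation distribution
of the maximal component size. Defaults mirror the study conditions:
primary thresholds 2.0–4.0 in steps of 0.1, 5000 permutations,
*intensity* (summed t) as the size measure, $\alpha = 0.05$.

Open choices resolved here:

* **Permutation scheme.** With nuisance covariates, labels are not
  exchangeable, so Freedman–Lane permutation is used: residuals from the
  nuisance-only model are permuted and added back to the nuisance fit
  before the full model is re-estimated. This is the accepted standard
  for GLM permutation inference in neuroimaging.
* **Directional contrasts.** One-sided signed-t contrasts (e.g.
  `"patient<control"`), run separately per direction, rather than an
  F-statistic; the directional formulation matches how deficit and
  excess subnetworks are reported.
* **P-value estimator.** The add-one estimator
  $p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_\text{perm}+1)$, whose
  minimum attainable value is $1/(n_\text{perm}+1)$ and which is valid
  under exchangeability. When the requested permutation count exceeds
  the number of distinct subject permutations, all permutations are
  enumerated instead (with a warning).

Because supra-threshold edge sets shrink as the threshold grows, maximal
component sizes are non-increasing across the sweep; the suite checks
this monotone-shrinkage property on planted cohorts.

## 5. Cohort statistics

* **Group comparisons** of global metrics use OLS with group plus
  age/sex (plus mean motion for functional metrics) and HC3
  heteroscedasticity-consistent standard errors (`robust_ancova()`).
  The methods literature says "robust ANCOVA" without naming an
  estimator; the sandwich/HC3 choice is a defensible default, and a
  classical-ANCOVA flag is provided — on homoscedastic data the two
  agree closely, which is tested. Benjamini–Hochberg step-up controls
  the false discovery rate across metrics (`bh_fdr()`, backed by
  `stats::p.adjust` and validated against a hand-computed oracle).
* **Disruption / deviation indices.** For each subnetwork edge, every
  subject's weight is referenced to the covariate-adjusted control
  distribution: a linear model fit in controls only predicts the edge
  weight from age and sex (plus motion for functional edges), and
  $z = (\text{obs} - \text{pred})/\mathrm{SD}(\text{control residuals})$.
  The per-subject index is the mean z over subnetwork edges; structural
  mode uses raw weights (negative = disconnection), functional mode uses
  absolute weights (positive = increased connectivity). By construction
  the control mean is 0. Regression-based adjustment is applied
  uniformly, including to global metrics.
* **Effect sizes** use pooled-SD Cohen's d with $(n-1)$ weighting.
* **Robust correlations** are percentage-bend partial correlations
  (bend constant 0.2, the robust-statistics toolbox default), with
  p-values from the t approximation on $n - 2 - k$ degrees of freedom
  (k = partialled covariates) and percentile-bootstrap 95% CIs over
  subjects (1000 replications, seeded).
* **Moderation.** OLS of the cognitive score on disruption, deviation,
  their product, age and sex (`moderation_fit()`), with simple slopes
  of disruption at moderator levels mean and mean ± 1 SD
  (`simple_slopes()`): $\text{slope}(v) = \beta_\text{disr} +
  \beta_\text{inter} v$. Cognitive-score analyses are run on the scored
  patient subgroup; the subgroup size is a parameter, not hard-coded.

## 6. The synthetic cohort generator

No patient data are distributable, so validation runs on synthetic
cohorts (`gen_cohort()`) whose statistical structure mirrors the
analysis assumptions:

* **Groups:** 46 patients, 49 controls (the study's sizes), 100 nodes.
* **Structural template:** a random geometric graph on the unit cube —
  nodes uniform, edges where distance falls below the 30% quantile,
  weights $e^{-d/0.5}$ — giving the sparse, distance-decaying weight
  structure of tractography matrices. Each subject adds Gaussian edge
  noise (SD 0.1 in signal-fraction units) clipped at zero, so edge
  presence varies realistically across subjects.
* **Planted effects:** patients' weights are reduced by a global factor
  (default 2%) and subnetwork edges by an additional factor (default
  25%). The default subnetwork is the 8 most central, spatially
  clustered nodes, guaranteeing a connected planted component.
  `calibrate_subnet_effect()` inverts the noise model analytically to
  hit a requested disruption effect size.
* **Functional model:** 5 equal modules of latent shared signal; node
  series are $\sqrt{\rho}\,s_m + \sqrt{1-\rho}\,\varepsilon$ over 200
  time points (matching the acquisition length), with $\rho = 0.30$ in
  controls and $+0.15$ in patients — raising within-module correlation
  and hence modularity. Finite series keep sampling noise in the
  correlation matrices realistic.
* **Covariates:** age $\sim N(42, 15^2)$ truncated to [18, 80], sex
  Bernoulli(0.5) coded 0/1, motion log-normal (a unitless mean
  framewise-displacement proxy).
* **Cognition:** scores follow the moderation model
  $\beta \cdot (1, \text{disr}, \text{dev}, \text{disr}\times\text{dev},
  \text{age}, \text{sex})$ + noise, with the published coefficient
  vector (16.364, 15.809, −10.793, −28.636, −0.070, −0.681) as default.
  The disruption/deviation entering the score are the model-defined
  indices computed on the generated connectomes themselves, so parameter
  recovery is self-consistent, and exact when the score noise is zero.

What the generator does **not** emulate: image-space artefacts, lesion
geometry, head motion's actual effect on edges (motion is an independent
covariate), spatially correlated edge noise, negative structural
weights, or hub/rich-club topology. Passing tests therefore demonstrate
correctness of the estimators and calibration of the inference under
the stated model — not robustness to every property of real MRI data.

Toy tractograms (`gen_toy_tractogram()`) are straight axis-aligned voxel
paths on grids of at most 1000 voxels, sampled without replacement from
the set of admissible placements so that operator columns stay distinct;
ground-truth weights are uniform on [0.1, 1].

## 7. Problem sizes and numerical tolerances

The validation suite uses: noiseless 50-streamline recovery on a fully
mapped 3×3×3 grid (weight RMSE < 10⁻⁶; the full-rank design makes the
non-negative least-squares solution unique); graph-metric oracles on
50 random 8-node graphs (10⁻¹² agreement, exhaustive modularity search
over all 4140 partitions); null calibration of the network-based
statistic on 200 simulated 46/49 cohorts with 500 permutations each at
threshold 3.0 (family-wise rejection inside the binomial 95% band around
0.05); planted-subnetwork recovery with 1000 permutations across the
full threshold sweep, where the recovery experiment sets the global
effect to zero so the planted subnetwork is the only group difference
(Jaccard ≥ 0.8 against the planted node set at t = 3.0); moderation
CI coverage over 500 noisy replicates (≥ 93%); and null calibration of
the robust ANCOVA and robust correlation over 500 replicates each.
Symmetry is enforced at 10⁻¹⁰ on matrix input; modularity split gains
below 10⁻¹⁰ count as indivisible.

## 8. Known limitations

* The decomposition is toy-scale by design: dense operators, no
  curved streamlines, no TCK/TRK parsing, no GPU or blocked solvers.
* Spectral modularity is a deterministic heuristic; on graphs with
  near-degenerate leading eigenvectors it may return a slightly
  sub-optimal partition (never above the optimum, as tested).
* The percentage-bend correlation's t approximation is asymptotic;
  at very small n its calibration is checked empirically rather than
  guaranteed.
* Edge noise is independent across edges in the generator; real
  tractography errors are spatially structured, which would widen the
  null distribution of component sizes.
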