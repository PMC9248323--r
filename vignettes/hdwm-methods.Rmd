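---
title: "White-matter microstructure analysis in premanifest Huntington disease: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{White-matter microstructure analysis in premanifest Huntington disease: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdwm)
```

## The scientific problem

Premanifest Huntington disease (HD) — gene carriers before motor diagnosis —
shows subtle white-matter alterations whose biological driver is disputed:
loss or gain of myelin/iron (visible to magnetization transfer imaging) versus
changes in axon density (visible to restricted-diffusion imaging). Separating
the two requires (i) quantitative maps that are differentially sensitive to
each compartment, (ii) a regionally resolved analysis of the corpus callosum,
whose anterior segments myelinate late and posterior segments early, and
(iii) a whole-brain search that respects white-matter geometry.

`hdwm` implements that analysis chain end to end:

1. **Quantitative maps** — MTR from paired saturation images; FA/AD/RD/MD from
   a b-restricted diffusion tensor fit; the restricted signal fraction FR from
   a composite hindered-and-restricted (CHARMED-style) two-compartment model;
   and a free-water signal fraction FWF.
2. **Callosal tractometry** — per-vertex sampling of each map along seven
   labeled callosal bundles (rostrum ... splenium), aggregated to a
   subject-by-segment-by-metric table.
3. **Group statistics** — varimax PCA over the five metrics with KMO/Bartlett
   adequacy checks, Type III ANCOVA with group-by-segment and group-by-age
   interactions, simple-slopes moderation, and Spearman / partial Spearman
   correlation families (cognition, CAG repeat length, disease burden score)
   under Bonferroni correction.
4. **Tract-based cluster analysis (TBCA)** — a permutation GLM at the voxel
   level combined with a *hypervoxel* template: suprathreshold voxels form a
   cluster when they are spatially adjacent *or* intersected by a common
   streamline, cluster mass (the summed t-score) is the statistic, and
   family-wise error is controlled by the permutation distribution of the
   maximum cluster mass.
5. **A synthetic cohort generator** that stands in for the MRI data, so every
   stage is testable without any download.

## Signal models

**MTR.** `MTR = (S0 - SMT) / S0 x 100`, computed only where `S0 > 0`;
degenerate voxels become missing values. The map is invariant to common
rescaling of the two inputs.

**Diffusion tensor.** `log S = log S0 - b g' D g`, fitted by linear least
squares on the log signal with one reweighting pass (weights = squared
predicted signal). Only `b = 0` and shells in `[500, 1200]` s/mm^2 enter
the fit — high-b shells carry non-Gaussian signal and low-b CSF partial
volume would bias the metrics; both endpoints are included. Eigenvalues are
clipped at zero before FA.

**CHARMED-style restricted fraction.** The signal is modeled as
`S = S0 ((1 - FR) E_h + FR E_r)` with a Gaussian hindered tensor compartment
and a cylindrically restricted compartment. Writing
`b = 4 pi^2 q^2 (Delta - delta/3)`, the restricted attenuation along the
cylinder axis is mono-exponential in the intracellular axial diffusivity, and
perpendicular to it follows the small-radius Gaussian-phase closed form with
fixed radius `a`:

`E_r = exp(-b cos^2(theta) D_par) * exp(-(7/96) (4 pi^2 q_perp^2) (a^4 / (D_perp Delta)) (2 - (99/112) a^2 / (D_perp Delta)))`

Simplifications, chosen because only FR is analyzed downstream: a single
cylinder population, radius fixed at 3 um (about the smallest radius
resolvable with ultra-strong gradients), the intracellular perpendicular
diffusivity tied to the axial one, and the cylinder axis following the
hindered tensor's principal eigenvector. The fit is box-constrained
Levenberg-Marquardt per voxel, seeded by the DTI tensor, with FR started at
0.3 and 0.7 (keeping the lower misfit) because the FR likelihood has local
minima at the box edges. Least squares on magnitudes is used throughout;
at the SNR regimes analyzed (>= 20) the Gaussian approximation to Rician
noise is standard practice.

**Free-water fraction.** `S/S0 = FWF exp(-b D_free) + (1 - FWF) exp(-b g' D_t g)`
with `D_free` fixed at `3.0e-3` mm^2/s, fitted on shells `<= 1200` s/mm^2.
The tissue-tensor elements are bounded below the free diffusivity
(`2.5e-3` mm^2/s): without that bound the model is unidentifiable in voxels of
nearly pure fluid, since the tissue compartment can imitate free water.
Free-water estimators in the literature differ in their regularization and
are often underdocumented; this fixed-`D_free` two-compartment fit is the
package's own estimator and its outputs are labeled as such.

## Tractometry

Maps are sampled by trilinear interpolation at every streamline vertex
(world-to-voxel through the inverse affine; voxel centers sit at integer
0-based indices, voxel extents are half-open `[c - 0.5, c + 0.5)`). The
segment summary is the *median over each streamline's vertices, then the mean
over streamlines*. Median-then-mean phrasing in tractometry reports is
ambiguous about whether vertices are pooled across streamlines before the
median; the chosen order matches tractometry convention, and `aggregate =
"pooled-median"` switches to the pooled variant. Vertices outside the grid
are excluded from their streamline's median; fully out-of-grid streamlines
are dropped with a logged count.

## TBCA inference

The voxel model is an ordinary least-squares GLM of the metric on a group
indicator plus age and sex; the group effect is tested one-sided in a stated
direction (patient-greater for FR and FA, patient-lower for MTR), each
direction with its own analysis and its own max-mass null. Permutation
inference follows the Freedman-Lane scheme: the reduced model (age, sex) is
fitted once, its residual rows are permuted, the full model is refitted, and
the observed statistic is ranked within the pooled stack, giving
`p = (1 + #{t_perm >= t_obs}) / (n_perm + 1)`. The cluster-forming threshold
`p = .01` is applied to this permutation p-map rather than to a parametric t
threshold: the pipeline is nonparametric throughout, and whether the
threshold is parametric or permutation-based is left configurable.

Clusters are connected components over two edge types: 26-neighborhood
spatial adjacency and shared-streamline incidence from the hypervoxel
template. The template links a streamline to every voxel its segments
traverse, stepping at half-voxel length so voxels crossed between sparse
vertices are not missed. Published hypervoxel constructions carry
additional orientation/topology dimensions that the clustering rule never
uses; the template here is deliberately the minimal incidence structure
that supports the adjacent-or-shared-streamline rule.
Cluster mass is the sum of member-voxel t-scores; FWE-corrected p-values
compare each observed mass with the per-permutation maximum mass,
`p_fwe = (1 + #{max_mass_perm >= mass}) / (n_perm + 1)`. The uncorrected
cluster p uses the pooled permutation cluster-mass distribution, capped at
`p_fwe` so the pair is always ordered. Significant clusters are unioned and
binarized into an ROI whose per-subject means feed cross-metric Spearman
correlations.

## Group statistics

- **Outliers**: values more than 3 SD from their own group's mean are
  removed, per dependent variable, patients and controls separately.
- **Adequacy**: KMO from zero-order versus anti-image correlations;
  Bartlett's `chi^2 = -(n - 1 - (2p + 5)/6) log det(R)` on `p(p-1)/2` df.
- **PCA**: correlation-matrix eigendecomposition on standardized data,
  varimax rotation with Kaiser normalization when at least two components
  are retained, regression-method scores, components sign-aligned so the
  dominant loading is positive and labeled by it ("magnetization transfer"
  when MTR dominates, "axon density" for the diffusion metrics). Scores can
  be computed from rotated (the default) or unrotated loadings
  (`rotate = FALSE`).
- **Retention**: `pca_varimax()` defaults to the Kaiser criterion
  (eigenvalue > 1). The pipeline combines Kaiser with interpretability:
  if Kaiser alone does not yield both a-priori components, both are
  retained by the fixed-k rule. This matters at demo
  scale because the planted anterior-posterior MTR group pattern shares
  segment-profile variance with the diffusion density gradient, which can
  push the MT eigenvalue marginally below 1.
- **ANCOVA**: OLS with sum-to-zero contrasts and Type III F-tests (the
  SPSS-style convention appropriate for unbalanced groups), group and
  segment crossed as fixed factors. Repeated segments per subject are
  deliberately treated as crossed fixed effects, not as a subject random
  effect — a mixed model would be the statistically stronger choice and is
  out of scope. Covariates enter after screening
  (|Pearson r| > 0.3 against the outcome). The covariate set follows each
  analysis as reported (age for the main models; age, ICV and FWF with
  group-by-age and group-by-FWF interactions in the partial-volume
  re-analysis, where slope homogeneity cannot be assumed) rather than being
  unified across models.
- **Simple slopes**: the conditional group effect per segment, obtained by
  refitting with the target segment as reference level and covariates
  centered at their means.
- **Correlations**: Spearman as Pearson-on-ranks with a t-approximation;
  the partial variant residualizes the ranks on the covariates (ICV, DBS)
  and adjusts the degrees of freedom; with no covariates the two code paths
  coincide exactly. Bonferroni multiplies by the family size (7 segments)
  and caps at 1. `DBS = age x (CAG - 35.5)`.
- The cognitive PCA uses patients only, complete cases, and extracts a
  single component whose regression scores are the composite cognitive
  score.

## The synthetic cohort

The generator emulates a premanifest-HD imaging study's conditions, not
brain anatomy: a
48^3-voxel grid at 2 mm (24^3 in the demo configuration), seven callosal
arcs as half-ellipses in parallel slabs ordered anterior-to-posterior plus a
vertical CST-like tube spatially disjoint from them, 2,000 streamlines per
bundle (200 in the demo). Subjects get matched ages (controls are permuted
patient ages plus U(-2, 2) years), integer CAG 37-45 for patients, ICV, and
exact DBS. Maps are a background/bundle two-level baseline plus planted
effects plus Gaussian voxel noise, smoothed at 4 mm FWHM; effects are
painted on bundle masks dilated by one voxel so that trilinear sampling at
any traversed vertex sees bundle values on all eight corners. Noise is
additive Gaussian on the scalar maps (they are derived quantities, not raw
magnitude images); Rician noise is applied only to simulated diffusion
signals. All draws descend from one root seed through named substreams, so
adding a generator never perturbs existing draws.

The planted effects encode the findings the pipeline must recover: a
patient MTR offset per segment (+2.0, +1.4, +0.7, 0, -0.7, -1.4, -2.0 MTR
units, anterior-positive/posterior-negative), a CAG-MTR slope of +0.15 MTR
units per repeat, a baseline age slope of -0.05 units/year with a
patient-minus-control slope difference of -0.04 units/year, a +0.05 FR
offset in the patients' CST, and a posterior-high density gradient on
FA/FR/AD (opposite on RD). A per-subject latent myelin factor drives the
between-subject MTR offset and leaks weakly into RD (-1.5e-5 mm^2/s per SD),
which is what gives the MT component more than one variable's worth of
variance, as observed in real data. Real cohorts of this kind are reported
through component scores and test statistics, not native-unit effect sizes,
so these magnitudes are free design parameters: they were chosen once, by power
reasoning at the demo cohort size (12+12), to be clearly detectable —
roughly 2-3 within-group SDs at the bundle level — and are not calibrated to
any published values. What passing recovery tests shows is that the pipeline
detects effects of the planted geometry and size under Gaussian smoothness;
it says nothing about sensitivity at the (unknown) real effect sizes, about
registration error, or about non-Gaussian artifact structure in real maps.

## Numerical choices and degenerate inputs

- Voxel p-values and suprathreshold masks for *every* permutation row are
  computed from one pooled rank pass, keeping observed and permuted rows
  exchangeable; the minimum attainable p is `1/(n_perm + 1)`.
- If `n_perm` exceeds the number of distinct permutations the set is
  enumerated exhaustively (with a warning) and the identity permutation
  plays the role of the observed row.
- Voxels with zero residual variance get `t = 0` and are counted; all-NA
  streamlines and non-positive diffusion signals are excluded with logged
  counts; empty cluster sets are legal results.
- Union-find with path halving gives the cluster partition; the partition
  is invariant to voxel visiting order and streamline relabeling (tested).
- The demo problem sizes (24^3 grid, 12+12 subjects, 200 streamlines per
  bundle, 300-500 permutations, 100 null Monte-Carlo repeats) were chosen
  so the full suite and the acceptance script each run comfortably on a
  single CPU; the full-scale configuration (48^3, 2,000 streamlines, 25+25)
  is the package default for `phantom_config()`.

## Known limitations

- The hypervoxel template is pure voxel-streamline incidence; orientation
  binning from richer published constructions is not modeled.
- Exchangeability blocks, variance smoothing and TFCE are out of scope.
- The FWF estimator is a stand-in (see above), and CHARMED radius/axon
  -diameter estimation is deliberately excluded.
- Tractometry offers no along-tract (per-node) profiling.
- The crossed fixed-factor ANCOVA understates within-subject correlation
  across segments; see the README caveat.
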