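---
title: "Methods: virtual SLF dissection and the multivariate maturation index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual SLF dissection and the multivariate maturation index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slfmature)
```

## What the package computes

The superior longitudinal fasciculus (SLF) is the major fronto-parietal
association tract, conventionally divided into a dorsal (SLF I), middle
(SLF II) and ventral (SLF III) branch. `slfmature` implements a complete
analysis chain for asking how far each branch of a neonatal brain has
progressed toward its adult microstructural state:

1. **Virtual dissection** of the three branches, per hemisphere, from a
   whole-brain streamline tractogram by boolean region-of-interest (ROI)
   logic.
2. **Microstructure fitting**: the diffusion tensor (FA, MD, AD, RD) on
   the b = 0/1000 s/mm² sub-scheme, and a simplified three-compartment
   neurite model (NDI, ODI) on all shells.
3. **Tract sampling**: trilinear sampling of each metric map along every
   streamline, reduced to one tract mean per subject × bundle × metric.
4. **Maturation statistics**: hemispheric lateralization, Pearson age
   trends, neonate-vs-adult contrasts with Cohen's d, and — the core
   quantity — a per-branch Mahalanobis distance M between each neonate's
   six-metric vector and the adult reference distribution of the same
   branch. Smaller M means closer to the adult stage.

Everything runs on synthetic phantoms, so the full chain is testable
without any imaging data.

## The dissection model

A streamline belongs to a bundle iff it visits **every** include ("AND")
ROI and touches **no** exclude ("NOT") ROI. The shipped rule table
(`slf_rules()`) pairs a parietal waypoint with a frontal classifier ROI
per branch — superior frontal for SLF I, middle frontal for SLF II,
precentral for SLF III — and excludes the temporal lobe (arcuate
streamlines) and the mid-sagittal plane (callosal streamlines) in every
rule. The neonatal protocol differs in exactly one place: SLF II is
tracked with a posterior middle-frontal ROI (between the commissural
planes) instead of the parietal ROI, because immature SLF II streamlines
need not reach the parietal ROI.

Design choices worth knowing:

* **"AND" is unordered.** An include ROI is satisfied by ≥ 1 tested
  point, anywhere along the streamline. The ROIs are waypoint masks with
  no traversal-order semantics.
* **Point-in-ROI convention.** A world point maps to the voxel
  `floor(c + 0.5)` of its continuous 0-based index `c`, i.e. voxel `i`
  owns `[i − 0.5, i + 0.5)`. This matches centre-based NIfTI sampling
  and is stated explicitly so it can be tested.
* **Supersampling is on by default** (test points at most half the
  smallest voxel edge apart). Without it a long segment can step
  straight over the one-voxel mid-sagittal slab and silently break the
  callosal exclusion. Whether vertices or segment interiors should be
  tested is a genuine open choice; we document supersampling as ours and
  expose `supersample = FALSE` for vertex-only semantics.
* **Overlaps are reported, not hidden.** A streamline satisfying two
  rules appears in both bundles with a warning; an optional post-filter
  (`resolve_overlap = TRUE`) assigns SLF II/III-ambiguous streamlines by
  mean vertex height (more dorsal → SLF II), off by default.

## The signal model and its fits

The forward model (`noddi_signal()`) is the standard three-compartment
picture: an intra-neurite compartment of sticks dispersed by a Watson
distribution with concentration κ, an extra-neurite Gaussian
("zeppelin") whose mean tensor follows the same Watson distribution and
whose perpendicular diffusivity obeys the tortuosity rule
`d_perp = d_par (1 − ndi)`, and isotropic free water:

S/S0 = (1 − f_iso) [ndi · A_intra + (1 − ndi) · A_extra] + f_iso · e^{−b d_iso}

with `odi = (2/π) atan(1/κ)`. The intrinsic diffusivities are fixed at
the conventional values d_par = 1.7×10⁻³ mm²/s and d_iso = 3.0×10⁻³
mm²/s (configurable); they are model constants, not fitted.

**Numerics.** The Watson sphere integrals reduce, after analytic
azimuthal integration via the Bessel function I₀, to a 1-D polar
integral evaluated by 64-point Gauss–Legendre quadrature, carried in log
space so large κ cannot overflow. The rule is accurate to well below
1e-6 for κ ≤ 128 (odi ≥ 0.005), which is why `fit_noddi()` bounds odi
below at 0.01.

**DTI** is the log-linear tensor model solved by OLS followed by one
weighted refit with squared-predicted-signal weights. Whether the
original toolchain used OLS or WLS inside its tensor fit is not
recorded; WLS is the standard, stable choice and is documented here as
ours (`wls = FALSE` gives plain OLS). Non-positive samples are dropped
and counted; negative eigenvalues are clamped to zero for metric
computation (keeping FA in [0, 1]) and counted.

**NODDI fitting** is a transparent coarse-grid search (step 0.05 over
ndi, odi, f_iso) followed by bounded local refinement (tolerance 1e-4),
with the mean neurite direction fixed to the DTI principal eigenvector.
The named reference toolbox specifies no algorithm; grid-plus-refine is
chosen because every stage of it is testable. When the fitted free-water
fraction exceeds 0.95, ndi/odi are unidentifiable and the fit is
flagged.

## Tract means

`tract_mean()` averages over **all sampling points of all streamlines**
(point-weighted): a streamline with more vertices contributes more. The
alternative reading — first average within each streamline, then across
streamlines — is available as `weight = "streamline"`; the point-
weighted form is the default because it follows the stated averaging
rule verbatim. Sampling is trilinear (the named sampling tool's
default); nearest-neighbour is available via `method = "nearest"`.
Out-of-grid vertices are dropped and counted, never zero-filled, because
zero-filling biases tract means toward zero. Empty bundles are explicit
errors, not silent zeros.

Left and right tract means are averaged arithmetically into the `"avg"`
rows after the lateralization analysis finds no systematic asymmetry —
the same order of operations as the motivating analysis. Whether the
original Mahalanobis computation used per-hemisphere or averaged vectors
is not stated; averaged vectors are assumed here, consistent with the
preceding averaging step, and we flag this as an assumption.

## The maturation index

For each branch, the adult reference (`build_adult_reference()`) is the
sample mean vector μ and sample covariance Σ (n − 1 denominator; the
source is silent on the denominator, so the unbiased convention is
documented here) of the adults' six-metric vectors (NDI, ODI, FA, MD,
AD, RD), with the eigen-decomposition Σ = V diag(λ) Vᵀ stored. A
reference needs ≥ 8 adults and a covariance condition number ≤ 1e10;
otherwise it is refused with a diagnostic naming the most collinear
metric pair.

The distance is computed in the eigen form

M²(x) = Σᵢ ((x − μ)·vᵢ)² / λᵢ

with the direct-inverse form (x − μ)ᵀ Σ⁻¹ (x − μ) evaluated as a
cross-check; the two are algebraically identical for full-rank Σ.
Because M is invariant under any invertible linear remap of the metric
space, per-metric units cannot bias it — diffusivities at ~1e-3 mm²/s
coexist with order-one fractions. **Numerical note:** both forms are
evaluated after standardising each metric by its reference SD (i.e. on
the correlation matrix). M is mathematically unchanged by this diagonal
remap, but evaluating the eigen form on the raw covariance loses
precision once the metric magnitudes span many decades; the
standardised evaluation keeps the two forms within 1e-8 of each other
under arbitrary rescalings.

Downstream, `maturation_analysis()` compares the per-neonate M across
branches with pairwise Wilcoxon signed-rank tests at the Bonferroni
threshold 0.01 (0.05/3, as the motivating analysis rounds it), and
correlates M with post-menstrual age (PMA) by Spearman rank correlation.
The Wilcoxon test is implemented in-package: exact null distribution by
dynamic programming for ≤ 25 zero/tie-free differences, otherwise a
normal approximation with Pratt zero handling, tie correction and
continuity correction — chosen so results are reproducible across
implementations and checkable against an enumeration oracle.

Multiple-comparison handling follows the Bonferroni–Dunn convention of
the motivating analysis: trend flags use the divided threshold
(0.05/6 = 0.008 for six metrics), while contrast tables also report
Bonferroni-multiplied adjusted p values. Cohen's d is reported
adult-minus-neonate with absolute values alongside.

## What the synthetic world does (and does not) establish

The phantom (`make_phantom()`) is a 48³ grid of 2 mm voxels with
axis-aligned ROI boxes: frontal boxes anterior to the
anterior-commissure plane, parietal boxes posterior to the
posterior-commissure plane, the neonatal posterior middle-frontal box
strictly between them, temporal slabs inferiorly, and a one-voxel
mid-sagittal plane. The true hand-drawn ROI geometry is unknowable from
any description; these schematic boxes preserve the topology the rules
rely on (plane ordering, laterality, mirror symmetry), nothing more.
Bundles (`simulate_bundle()`) are straight, jittered polylines through
clamped waypoints, so include-ROI hits are guaranteed by construction —
a green dissection test establishes that the boolean engine implements
its contract, not that the rules segment real anatomy.

The cohort generator (`cohort_spec()`) states the emulated world
explicitly: 40 neonates at 37–44 weeks PMA (ages uniform by default —
uniform maximises trend-estimation power in tests; a Gaussian matched to
the real scan-age distribution, 39.89 ± 2.08 weeks, is available), 40
adults at 22–35 years. Neonatal tract means drift linearly toward adult
values (NDI +0.008/wk and FA +0.005/wk rising; MD and RD −0.02×10⁻³
mm²/s per week falling; AD and ODI essentially flat), with
between-subject SDs sized so the sample age correlations land in the
r ≈ 0.5–0.7 range the real neonatal cohort shows for NDI/FA while AD/ODI
stay non-significant. Adults sit at distinct means with zero slope.
Intercepts (e.g. neonatal NDI 0.25 vs adult 0.55, FA 0.22 vs 0.45, MD
1.30 vs 0.72 ×10⁻³ mm²/s) are realistic mid-range white-matter values
chosen once; no quantitative group offsets are published in the source's
main text, so these are labelled synthetic, not derived. A shared
per-subject "maturity" factor (loading 0.6, signed by the direction of
maturation per metric) gives the adult covariance a realistic
correlated structure so the reference Σ is full-rank but far from
diagonal.

The SLF II branch lags by construction: its neonate-to-adult offset is
scaled `slf2_lag = 2` times farther, in covariance-whitened units, than
SLF I/III — the configuration specified for the headline recovery test.
Because all six metrics drift toward the adult means with age, M
decreases with PMA, and the pipeline should (and does, in ≥ 95% of
seeded replicates) rank SLF II least mature with significant pairwise
Wilcoxon tests. This establishes that the statistics recover a known
generative structure; it says nothing about effect sizes in real
cohorts, whose preprocessing, tractography and ROI drawing are out of
scope here.

## Degenerate inputs and tie-breaks

* Tractograms: streamlines need ≥ 2 finite vertices; a declared `count`
  that disagrees with the file content is a warning, and the actual
  count wins.
* NIfTI: when qform and sform disagree, sform wins (with a message).
* Shell grouping tolerates ±50 s/mm² of b-value jitter.
* `fit_dti` needs ≥ 7 positive samples including a b = 0; rank-deficient
  designs are errors.
* `fit_noddi` refuses single-shell schemes (the model is degenerate).
* References: < 8 adults, or covariance condition > 1e10, are refused.
* Wilcoxon: all-zero difference vectors are errors at the function
  level; `maturation_analysis()` converts them to NA p values so a
  degenerate cohort still returns its (flat) distance table.
* Streamlines satisfying two dissection rules are kept in both bundles
  (warning); `resolve_overlap` breaks SLF II/III ties by mean height.

## A worked miniature

```{r example, eval = FALSE}
layout <- make_phantom()
sim <- simulate_tractogram(layout, seed = 1)
bundles <- dissect_slf(sim$tractogram, layout, protocol = "neonate")
attr(bundles, "report")[, c("name", "n_kept")]

cohort <- simulate_cohort_tables(cohort_spec(), seed = 1)
trend_analysis(cohort)          # Pearson r/t/df per bundle x metric
contrast_analysis(cohort)       # adult-vs-neonate t, Cohen's d
mat <- maturation_analysis(cohort)
mat$ranking                     # largest mean M = least mature
autoplot(mat)                   # M vs PMA per branch
```

## Known limitations

* The phantom is schematic; no fibre-crossing geometry, no FOD-based
  tractography, no registration — tract generation and atlas steps of a
  real study are out of scope by design.
* The NODDI implementation is the simplified dispersed-stick/zeppelin/
  free-water model with fixed diffusivities; no analytic spherical-
  harmonic Watson evaluation, no convex (AMICO-style) reformulation,
  no kurtosis.
* Rician noise is applied per channel independently; no spatial noise
  correlation, motion or susceptibility artefacts.
* Statistics stop at Bonferroni/Bonferroni–Dunn corrections and
  two-group designs, mirroring the motivating analysis; no mixed
  models, no sex effects.
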