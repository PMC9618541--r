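# slfmature

Virtual dissection and maturation analysis of the superior longitudinal
fasciculus (SLF) in diffusion MRI.

The SLF is the major fronto-parietal association tract, classically split
into a dorsal (SLF I), middle (SLF II) and ventral (SLF III) branch. In
neonates these branches mature at different rates, and no single diffusion
metric captures "how adult-like" a bundle is. This package implements, end
to end, a pipeline for quantifying per-branch maturation:

1. **Virtual dissection** — select each branch from a whole-brain
   streamline tractogram by boolean ROI logic: a streamline is kept iff it
   visits every include ("AND") ROI and touches no exclude ("NOT") ROI
   (temporal lobe and mid-sagittal plane, removing arcuate and callosal
   contaminants). The neonatal protocol tracks SLF II via a posterior
   middle-frontal ROI instead of the parietal ROI.
2. **Microstructure fitting** — the diffusion tensor (FA, MD, AD, RD) on
   the b = 0/1000 s/mm² sub-scheme by weighted least squares, and a
   simplified three-compartment neurite model (NDI, ODI; Watson-dispersed
   sticks + tortuosity zeppelin + free water) on all shells.
3. **Tract sampling** — trilinear sampling of each metric volume along
   every streamline, averaged over all sampling points of all streamlines
   into one tract mean per subject × bundle × metric.
4. **Maturation statistics** — lateralization indices
   (LI = (L − R)/(L + R)), Pearson age trends with Bonferroni–Dunn
   correction (p = 0.05/6 = 0.008), adult-vs-neonate contrasts with
   Cohen's d, and the headline quantity: for each branch, the Mahalanobis
   distance

   M²(x) = (x − μ)ᵀ Σ⁻¹ (x − μ) = Σᵢ ((x − μ)·vᵢ)² / λᵢ

   between a neonate's six-metric vector x = (NDI, ODI, FA, MD, AD, RD)
   and the adult reference distribution (μ, Σ) of the same branch, where
   vᵢ, λᵢ are the eigenvectors/eigenvalues of Σ. Smaller M = closer to the
   adult stage. Branches are compared by pairwise Wilcoxon signed-rank
   tests (α = 0.01 = 0.05/3) and M is correlated with post-menstrual age
   by Spearman rank correlation.

It also ships bit-exact readers/writers for TCK tractograms, NIfTI-1
volumes and FSL/MRtrix gradient tables, plus a synthetic phantom world
(ROI layout, bundle tractograms with ground-truth provenance, multi-shell
DWI signals, two-cohort metric tables) so the entire pipeline is testable
without any imaging data.

## Worked example

```r
library(slfmature)

# a phantom with 13 ROIs, six SLF-like bundles + callosal/arcuate
# contaminants, dissected with the neonatal rule table
layout  <- make_phantom()
sim     <- simulate_tractogram(layout, seed = 1)
bundles <- dissect_slf(sim$tractogram, layout, protocol = "neonate")
attr(bundles, "report")[, c("name", "n_kept")]
#> 1 SLF I L      100
#> 2 SLF II L     100
#> 3 SLF III L    100
#> 4 SLF I R      100
#> 5 SLF II R     100
#> 6 SLF III R    100
```

All 600 bundle streamlines are recovered (100 per branch and hemisphere);
the 180 contaminant streamlines are excluded by the NOT-ROIs.

```r
# synthetic neonate + adult cohorts and the maturation analysis
cohort <- simulate_cohort_tables(cohort_spec(), seed = 1)
maturation_analysis(cohort)
#> <maturation_result> 40 neonates, 3 bundles
#>   maturity ranking (least mature first):
#>     SLF II   mean M = 59.95 (SD 1.90)
#>     SLF I    mean M = 25.46 (SD 1.68)
#>     SLF III  mean M = 21.84 (SD 1.62)
#>   Wilcoxon (alpha = 0.01): SLF I vs SLF II; SLF I vs SLF III; SLF II vs SLF III significant
```

The generator gives SLF II a neonate-to-adult offset twice as far (in
covariance-whitened units) as the other branches, and the pipeline ranks
it least mature: its mean Mahalanobis distance (59.95) is far above
SLF I/III, and the pairwise Wilcoxon tests pass the corrected threshold.
`tidy()` returns the per-neonate distance table, `glance()` the per-branch
summary with the Spearman M-vs-age correlations (negative in every branch:
bundles drift toward the adult reference as PMA increases), and
`autoplot()` draws M against age per branch.

```r
dplyr::filter(trend_analysis(cohort), metric == "ndi")
#>   bundle  metric     r     t    df         p threshold significant
#> 1 SLF I   ndi    0.509  3.65    38 0.000791    0.00833 TRUE
#> 2 SLF II  ndi    0.595  4.57    38 0.0000507   0.00833 TRUE
#> 3 SLF III ndi    0.522  3.78    38 0.0005468   0.00833 TRUE
```

Neurite density rises significantly with post-menstrual age in all three
branches (r ≈ 0.5–0.6 at n = 40), while AD and ODI stay flat — the trend
structure the generator encodes and the real neonatal cohorts show.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the pipeline end to end against the installed package: phantom
dissection with ground-truth recovery accounting, tensor + neurite-model
fits on simulated multi-shell signals at SNR 30, and the full cohort
statistics (trends, contrasts, maturation ranking), printing a short
summary and writing the machine-readable report to `--out`.

## Layout

- `R/` — implementation: IO (`tck.R`, `nifti.R`, `gradients.R`), phantom
  and simulators (`phantom.R`, `simulate_tracts.R`, `signal.R`,
  `cohorts.R`), models (`dti.R`, `noddi.R`), dissection (`dissect.R`),
  sampling (`sampling.R`), statistics (`stats.R`, `wilcoxon.R`,
  `mahalanobis.R`), plus tidiers and plots.
- `inst/extdata/slf_rules.json` — the packaged adult/neonate rule table.
- `inst/cli/slfpipe.R` — thin command-line wrapper
  (`simulate`/`dissect`/`sample`/`stats`).
- `vignettes/slf-maturation-methods.Rmd` — the methods vignette: model
  assumptions, parameter choices, numerical decisions, what the synthetic
  world does and does not establish.
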